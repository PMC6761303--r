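#' Repeated ensemble training with per-contig vote fractions
#'
#' Trains `n_replicates` models (random forest or radial SVM) on
#' stratified random `train_frac` splits of the labeled contigs'
#' canonical k-mer frequencies (plus GC and/or coverage when the config's
#' `feature_type` asks for them), records held-out accuracy on the
#' remaining contigs of each replicate, and has every model classify all
#' unlabeled contigs. The vote fraction of class c for a contig is the
#' fraction of replicates predicting c; the final label is the class with
#' the highest fraction, with exact ties flagged ambiguous and left
#' unlabeled. Fully reproducible from the config seed.
#'
#' @param features a [build_kmer_matrix()] result.
#' @param labels label table; rows at `rank` define the training classes.
#' @param rank rank being predicted.
#' @param algo `"rf"` or `"svm"`.
#' @param cfg an [run_config()].
#' @param coverage optional coverage table, required when `"cov"` is in
#'   `feature_type`.
#' @param universe optional contig ids restricting the feature rows used
#'   (for nested classification); default all rows.
#' @return An object of class `vote_matrix`: list with `votes` (matrix
#'   unlabeled-contig x class of vote fractions), `final`
#'   (`data.frame(contig_id, rank, label, vote, ambiguous)`),
#'   `replicate_accuracy` (`data.frame(replicate, accuracy)`), `algo`,
#'   `rank`, `classes`.
#' @export
train_and_vote <- function(features, labels, rank, algo = c("rf", "svm"),
                           cfg = run_config(), coverage = NULL,
                           universe = NULL) {
  algo <- match.arg(algo)
  X <- classifier_features(features, cfg, coverage)
  if (!is.null(universe)) X <- X[intersect(rownames(X), universe), , drop = FALSE]
  lab <- labels[labels$rank == rank & labels$contig_id %in% rownames(X), , drop = FALSE]
  lab <- lab[!duplicated(lab$contig_id), , drop = FALSE]
  cls_n <- table(lab$label)
  small <- names(cls_n)[cls_n < cfg$min_class_size]
  if (length(small)) {
    warning("dropping class(es) with fewer than ", cfg$min_class_size,
            " labeled contigs: ", paste(small, collapse = ", "))
    lab <- lab[!lab$label %in% small, , drop = FALSE]
  }
  classes <- sort(unique(lab$label))
  if (length(classes) < 2)
    stop("need at least two classes with enough labeled contigs; ",
         "consider graph extension of the taxonomy or looser thresholds")
  unlabeled <- setdiff(rownames(X), lab$contig_id)
  y <- factor(lab$label, levels = classes)
  names(y) <- lab$contig_id
  Xl <- X[lab$contig_id, , drop = FALSE]
  Xu <- X[unlabeled, , drop = FALSE]

  set.seed(derive_seed(cfg$seed, paste0("classifier_", algo, "_", rank)))
  vote_counts <- matrix(0L, nrow = length(unlabeled), ncol = length(classes),
                        dimnames = list(unlabeled, classes))
  acc <- numeric(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    train_idx <- unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(cfg$train_frac * length(i))))
    }), use.names = FALSE)
    test_idx <- setdiff(seq_along(y), train_idx)
    fit <- if (algo == "rf") {
      randomForest::randomForest(Xl[train_idx, , drop = FALSE],
                                 droplevels(y[train_idx]),
                                 ntree = cfg$rf_trees)
    } else {
      e1071::svm(Xl[train_idx, , drop = FALSE], droplevels(y[train_idx]),
                 kernel = cfg$svm_kernel)
    }
    pred_test <- predict(fit, Xl[test_idx, , drop = FALSE])
    acc[r] <- mean(as.character(pred_test) == as.character(y[test_idx]))
    if (length(unlabeled)) {
      pred_u <- as.character(predict(fit, Xu))
      vote_counts[cbind(seq_along(unlabeled), match(pred_u, classes))] <-
        vote_counts[cbind(seq_along(unlabeled), match(pred_u, classes))] + 1L
    }
  }
  votes <- vote_counts / cfg$n_replicates
  final <- vote_final_labels(votes, rank)
  structure(list(votes = votes, final = final,
                 replicate_accuracy = data.frame(replicate = seq_len(cfg$n_replicates),
                                                 accuracy = acc),
                 algo = algo, rank = rank, classes = classes),
            class = "vote_matrix")
}

vote_final_labels <- function(votes, rank) {
  if (nrow(votes) == 0)
    return(data.frame(contig_id = character(), rank = character(),
                      label = character(), vote = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  top <- apply(votes, 1, max)
  amb <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  lab <- colnames(votes)[apply(votes, 1, which.max)]
  data.frame(contig_id = rownames(votes), rank = rank, label = lab,
             vote = top, ambiguous = amb, stringsAsFactors = FALSE)
}

#' @export
print.vote_matrix <- function(x, ...) {
  cat(sprintf("vote_matrix (%s, rank %s): %d unlabeled contigs x %d classes; mean held-out accuracy %.3f\n",
              x$algo, x$rank, nrow(x$votes), ncol(x$votes),
              mean(x$replicate_accuracy$accuracy)))
  invisible(x)
}

classifier_features <- function(features, cfg, coverage = NULL) {
  X <- features$kmers[!features$flagged, , drop = FALSE]
  if ("gc" %in% cfg$feature_type)
    X <- cbind(X, gc = features$gc[rownames(X)])
  if ("cov" %in% cfg$feature_type) {
    if (is.null(coverage)) stop("feature_type includes 'cov' but no coverage table given")
    X <- cbind(X, cov = coverage$coverage[match(rownames(X), coverage$contig_id)])
  }
  X
}

#' Nested per-rank classification with graph correction
#'
#' Runs [train_and_vote()] along the configured rank sequence (coarse to
#' fine). After each rank the predictions are merged with the existing
#' labels and, when a pair graph is supplied, corrected with
#' [transfer_labels()] in `correct_predictions` mode (mixed components
#' lose their predicted labels, marked misclassified). Iteration i
#' restricts the contig universe to contigs whose label at rank i-1
#' (homology, graph-extended or predicted) equals the target lineage at
#' that rank, so e.g. only Bacteria-labeled contigs enter a class-level
#' classification.
#'
#' @param features a [build_kmer_matrix()] result.
#' @param labels label table covering the ranks in `cfg$rank_sequence`.
#' @param cfg an [run_config()].
#' @param algo `"rf"` or `"svm"`.
#' @param rank_targets named character vector rank -> target taxon label,
#'   used to restrict the universe between iterations (needed when
#'   `rank_sequence` has more than one rank).
#' @param graph optional filtered pair graph for prediction correction.
#' @param coverage optional coverage table (for `feature_type` "cov").
#' @return List with `labels` (combined label table across ranks, ordered
#'   by contig id), `votes` (list of `vote_matrix` per rank),
#'   `misclassified` (contig ids whose predictions were discarded),
#'   `reports` (transfer reports per rank).
#' @export
nested_classify <- function(features, labels, cfg = run_config(),
                            algo = c("rf", "svm"), rank_targets = NULL,
                            graph = NULL, coverage = NULL) {
  algo <- match.arg(algo)
  ranks <- cfg$rank_sequence
  if (length(ranks) > 1 && is.null(rank_targets))
    stop("rank_targets is required for a multi-rank rank_sequence")
  universe <- rownames(features$kmers)
  all_labels <- labels
  votes <- list(); reports <- list(); miscl <- character(0)
  for (i in seq_along(ranks)) {
    rk <- ranks[i]
    if (i > 1) {
      prev <- ranks[i - 1]
      tgt <- rank_targets[[prev]]
      keep <- all_labels$contig_id[all_labels$rank == prev & all_labels$label == tgt]
      universe <- intersect(universe, keep)
      if (!length(universe))
        stop("empty contig universe after restricting to ", tgt, " at rank ", prev)
    }
    vm <- train_and_vote(features, all_labels, rk, algo, cfg,
                         coverage = coverage, universe = universe)
    votes[[rk]] <- vm
    pred <- vm$final[!vm$final$ambiguous, , drop = FALSE]
    if (nrow(pred))
      all_labels <- rbind(all_labels,
                          data.frame(contig_id = pred$contig_id, rank = rk,
                                     label = pred$label, taxon_density = NA_real_,
                                     source = "predicted", stringsAsFactors = FALSE))
    if (!is.null(graph)) {
      tr <- transfer_labels(graph, all_labels, rk, cfg, mode = "correct_predictions")
      reports[[rk]] <- tr$report
      miscl <- union(miscl, tr$misclassified)
      all_labels <- rbind(all_labels[all_labels$rank != rk, , drop = FALSE], tr$labels)
    }
  }
  all_labels <- all_labels[order(all_labels$rank, all_labels$contig_id), , drop = FALSE]
  rownames(all_labels) <- NULL
  list(labels = all_labels, votes = votes, misclassified = miscl,
       reports = reports)
}

#' Write classifier outputs in the RFoutput/SVMoutput layout
#'
#' @param result a [nested_classify()] result.
#' @param dir run output directory.
#' @return The folder path, invisibly.
#' @export
write_classifier_output <- function(result, dir) {
  algo <- result$votes[[1]]$algo
  sub <- file.path(dir, if (algo == "rf") "RFoutput" else "SVMoutput")
  for (rk in names(result$votes)) {
    vm <- result$votes[[rk]]
    v <- data.frame(contig_id = rownames(vm$votes), vm$votes,
                    check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(v, file.path(sub, paste0("votes_", rk, ".tsv")))
    write_tsv(vm$replicate_accuracy,
              file.path(sub, paste0("heldout_accuracy_", rk, ".tsv")))
  }
  write_tsv(result$labels, file.path(sub, "labels.tsv"))
  invisible(sub)
}
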