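#' Run the full deconvolution workflow
#'
#' Orchestrates the whole procedure on in-memory inputs: coverage
#' calculation, 16S target identification, TaxonDensity homology labels,
#' graph-based taxonomy extension, canonical k-mer composition, repeated
#' RF/SVM ensemble classification with graph-based prediction
#' correction, and then either (flow A, `clustering_enabled = TRUE`)
#' UMAP+DBSCAN clustering of the predicted-target contigs with target
#' cluster selection anchored on the 16S contig and graph extension to
#' short contigs, or (flow B) direct extraction of the contigs labeled
#' as the target. When a truth map is given, count- and length-weighted
#' performance is computed for each algorithm. A single seed in the
#' config governs all randomness.
#'
#' @param contigs named [Biostrings::DNAStringSet] ([read_contigs()]).
#' @param links mate-link table ([read_mate_links()]).
#' @param hits homology hit table (nucleotide, or nucleotide+protein
#'   rbind-ed); filtered idempotently with [filter_hits()].
#' @param lineage lineage table ([read_lineage()]).
#' @param s16 16S record table with rank columns (coverage is filled in
#'   from the computed coverage table; an existing `coverage` column is
#'   overwritten).
#' @param cfg an [run_config()]; `target_rank_label` must be set.
#' @param truth optional truth table `data.frame(contig_id, genome,
#'   <rank columns>)` as produced by [generate_mixture()].
#' @param out_dir optional output directory; when given, the standard
#'   folder layout (Taxonomy/, Coverage/, SVMoutput/, RFoutput/,
#'   ClusteringOutputSVM/, ClusteringOutputRF/) is written.
#' @param algos classifiers to run, subset of `c("rf", "svm")`.
#' @return An object of class `endobin_run`: list with the effective
#'   config, coverage table, 16S target contig, per-rank homology and
#'   extended labels, pair graph, k-mer matrix, and per-algorithm
#'   classification results, target contig ids and (if truth was given)
#'   performance reports.
#' @export
run_pipeline <- function(contigs, links, hits, lineage, s16,
                         cfg = run_config(), truth = NULL, out_dir = NULL,
                         algos = c("rf", "svm")) {
  if (is.null(cfg$target_rank_label))
    stop("cfg$target_rank_label must name the target organism's taxon")
  algos <- match.arg(algos, several.ok = TRUE)

  cov <- compute_coverage(links, contigs)

  s16$coverage <- cov$coverage[match(s16$contig_id, cov$contig_id)]
  target_16s <- identify_16s_targets(s16, cfg$target_rank_label, cfg$target_rank)
  t_row <- s16[match(target_16s, s16$contig_id), , drop = FALSE]
  present <- intersect(canonical_ranks(), names(t_row))
  rank_targets <- stats::setNames(as.character(unlist(t_row[1, present])), present)

  hits <- filter_hits(hits, cfg)
  labels <- do.call(rbind, lapply(cfg$rank_sequence, function(rk)
    assign_taxonomy(hits, lineage, rk, cfg)))

  graph <- build_graph(links, cfg)
  reports_ext <- list()
  for (rk in cfg$rank_sequence) {
    tr <- transfer_labels(graph, labels, rk, cfg, mode = "extend_taxonomy")
    reports_ext[[rk]] <- tr$report
    labels <- rbind(labels[labels$rank != rk, , drop = FALSE], tr$labels)
  }

  features <- build_kmer_matrix(contigs, cfg)
  last_rank <- cfg$rank_sequence[length(cfg$rank_sequence)]

  runs <- list()
  for (algo in algos) {
    cls <- nested_classify(features, labels, cfg, algo = algo,
                           rank_targets = rank_targets, graph = graph,
                           coverage = cov)
    res <- list(classification = cls)
    if (cfg$clustering_enabled) {
      tgt_last <- rank_targets[[last_rank]]
      universe <- cls$labels$contig_id[cls$labels$rank == last_rank &
                                         cls$labels$label == tgt_last]
      assign <- embed_and_cluster(features, cfg, coverage = cov,
                                  universe = universe)
      core <- select_target_cluster(assign, target_16s)
      ext <- extend_target_cluster(graph, core, assign, cfg)
      res$cluster_assignment <- assign
      res$target_cluster <- core
      res$target_ids <- ext$target_ids
      res$cluster_extension_report <- ext$report
    } else {
      tgt <- rank_targets[[cfg$target_rank]]
      res$target_ids <- sort(unique(
        cls$labels$contig_id[cls$labels$rank == cfg$target_rank &
                               cls$labels$label == tgt]))
    }
    if (!is.null(truth)) {
      tr_lab <- ifelse(!is.na(truth[[cfg$target_rank]]) &
                         truth[[cfg$target_rank]] == cfg$target_rank_label,
                       "target", "other")
      names(tr_lab) <- truth$contig_id
      lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
      res$performance <- score_binning(res$target_ids, tr_lab, lens)
    }
    runs[[algo]] <- res
  }

  state <- structure(list(config = cfg, coverage = cov, graph = graph,
                          features = features, labels = labels,
                          target_16s = target_16s,
                          rank_targets = rank_targets,
                          extension_reports = reports_ext, runs = runs),
                     class = "endobin_run")
  if (!is.null(out_dir)) write_run(state, contigs, hits, out_dir)
  state
}

#' @export
print.endobin_run <- function(x, ...) {
  cat("endobin run: target", x$config$target_rank_label, "at rank",
      x$config$target_rank, "(16S anchor:", x$target_16s, ")\n")
  for (algo in names(x$runs)) {
    r <- x$runs[[algo]]
    cat(sprintf("  %s: %d target contigs\n", algo, length(r$target_ids)))
    if (!is.null(r$performance)) {
      cat(sprintf("    length-weighted F1 %.4f, sensitivity %.4f, precision %.4f\n",
                  r$performance$lengths$f1, r$performance$lengths$sensitivity,
                  r$performance$lengths$precision))
    }
  }
  invisible(x)
}

write_run <- function(state, contigs, hits, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(hits, file.path(out_dir, "Taxonomy", "filtered_hits.tsv"))
  write_tsv(state$labels, file.path(out_dir, "Taxonomy", "labels.tsv"))
  write_tsv(state$coverage, file.path(out_dir, "Coverage", "coverage.tsv"))
  write_composition(state$features, state$coverage, out_dir)
  write_graph_edges(state$graph, file.path(out_dir, "Taxonomy", "pair_graph_edges.tsv"))
  for (algo in names(state$runs)) {
    r <- state$runs[[algo]]
    write_classifier_output(r$classification, out_dir)
    sub <- file.path(out_dir, if (algo == "rf") "ClusteringOutputRF" else "ClusteringOutputSVM")
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(r$cluster_assignment))
      write_tsv(r$cluster_assignment, file.path(sub, "clusters.tsv"))
    writeLines(r$target_ids, file.path(sub, "target_contigs.txt"))
    Biostrings::writeXStringSet(contigs[r$target_ids],
                                file.path(sub, "target_contigs.fasta"))
    if (!is.null(r$performance))
      write_tsv(performance_table(r$performance),
                file.path(sub, "performance.tsv"))
  }
  invisible(out_dir)
}
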