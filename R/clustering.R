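#' DBSCAN density clustering
#'
#' Classic density-based clustering: points with at least `minpts`
#' neighbours (self included) within `eps` are core points; clusters are
#' the connected regions of core points plus their border points; the
#' rest is noise (cluster 0). Implemented directly on the pairwise
#' Euclidean distance matrix, which is adequate at the scale of a
#' per-assembly contig set.
#'
#' @param X numeric matrix (rows = points).
#' @param eps neighbourhood radius.
#' @param minpts minimum neighbourhood size of a core point.
#' @return Integer vector of cluster ids (0 = noise), one per row of `X`.
#' @export
dbscan_cluster <- function(X, eps, minpts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbs, length, integer(1)) >= minpts
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    cl[i] <- cur
    queue <- setdiff(nbs[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (cl[j] == 0L) {
        cl[j] <- cur
        if (core[j]) queue <- union(queue, nbs[[j]][cl[nbs[[j]]] == 0L])
      }
    }
  }
  cl
}

#' Choose a DBSCAN radius from the kNN-distance knee
#'
#' Sorts each point's distance to its `minpts`-th nearest neighbour and
#' returns the value at the knee of the curve (the point farthest from
#' the chord joining the curve's endpoints), the usual heuristic for
#' picking eps when dataset scale varies widely.
#'
#' @param X numeric matrix.
#' @param minpts neighbourhood size.
#' @return Numeric eps.
#' @export
knee_eps <- function(X, minpts) {
  D <- as.matrix(stats::dist(X))
  kd <- apply(D, 1, function(d) sort(d)[minpts])  # includes self at rank 1
  kd <- sort(kd)
  n <- length(kd)
  if (n < 3 || kd[n] == kd[1]) return(max(kd[n], .Machine$double.eps))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (kd - kd[1]) / (kd[n] - kd[1])
  dist_to_chord <- abs(y - x) / sqrt(2)
  eps <- kd[which.max(dist_to_chord)]
  max(eps, .Machine$double.eps)
}

#' Embed predicted-target contigs and cluster them
#'
#' UMAP embedding of the canonical k-mer frequencies into `ncomp`
#' dimensions, optionally augmented with z-score-standardised GC and/or
#' coverage columns appended to the embedding coordinates (the
#' augmentation happens after embedding), followed by DBSCAN. The run is
#' deterministic under the config seed.
#'
#' @param features a [build_kmer_matrix()] result, already restricted (or
#'   restricted via `universe`) to the predicted-target contigs.
#' @param cfg an [run_config()].
#' @param coverage coverage table, required when `"cov"` is in
#'   `feature_type`.
#' @param universe optional contig ids to restrict the rows used.
#' @return `data.frame(contig_id, <ncomp embedding columns>, cluster)`
#'   with cluster 0 meaning noise.
#' @export
embed_and_cluster <- function(features, cfg = run_config(), coverage = NULL,
                              universe = NULL) {
  X <- features$kmers[!features$flagged, , drop = FALSE]
  if (!is.null(universe)) X <- X[intersect(rownames(X), universe), , drop = FALSE]
  n <- nrow(X)
  if (n < max(10, cfg$dbscan_minpts))
    stop("too few contigs (", n, ") for the clustering step; ",
         "consider disabling clustering (flow B)")
  set.seed(derive_seed(cfg$seed, "umap"))
  emb <- uwot::umap(X, n_components = cfg$ncomp,
                    n_neighbors = min(cfg$umap_n_neighbors, n - 1),
                    min_dist = cfg$umap_min_dist, n_threads = 1,
                    n_sgd_threads = 0)
  rownames(emb) <- rownames(X)
  Z <- emb
  zscore <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  if ("gc" %in% cfg$feature_type)
    Z <- cbind(Z, gc = zscore(features$gc[rownames(X)]))
  if ("cov" %in% cfg$feature_type) {
    if (is.null(coverage)) stop("feature_type includes 'cov' but no coverage table given")
    Z <- cbind(Z, cov = zscore(coverage$coverage[match(rownames(X), coverage$contig_id)]))
  }
  eps <- if (is.null(cfg$dbscan_eps)) knee_eps(Z, cfg$dbscan_minpts) else cfg$dbscan_eps
  cl <- dbscan_cluster(Z, eps, cfg$dbscan_minpts)
  out <- data.frame(contig_id = rownames(X), emb, cluster = cl,
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + ncol(emb))] <- paste0("dim", seq_len(ncol(emb)))
  rownames(out) <- NULL
  out
}

#' Select the cluster anchored by the target 16S contig
#'
#' @param assignment [embed_and_cluster()] result.
#' @param target_16s_contig contig id carrying the target 16S gene.
#' @return Character vector of contig ids sharing the target contig's
#'   cluster.
#' @export
select_target_cluster <- function(assignment, target_16s_contig) {
  i <- match(target_16s_contig, assignment$contig_id)
  if (is.na(i))
    stop("target 16S contig ", target_16s_contig, " absent from the cluster ",
         "assignment (possibly shorter than min_contig_len); ",
         "use the graph-extension path or lower the length threshold")
  cl <- assignment$cluster[i]
  if (cl == 0) {
    emb_cols <- grep("^dim", names(assignment))
    centers <- stats::aggregate(assignment[assignment$cluster != 0, emb_cols, drop = FALSE],
                                by = list(cluster = assignment$cluster[assignment$cluster != 0]),
                                FUN = mean)
    dists <- sqrt(rowSums((as.matrix(centers[, -1, drop = FALSE]) -
                             matrix(as.numeric(assignment[i, emb_cols]),
                                    nrow(centers), length(emb_cols), byrow = TRUE))^2))
    stop("target 16S contig was classed as noise; nearest cluster is ",
         centers$cluster[which.min(dists)], " at embedding distance ",
         signif(min(dists), 3))
  }
  members <- assignment$contig_id[assignment$cluster == cl]
  if (length(members) == 1)
    warning("target 16S contig is the only member of its cluster")
  sort(members)
}

#' Extend the target cluster to short contigs via the pair graph
#'
#' Contigs below the composition length threshold never enter the k-mer
#' matrix, but they do appear in the read-pair graph; cluster membership
#' is therefore transferred along connected components with the same
#' rules as taxonomy extension (target members vote "target", other
#' clustered contigs "nontarget").
#'
#' @param graph filtered pair graph.
#' @param target_ids contigs currently in the target cluster.
#' @param assignment [embed_and_cluster()] result (defines the
#'   "nontarget" labeled contigs).
#' @param cfg an [run_config()].
#' @return List with `target_ids` (extended, sorted) and `report` (the
#'   transfer report).
#' @export
extend_target_cluster <- function(graph, target_ids, assignment, cfg = run_config()) {
  clustered <- assignment[assignment$cluster != 0, , drop = FALSE]  # noise stays unlabeled
  lab <- data.frame(contig_id = clustered$contig_id, rank = "cluster",
                    label = ifelse(clustered$contig_id %in% target_ids,
                                   "target", "nontarget"),
                    taxon_density = NA_real_, source = "cluster",
                    stringsAsFactors = FALSE)
  tr <- transfer_labels(graph, lab, "cluster", cfg, mode = "extend_clusters")
  ext <- tr$labels$contig_id[tr$labels$label == "target"]
  list(target_ids = sort(union(target_ids, ext)), report = tr$report)
}
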