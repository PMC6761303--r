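#' Build the read-pair linkage graph
#'
#' Two contigs are connected when at least one read pair has its mates on
#' both; edge weight is the number of supporting pairs. Chimeric links
#' are controlled in two fixed passes: edges with weight below
#' `edges_min` are removed first, then vertices whose remaining degree
#' exceeds `vertices_max_degree` are removed with their incident edges
#' (a single pass by default; set `iterate_degree_filter` in the config
#' to iterate to a fixed point). Every mapped contig stays as a vertex,
#' so isolated contigs form singleton components.
#'
#' @param links mate-link table.
#' @param cfg an [run_config()].
#' @return An [igraph::graph] with vertex attribute `name` (contig id)
#'   and edge attribute `weight`.
#' @export
build_graph <- function(links, cfg = run_config()) {
  verts <- sort(unique(stats::na.omit(c(links$contig_a, links$contig_b))))
  cross <- links$type == "paired" & !is.na(links$contig_a) &
    !is.na(links$contig_b) & links$contig_a != links$contig_b
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (any(cross)) {
    a <- pmin(links$contig_a[cross], links$contig_b[cross])
    b <- pmax(links$contig_a[cross], links$contig_b[cross])
    tab <- table(paste(a, b, sep = "\r"))
    keep <- as.numeric(tab) >= cfg$edges_min
    if (any(keep)) {
      ends <- do.call(rbind, strsplit(names(tab)[keep], "\r", fixed = TRUE))
      g <- igraph::add_edges(g, as.vector(t(ends)),
                             weight = as.numeric(tab)[keep])
    }
  }
  repeat {
    too_connected <- igraph::V(g)[igraph::degree(g) > cfg$vertices_max_degree]
    if (length(too_connected) == 0) break
    g <- igraph::delete_vertices(g, too_connected)
    if (!cfg$iterate_degree_filter) break
  }
  g
}

#' Transfer taxonomy labels along the read-pair graph
#'
#' Within each connected component (CC) the majority label among labeled
#' members can be propagated to unlabeled members. Three modes share the
#' transfer rules:
#' \describe{
#'   \item{extend_taxonomy}{extend homology labels before classification;
#'     new labels get `source = "graph_extension"`.}
#'   \item{correct_predictions}{same transfer, but a CC whose labels are
#'     too mixed additionally has every `source = "predicted"` label
#'     removed and those contigs recorded as misclassified.}
#'   \item{extend_clusters}{extend cluster membership to short contigs;
#'     new labels get `source = "cluster"`.}
#' }
#'
#' With `vertexdist = "all"` the mixed-component veto applies: let `f` be
#' the fraction of labeled members disagreeing with the majority label;
#' if `f > mixedcomp_max` (or the majority is tied) the CC is skipped,
#' otherwise the majority label spreads to every unlabeled member. With
#' an integer `vertexdist` the veto is bypassed and the majority label
#' (ties broken lexicographically) propagates along unweighted shortest
#' paths up to that distance, stopping two hops short of any
#' conflicting labeled vertex (the "up to node n-2" rule); conflicting
#' labels act only as blockers. Existing labels are never overwritten.
#'
#' @param graph filtered [build_graph()] result.
#' @param labels label table at one rank.
#' @param rank rank being transferred.
#' @param cfg an [run_config()].
#' @param mode one of `"extend_taxonomy"`, `"correct_predictions"`,
#'   `"extend_clusters"`.
#' @return List with `labels` (updated label table) and `report` (one row
#'   per CC: `cc_id, n_members, n_labeled, majority_label, f, action,
#'   n_transferred, n_misclassified, members`), plus `misclassified`
#'   (character vector of contig ids stripped of their predicted label).
#' @export
transfer_labels <- function(graph, labels, rank, cfg = run_config(),
                            mode = c("extend_taxonomy", "correct_predictions",
                                     "extend_clusters")) {
  mode <- match.arg(mode)
  new_source <- switch(mode, extend_taxonomy = "graph_extension",
                       correct_predictions = "graph_extension",
                       extend_clusters = "cluster")
  labels <- labels[labels$rank == rank, , drop = FALSE]
  comp <- igraph::components(graph)
  vnames <- igraph::V(graph)$name
  rows <- list(); added <- list(); miscl <- character(0)
  for (cc in seq_len(comp$no)) {
    members <- vnames[comp$membership == cc]
    lab <- labels[labels$contig_id %in% members, , drop = FALSE]
    rec <- data.frame(cc_id = cc, n_members = length(members),
                      n_labeled = nrow(lab), majority_label = NA_character_,
                      f = NA_real_, action = NA_character_,
                      n_transferred = 0L, n_misclassified = 0L,
                      members = paste(sort(members), collapse = ","),
                      stringsAsFactors = FALSE)
    if (nrow(lab) == 0) {
      rec$action <- "skipped_unlabeled"
      rows[[cc]] <- rec
      next
    }
    tab <- sort(table(lab$label), decreasing = TRUE)
    tied <- length(tab) > 1 && tab[2] == tab[1]
    majority <- names(tab)[1]
    f <- 1 - as.numeric(tab[1]) / nrow(lab)
    rec$f <- f
    unlabeled <- setdiff(members, lab$contig_id)
    if (identical(cfg$vertexdist, "all")) {
      if (tied || f > cfg$mixedcomp_max) {
        rec$action <- "skipped_mixed"
        if (mode == "correct_predictions") {
          bad <- lab$contig_id[lab$source == "predicted"]
          miscl <- c(miscl, bad)
          rec$n_misclassified <- length(bad)
        }
      } else {
        rec$majority_label <- majority
        rec$action <- "transferred"
        rec$n_transferred <- length(unlabeled)
        if (length(unlabeled))
          added[[length(added) + 1L]] <- data.frame(
            contig_id = unlabeled, rank = rank, label = majority,
            taxon_density = NA_real_, source = new_source,
            stringsAsFactors = FALSE)
      }
    } else {
      d <- cfg$vertexdist
      majority <- sort(names(tab)[tab == tab[1]])[1]  # deterministic under ties
      rec$majority_label <- majority
      src <- lab$contig_id[lab$label == majority]
      blockers <- lab$contig_id[lab$label != majority]
      if (length(unlabeled)) {
        hop <- function(from) apply(igraph::distances(graph, v = from,
                                                      to = unlabeled,
                                                      weights = NA), 2, min)
        d_maj <- hop(src)
        d_conf <- if (length(blockers)) hop(blockers) else rep(Inf, length(unlabeled))
        ok <- d_maj <= d & d_conf >= 2
        rec$n_transferred <- sum(ok)
        rec$action <- if (all(ok)) "transferred" else "truncated_at_distance"
        if (any(ok))
          added[[length(added) + 1L]] <- data.frame(
            contig_id = unlabeled[ok], rank = rank, label = majority,
            taxon_density = NA_real_, source = new_source,
            stringsAsFactors = FALSE)
      } else {
        rec$action <- "transferred"
      }
    }
    rows[[cc]] <- rec
  }
  out_labels <- labels
  if (length(miscl))
    out_labels <- out_labels[!(out_labels$contig_id %in% miscl &
                                 out_labels$source == "predicted"), , drop = FALSE]
  if (length(added))
    out_labels <- rbind(out_labels, do.call(rbind, added))
  out_labels <- out_labels[order(out_labels$contig_id), , drop = FALSE]
  rownames(out_labels) <- NULL
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(labels = out_labels, report = report, misclassified = unique(miscl))
}

#' Export the pair graph as a weighted edge list
#'
#' @param graph [build_graph()] result.
#' @param path output TSV (`contig_a, contig_b, weight`).
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  e <- igraph::as_data_frame(graph, what = "edges")
  names(e) <- c("contig_a", "contig_b", "weight")
  write_tsv(e, path)
}
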