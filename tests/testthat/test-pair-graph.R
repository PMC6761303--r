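pairs_df <- function(a, b, n) {
  data.frame(fragment_id = sprintf("%s_%s_%d", a, b, seq_len(n)),
             contig_a = a, contig_b = b, type = "paired",
             stringsAsFactors = FALSE)
}

test_that("edge-weight and vertex-degree filters prune the graph in order", {
  links <- rbind(pairs_df("c1", "c2", 12), pairs_df("c1", "c3", 3))
  g <- build_graph(links, run_config())
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1)
  expect_equal(sort(unlist(e[1, 1:2])), c("c1", "c2"), ignore_attr = TRUE)
  expect_equal(e$weight, 12)

  # hub with 6 strong neighbours: edge filter keeps all, degree filter kills the hub
  hub <- do.call(rbind, lapply(paste0("n", 1:6), function(x) pairs_df("hub", x, 20)))
  gh <- build_graph(hub, run_config())
  expect_false("hub" %in% igraph::V(gh)$name)
  expect_equal(igraph::ecount(gh), 0)

  gh2 <- build_graph(hub, run_config(vertices_max_degree = Inf))
  expect_true("hub" %in% igraph::V(gh2)$name)
  expect_equal(igraph::ecount(gh2), 6)

  same <- pairs_df("c1", "c1", 30)
  gs <- build_graph(same, run_config())
  expect_equal(igraph::vcount(gs), 1)
  expect_equal(igraph::ecount(gs), 0)
})

test_that("a single-label component transfers to every member", {
  g <- path_graph(c("L", "u1", "u2", "u3"))
  lab <- label_row("L", "Bacteria")
  tr <- transfer_labels(g, lab, "superkingdom", run_config(), "extend_taxonomy")
  got <- tr$labels[tr$labels$source == "graph_extension", ]
  expect_equal(sort(got$contig_id), c("u1", "u2", "u3"))
  expect_true(all(got$label == "Bacteria"))
  expect_equal(tr$report$action, "transferred")

  # idempotence: a second pass changes nothing
  tr2 <- transfer_labels(g, tr$labels, "superkingdom", run_config(), "extend_taxonomy")
  expect_equal(tr2$labels, tr$labels)
})

test_that("a 3:1 mixed component is vetoed at the default MIXEDCOMP", {
  g <- path_graph(c("a", "b", "c", "d", "u"))
  lab <- rbind(label_row(c("a", "b", "c"), "Bacteria"),
               label_row("d", "Eukaryota"))
  tr <- transfer_labels(g, lab, "superkingdom", run_config(), "extend_taxonomy")
  expect_equal(tr$report$action, "skipped_mixed")
  expect_equal(tr$report$f, 0.25)
  expect_false("u" %in% tr$labels$contig_id)

  # a looser threshold lets the same component through
  tr2 <- transfer_labels(g, lab, "superkingdom",
                         run_config(mixedcomp_max = 0.3), "extend_taxonomy")
  expect_equal(tr2$report$action, "transferred")
  expect_equal(tr2$labels$label[tr2$labels$contig_id == "u"], "Bacteria")
})

test_that("bounded transfer stops two hops short of a conflicting vertex", {
  g <- path_graph(c("L", "u1", "u2", "X"))
  lab <- rbind(label_row("L", "Bacteria"), label_row("X", "Eukaryota"))
  tr <- transfer_labels(g, lab, "superkingdom",
                        run_config(vertexdist = 3), "extend_taxonomy")
  new <- tr$labels[tr$labels$source == "graph_extension", ]
  expect_equal(new$contig_id, "u1")
  expect_equal(new$label, "Bacteria")

  # without the conflict the whole path within distance is labeled
  tr2 <- transfer_labels(g, label_row("L", "Bacteria"), "superkingdom",
                         run_config(vertexdist = 2), "extend_taxonomy")
  expect_equal(sort(tr2$labels$contig_id[tr2$labels$source == "graph_extension"]),
               c("u1", "u2"))
})

test_that("correction mode strips predicted labels in mixed components", {
  g <- path_graph(c("h1", "h2", "p1", "p2"))
  lab <- rbind(label_row("h1", "Bacteria"),
               label_row("h2", "Eukaryota"),
               label_row(c("p1", "p2"), "Bacteria", source = "predicted"))
  tr <- transfer_labels(g, lab, "superkingdom", run_config(), "correct_predictions")
  expect_equal(sort(tr$misclassified), c("p1", "p2"))
  expect_false(any(tr$labels$contig_id %in% c("p1", "p2")))
  expect_true(all(c("h1", "h2") %in% tr$labels$contig_id))  # homology labels kept
})

test_that("with mixedcomp_max = 0 any two-label component is skipped", {
  g <- path_graph(c("a", "b", "c"))
  lab <- rbind(label_row(c("a", "b"), "Bacteria"), label_row("c", "Eukaryota"))
  tr <- transfer_labels(g, lab, "superkingdom",
                        run_config(mixedcomp_max = 0), "extend_taxonomy")
  expect_equal(tr$report$action, "skipped_mixed")
})

test_that("labels never cross connected components", {
  set.seed(404)
  for (rep in 1:100) {
    n_cc <- sample(2:4, 1)
    ids <- list(); g <- igraph::make_empty_graph(directed = FALSE)
    for (cc in seq_len(n_cc)) {
      sz <- sample(2:6, 1)
      v <- sprintf("cc%d_v%d", cc, seq_len(sz))
      ids[[cc]] <- v
      g <- igraph::add_vertices(g, sz, name = v)
      for (i in seq_len(sz - 1))
        g <- igraph::add_edges(g, c(v[i], v[i + 1]), weight = 20)
    }
    labeled_cc <- sample(n_cc, 1)
    lab <- label_row(ids[[labeled_cc]][1], "Bacteria")
    tr <- transfer_labels(g, lab, "superkingdom", run_config(), "extend_taxonomy")
    outside <- unlist(ids[-labeled_cc])
    expect_false(any(tr$labels$contig_id %in% outside))
  }
})

test_that("graph extension is perfectly precise when genomes share no links", {
  mix <- fixture_mixture()
  expect_equal(mix$spec$cross_noise, 0)
  g <- build_graph(mix$links, run_config())
  # no edge joins the two genomes
  e <- igraph::as_data_frame(g)
  genome_of <- stats::setNames(mix$truth$genome, mix$truth$contig_id)
  expect_true(all(genome_of[e$from] == genome_of[e$to]))

  lab <- assign_taxonomy(filter_hits(mix$hits, run_config()), mix$lineage,
                         "superkingdom", run_config())
  tr <- transfer_labels(g, lab, "superkingdom", run_config(), "extend_taxonomy")
  ext <- tr$labels[tr$labels$source == "graph_extension", ]
  expect_gt(nrow(ext), 0)
  truth_sk <- stats::setNames(mix$truth$superkingdom, mix$truth$contig_id)
  expect_true(all(ext$label == truth_sk[ext$contig_id]))  # precision 1.0
})
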