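test_that("DBSCAN finds two blobs and marks stragglers as noise", {
  set.seed(505)
  X <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
             matrix(rnorm(100, 5, 0.2), ncol = 2),
             c(20, 20))                       # far outlier
  cl <- dbscan_cluster(X, eps = 1, minpts = 5)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
  expect_true(cl[1] != cl[51])
  expect_equal(cl[101], 0)
})

test_that("the knee heuristic picks a workable radius", {
  set.seed(506)
  X <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
             matrix(rnorm(200, 6, 0.3), ncol = 2))
  eps <- knee_eps(X, 5)
  cl <- dbscan_cluster(X, eps, 5)
  expect_gte(length(setdiff(unique(cl), 0)), 2)
})

majority_purity <- function(assign, truth_genome) {
  ok <- 0
  for (g in unique(truth_genome)) {
    members <- assign$cluster[truth_genome[assign$contig_id] == g]
    members <- members[members != 0]
    ok <- ok + max(table(members))
  }
  ok / sum(assign$cluster != 0)
}

test_that("genomes with divergent composition separate in the embedding", {
  mix <- fixture_separable()
  cfg <- run_config(seed = 12)
  km <- build_kmer_matrix(mix$contigs, cfg)
  assign <- embed_and_cluster(km, cfg)
  truth_genome <- stats::setNames(mix$truth$genome, mix$truth$contig_id)
  expect_gte(length(setdiff(unique(assign$cluster), 0)), 2)
  expect_gt(majority_purity(assign, truth_genome), 0.9)
  # deterministic under the seed
  assign2 <- embed_and_cluster(km, cfg)
  expect_identical(assign$cluster, assign2$cluster)
})

test_that("the coverage channel separates composition-identical genomes", {
  tr <- matrix(0.25, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  g1 <- genome_spec("one", 1L, c(superkingdom = "Bacteria"), n_contigs = 80L,
                    contig_meanlog = log(2000), contig_sdlog = 0.2,
                    min_contig = 1200L, gc = 0.5, coverage_multiplier = 10,
                    transition = tr)
  g2 <- genome_spec("two", 2L, c(superkingdom = "Bacteria"), n_contigs = 80L,
                    contig_meanlog = log(2000), contig_sdlog = 0.2,
                    min_contig = 1200L, gc = 0.5, coverage_multiplier = 1,
                    transition = tr)
  mix <- generate_mixture(mixture_spec(list(g1, g2), seed = 8))
  cfg <- run_config(seed = 8, feature_type = c("kmers", "cov"))
  km <- build_kmer_matrix(mix$contigs, cfg)
  cov <- compute_coverage(mix$links, mix$contigs)
  assign <- embed_and_cluster(km, cfg, coverage = cov)
  truth_genome <- stats::setNames(mix$truth$genome, mix$truth$contig_id)
  expect_gt(majority_purity(assign, truth_genome), 0.9)
})

test_that("a homogeneous genome yields one dominant cluster", {
  g <- genome_spec("solo", 1L, c(superkingdom = "Bacteria"), n_contigs = 100L,
                   contig_meanlog = log(2000), contig_sdlog = 0.2,
                   min_contig = 1200L, gc = 0.4)
  mix <- generate_mixture(mixture_spec(list(g), seed = 13))
  cfg <- run_config(seed = 13)
  km <- build_kmer_matrix(mix$contigs, cfg)
  assign <- embed_and_cluster(km, cfg)
  expect_gt(max(table(assign$cluster[assign$cluster != 0])) / nrow(assign), 0.8)
})

test_that("target-cluster selection returns the anchor's cluster and flags edge cases", {
  assign <- data.frame(contig_id = c("a", "b", "c", "d", "e"),
                       dim1 = c(0, 0.1, 5, 5.1, 9), dim2 = 0,
                       cluster = c(1L, 1L, 2L, 2L, 0L),
                       stringsAsFactors = FALSE)
  expect_equal(select_target_cluster(assign, "c"), c("c", "d"))
  expect_error(select_target_cluster(assign, "zz"), "absent")
  expect_error(select_target_cluster(assign, "e"), "noise")

  lone <- data.frame(contig_id = c("a", "b"), dim1 = c(0, 9), dim2 = 0,
                     cluster = c(1L, 2L), stringsAsFactors = FALSE)
  expect_warning(got <- select_target_cluster(lone, "a"), "only member")
  expect_equal(got, "a")
})

test_that("graph extension pulls linked short contigs into the target set", {
  g <- path_graph(c("long1", "long2", "short1"))
  assign <- data.frame(contig_id = c("long1", "long2", "other1", "other2"),
                       dim1 = c(0, 0.1, 5, 5.1), dim2 = 0,
                       cluster = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  ext <- extend_target_cluster(g, c("long1", "long2"), assign, run_config())
  expect_true("short1" %in% ext$target_ids)
  expect_false(any(c("other1", "other2") %in% ext$target_ids))
})
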