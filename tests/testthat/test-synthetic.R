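test_that("generated genomes honour their GC and coverage specifications", {
  ga <- genome_spec("lowgc", 1L, c(superkingdom = "Bacteria"), n_contigs = 200L,
                    contig_meanlog = log(1200), contig_sdlog = 0.3, gc = 0.30,
                    coverage_multiplier = 9)
  gb <- genome_spec("highgc", 2L, c(superkingdom = "Eukaryota"), n_contigs = 200L,
                    contig_meanlog = log(1200), contig_sdlog = 0.3, gc = 0.55,
                    coverage_multiplier = 1)
  mix <- generate_mixture(mixture_spec(list(ga, gb), seed = 77))
  gcs <- vapply(as.character(mix$contigs), gc_content, numeric(1))
  genome <- stats::setNames(mix$truth$genome, mix$truth$contig_id)[names(gcs)]
  expect_equal(mean(gcs[genome == "lowgc"]), 0.30, tolerance = 0.03)
  expect_equal(mean(gcs[genome == "highgc"]), 0.55, tolerance = 0.03)

  cov <- compute_coverage(mix$links, mix$contigs)
  cov_genome <- genome[cov$contig_id]
  ratio <- mean(cov$coverage[cov_genome == "lowgc"]) /
    mean(cov$coverage[cov_genome == "highgc"])
  expect_gt(ratio, 6)
  expect_lt(ratio, 12)
})

test_that("homology labels appear at the requested rate and match truth when error-free", {
  mix <- fixture_mixture()
  expect_equal(mix$spec$label_error, 0)
  hits <- filter_hits(mix$hits, run_config())
  labeled <- unique(hits$contig_id)
  rate <- length(labeled) / length(mix$contigs)
  expect_gt(rate, 0.25)
  expect_lt(rate, 0.40)
  lab <- assign_taxonomy(hits, mix$lineage, "superkingdom", run_config())
  truth_sk <- stats::setNames(mix$truth$superkingdom, mix$truth$contig_id)
  expect_true(all(lab$label == truth_sk[lab$contig_id]))
})

test_that("the below-threshold spike-ins are removed by the hit filter", {
  mix <- fixture_mixture()
  raw <- mix$hits
  kept <- filter_hits(raw, run_config())
  expect_lt(nrow(kept), nrow(raw))
  dropped <- raw[!(paste(raw$contig_id, raw$pident, raw$hsp_len) %in%
                     paste(kept$contig_id, kept$pident, kept$hsp_len)), ]
  expect_true(all(dropped$pident < 70 | dropped$hsp_len < 200))
})

test_that("identical seeds give byte-identical mixtures; seeds matter", {
  m1 <- generate_mixture(default_mixture_spec(seed = 3))
  m2 <- generate_mixture(default_mixture_spec(seed = 3))
  expect_identical(as.character(m1$contigs), as.character(m2$contigs))
  expect_identical(m1$links, m2$links)
  expect_identical(m1$hits, m2$hits)
  m3 <- generate_mixture(default_mixture_spec(seed = 4))
  expect_false(identical(as.character(m1$contigs), as.character(m3$contigs)))
})

test_that("without link noise the pair graph never joins genomes", {
  mix <- fixture_mixture()
  g <- build_graph(mix$links, run_config())
  e <- igraph::as_data_frame(g)
  genome <- stats::setNames(mix$truth$genome, mix$truth$contig_id)
  expect_gt(nrow(e), 0)
  expect_true(all(genome[e$from] == genome[e$to]))
})

test_that("written mixture files read back into equivalent tables", {
  dir <- withr::local_tempdir()
  mix <- fixture_mixture()
  paths <- write_mixture(mix, dir)
  cs <- read_contigs(paths["contigs"])
  expect_identical(as.character(cs), as.character(mix$contigs))
  lk <- read_mate_links(paths["links"])
  expect_equal(lk, mix$links, ignore_attr = TRUE)
  h <- read_hits(paths["hits"], "nucleotide", run_config())
  expect_equal(h[, c("contig_id", "taxid", "pident", "hsp_len")],
               filter_hits(mix$hits, run_config())[, c("contig_id", "taxid",
                                                       "pident", "hsp_len")],
               ignore_attr = TRUE)
  li <- read_lineage(paths["lineage"])
  expect_equal(li, mix$lineage, ignore_attr = TRUE)
  g16 <- read_16s_gff(paths["gff"])
  expect_equal(g16$contig_id, mix$s16$contig_id)
  expect_equal(g16$start, mix$s16$start)
  expect_equal(g16$end, mix$s16$end)
})
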