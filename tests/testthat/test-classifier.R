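test_that("both ensembles recover a separable two-class mixture", {
  mix <- fixture_separable()
  cfg <- run_config(seed = 9, n_replicates = 25)
  km <- build_kmer_matrix(mix$contigs, cfg)
  expect_equal(nrow(km$kmers), 300)
  lab <- truth_labels(mix, 200)
  truth_sk <- stats::setNames(mix$truth$superkingdom, mix$truth$contig_id)
  for (algo in c("rf", "svm")) {
    vm <- train_and_vote(km, lab, "superkingdom", algo, cfg)
    expect_gt(mean(vm$replicate_accuracy$accuracy), 0.95)
    expect_equal(nrow(vm$votes), 100)
    expect_equal(unname(rowSums(vm$votes)), rep(1, 100))  # votes sum to 1
    final <- vm$final[!vm$final$ambiguous, ]
    expect_gt(mean(final$label == truth_sk[final$contig_id]), 0.95)
  }
})

test_that("the vote matrix is reproducible from the seed", {
  mix <- fixture_separable()
  cfg <- run_config(seed = 33, n_replicates = 10)
  km <- build_kmer_matrix(mix$contigs, cfg)
  lab <- truth_labels(mix, 120)
  v1 <- train_and_vote(km, lab, "superkingdom", "rf", cfg)
  v2 <- train_and_vote(km, lab, "superkingdom", "rf", cfg)
  expect_identical(v1$votes, v2$votes)
  expect_identical(v1$replicate_accuracy, v2$replicate_accuracy)
})

test_that("small classes are dropped and a single surviving class is an error", {
  mix <- fixture_separable()
  cfg <- run_config(seed = 2, n_replicates = 5)
  km <- build_kmer_matrix(mix$contigs, cfg)
  lab <- truth_labels(mix, 100)
  # shrink one class below min_class_size
  keep_b <- lab$contig_id[lab$label == "Bacteria"][1:5]
  lab2 <- lab[lab$label != "Bacteria" | lab$contig_id %in% keep_b, ]
  expect_warning(expect_error(
    train_and_vote(km, lab2, "superkingdom", "rf", cfg),
    "at least two classes"), "fewer than")
})

test_that("nested classification restricts the universe by the parent-rank target", {
  cyto <- genome_spec("cardinium", 3003L,
                      c(superkingdom = "Bacteria", phylum = "Bacteroidetes",
                        class = "Cytophagia"),
                      n_contigs = 60L, contig_meanlog = log(2000),
                      contig_sdlog = 0.25, min_contig = 1200L, gc = 0.36,
                      coverage_multiplier = 4)
  alpha <- genome_spec("wolbachia", 2002L,
                       c(superkingdom = "Bacteria", phylum = "Proteobacteria",
                         class = "Alphaproteobacteria"),
                       n_contigs = 60L, contig_meanlog = log(2000),
                       contig_sdlog = 0.25, min_contig = 1200L, gc = 0.28,
                       coverage_multiplier = 6, has_16s = TRUE)
  host <- genome_spec("nematode", 1001L,
                      c(superkingdom = "Eukaryota", phylum = "Nematoda",
                        class = "Chromadorea"),
                      n_contigs = 80L, contig_meanlog = log(2000),
                      contig_sdlog = 0.25, min_contig = 1200L, gc = 0.52)
  mix <- generate_mixture(mixture_spec(list(cyto, alpha, host),
                                       label_rate = 0.6, seed = 21))
  cfg <- run_config(seed = 21, n_replicates = 15,
                    rank_sequence = c("superkingdom", "class"),
                    target_rank_label = "Alphaproteobacteria")
  km <- build_kmer_matrix(mix$contigs, cfg)
  hits <- filter_hits(mix$hits, cfg)
  lab <- rbind(assign_taxonomy(hits, mix$lineage, "superkingdom", cfg),
               assign_taxonomy(hits, mix$lineage, "class", cfg))
  res <- nested_classify(km, lab, cfg, algo = "rf",
                         rank_targets = c(superkingdom = "Bacteria",
                                          class = "Alphaproteobacteria"))
  cls_rows <- res$labels[res$labels$rank == "class", ]
  truth_gen <- stats::setNames(mix$truth$genome, mix$truth$contig_id)
  # no eukaryote-truth contig enters the class-level prediction universe
  euk_pred <- cls_rows$contig_id[truth_gen[cls_rows$contig_id] == "nematode" &
                                   cls_rows$source == "predicted"]
  expect_length(euk_pred, 0)
  # class-level calls for the two bacteria are largely correct
  bac <- cls_rows[truth_gen[cls_rows$contig_id] != "nematode", ]
  truth_cl <- stats::setNames(mix$truth$class, mix$truth$contig_id)
  expect_gt(mean(bac$label == truth_cl[bac$contig_id]), 0.9)
})

test_that("homology labels are never overwritten by predictions", {
  mix <- fixture_separable()
  cfg <- run_config(seed = 3, n_replicates = 5)
  km <- build_kmer_matrix(mix$contigs, cfg)
  lab <- truth_labels(mix, 150)
  res <- nested_classify(km, lab, cfg, algo = "svm")
  hom <- res$labels[res$labels$source == "homology", names(lab)]
  expect_equal(hom[order(hom$contig_id), ]$label, lab[order(lab$contig_id), ]$label)
  pred <- res$labels[res$labels$source == "predicted", ]
  expect_length(intersect(pred$contig_id, lab$contig_id), 0)
})
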