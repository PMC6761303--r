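#' Canonical taxonomic ranks
#'
#' Ordered rank names recognised in lineage tables and per-rank label
#' tables, from coarsest to finest.
#'
#' @return Character vector of rank names.
#' @export
canonical_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Build a run configuration
#'
#' Collects every tunable of the deconvolution workflow with its default.
#' Thresholds are inclusive: "over 200 bp" is read as `>= 200`, "larger
#' than 0.75" as `>= 0.75`, and the contig length filter as
#' `length >= min_contig_len`.
#'
#' @param k k-mer length for the composition matrix (default 3).
#' @param min_contig_len minimum contig length (nt) entering the k-mer
#'   matrix and the classifiers (default 1000).
#' @param nt_min_hsp,nt_min_pident nucleotide homology filters: minimum
#'   HSP length in bp (default 200) and percent identity (default 70).
#' @param prot_min_hsp,prot_min_pident protein homology filters: minimum
#'   HSP length in aa (default 70) and percent identity (default 80).
#' @param taxon_density_min minimum TaxonDensity for a contig to keep its
#'   homology label (default 0.75).
#' @param edges_min minimum read-pair support for a graph edge (default 10).
#' @param vertices_max_degree maximum vertex degree kept after edge
#'   filtering; higher-degree vertices are dropped (default 5).
#' @param mixedcomp_max maximum fraction of labeled contigs in a connected
#'   component that may disagree with the majority label before the
#'   component is skipped (default 0.2).
#' @param vertexdist `"all"` (transfer to the whole component, gated by
#'   `mixedcomp_max`) or an integer hop distance for bounded transfer
#'   with the n-2 conflict truncation (default `"all"`).
#' @param n_replicates number of train/test replicates per classifier
#'   (default 100).
#' @param train_frac fraction of labeled contigs used for training in each
#'   replicate (default 0.66).
#' @param min_class_size classes with fewer labeled contigs are dropped
#'   before training (default 10).
#' @param rf_trees trees per random forest (default 500).
#' @param svm_kernel kernel for the support vector machine (default
#'   `"radial"`).
#' @param clustering_enabled run the final UMAP+DBSCAN step (flow A) when
#'   `TRUE`, otherwise stop after the classifier (flow B).
#' @param ncomp number of UMAP components (default 2).
#' @param feature_type features used downstream, a subset of
#'   `c("kmers", "gc", "cov")` (default `"kmers"`).
#' @param umap_n_neighbors,umap_min_dist UMAP hyperparameters.
#' @param dbscan_minpts DBSCAN core-point neighbourhood size (default 5).
#' @param dbscan_eps DBSCAN radius; `NULL` selects it from the knee of the
#'   sorted minPts-nearest-neighbour distance curve.
#' @param iterate_degree_filter iterate the vertex-degree filter to a
#'   fixed point instead of a single pass (default `FALSE`).
#' @param rank_sequence ordered ranks for nested classification, coarse to
#'   fine (default `"superkingdom"`).
#' @param target_rank rank at which the target label is defined; defaults
#'   to the last element of `rank_sequence`.
#' @param target_rank_label taxon label of the target organism at
#'   `target_rank` (e.g. `"Bacteria"` or `"Alphaproteobacteria"`).
#' @param seed integer seed governing all randomness of a run.
#'
#' @return An object of class `endobin_config` (a named list).
#' @export
run_config <- function(k = 3L,
                       min_contig_len = 1000L,
                       nt_min_hsp = 200L,
                       nt_min_pident = 70,
                       prot_min_hsp = 70L,
                       prot_min_pident = 80,
                       taxon_density_min = 0.75,
                       edges_min = 10L,
                       vertices_max_degree = 5L,
                       mixedcomp_max = 0.2,
                       vertexdist = "all",
                       n_replicates = 100L,
                       train_frac = 0.66,
                       min_class_size = 10L,
                       rf_trees = 500L,
                       svm_kernel = "radial",
                       clustering_enabled = TRUE,
                       ncomp = 2L,
                       feature_type = "kmers",
                       umap_n_neighbors = 15L,
                       umap_min_dist = 0.1,
                       dbscan_minpts = 5L,
                       dbscan_eps = NULL,
                       iterate_degree_filter = FALSE,
                       rank_sequence = "superkingdom",
                       target_rank = NULL,
                       target_rank_label = NULL,
                       seed = 1L) {
  cfg <- list(
    k = as.integer(k), min_contig_len = as.integer(min_contig_len),
    nt_min_hsp = as.integer(nt_min_hsp), nt_min_pident = nt_min_pident,
    prot_min_hsp = as.integer(prot_min_hsp), prot_min_pident = prot_min_pident,
    taxon_density_min = taxon_density_min,
    edges_min = as.integer(edges_min),
    vertices_max_degree = vertices_max_degree,
    mixedcomp_max = mixedcomp_max,
    vertexdist = vertexdist,
    n_replicates = as.integer(n_replicates),
    train_frac = train_frac,
    min_class_size = as.integer(min_class_size),
    rf_trees = as.integer(rf_trees),
    svm_kernel = svm_kernel,
    clustering_enabled = isTRUE(clustering_enabled),
    ncomp = as.integer(ncomp),
    feature_type = feature_type,
    umap_n_neighbors = as.integer(umap_n_neighbors),
    umap_min_dist = umap_min_dist,
    dbscan_minpts = as.integer(dbscan_minpts),
    dbscan_eps = dbscan_eps,
    iterate_degree_filter = isTRUE(iterate_degree_filter),
    rank_sequence = rank_sequence,
    target_rank = if (is.null(target_rank)) rank_sequence[length(rank_sequence)] else target_rank,
    target_rank_label = target_rank_label,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "endobin_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks range and consistency constraints; used by [run_config()] and
#' after programmatic modification of a config.
#'
#' @param cfg an `endobin_config` (or plain list with the same fields).
#' @return The config, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$k >= 2L, cfg$min_contig_len >= 1L)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1")
  if (cfg$taxon_density_min < 0 || cfg$taxon_density_min > 1)
    stop("taxon_density_min must lie in [0, 1]")
  if (cfg$mixedcomp_max < 0 || cfg$mixedcomp_max > 1)
    stop("mixedcomp_max must lie in [0, 1]")
  if (!identical(cfg$vertexdist, "all") &&
      !(is.numeric(cfg$vertexdist) && cfg$vertexdist >= 0))
    stop("vertexdist must be \"all\" or a nonnegative integer")
  if (length(cfg$feature_type) == 0)
    stop("feature_type must be nonempty")
  bad <- setdiff(cfg$feature_type, c("kmers", "gc", "cov"))
  if (length(bad))
    stop("unknown feature_type element(s): ", paste(bad, collapse = ", "))
  bad_rank <- setdiff(cfg$rank_sequence, canonical_ranks())
  if (length(bad_rank))
    stop("unknown rank(s) in rank_sequence: ", paste(bad_rank, collapse = ", "))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unset keys fall back to
#' the defaults. Unknown keys are a hard error so typos do not silently
#' revert a threshold to its default.
#'
#' @param path YAML file.
#' @return An `endobin_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.endobin_config <- function(x, ...) {
  cat("endobin run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "<auto>" else paste(v, collapse = ",")))
  }
  invisible(x)
}

# Derive a stage-specific seed from the run seed so stages can be rerun
# in isolation; kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483629) + 1L
}
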