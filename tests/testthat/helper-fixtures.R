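# Shared synthetic fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Default two-genome study mixture (host 1x, AT-rich bacterium 9x).
fixture_mixture <- function() {
  memo("mixture", function() generate_mixture(default_mixture_spec(seed = 42)))
}

# Two-class mixture for the ensemble classifier: 150 + 150 contigs, all
# passing the 1 kbp filter, divergent Markov compositions.
fixture_separable <- function() {
  memo("separable", function() {
    ga <- genome_spec("alpha", 2002L,
                      c(superkingdom = "Bacteria", phylum = "Proteobacteria",
                        class = "Alphaproteobacteria"),
                      n_contigs = 150L, contig_meanlog = log(2000),
                      contig_sdlog = 0.25, min_contig = 1200L, gc = 0.30,
                      coverage_multiplier = 9, has_16s = TRUE)
    gb <- genome_spec("fungus", 1001L,
                      c(superkingdom = "Eukaryota", phylum = "Ascomycota",
                        class = "Saccharomycetes"),
                      n_contigs = 150L, contig_meanlog = log(2000),
                      contig_sdlog = 0.25, min_contig = 1200L, gc = 0.55,
                      coverage_multiplier = 1)
    generate_mixture(mixture_spec(list(ga, gb), seed = 11))
  })
}

# Truth-derived labels at superkingdom for exactly n contigs of a mixture.
truth_labels <- function(mix, n, rank = "superkingdom", seed = 5) {
  set.seed(seed)
  pick <- sort(sample(mix$truth$contig_id, n))
  data.frame(contig_id = pick, rank = rank,
             label = mix$truth[[rank]][match(pick, mix$truth$contig_id)],
             taxon_density = 1, source = "homology", stringsAsFactors = FALSE)
}

# A hand-sized path graph a-b-c-... with unit-weight named edges.
path_graph <- function(ids) {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(ids) > 1) {
    e <- as.vector(rbind(ids[-length(ids)], ids[-1]))
    g <- igraph::add_edges(g, e, weight = 20)
  }
  g
}

label_row <- function(contig_id, label, rank = "superkingdom",
                      source = "homology") {
  data.frame(contig_id = contig_id, rank = rank, label = label,
             taxon_density = 1, source = source, stringsAsFactors = FALSE)
}
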