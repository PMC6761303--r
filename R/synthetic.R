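#' Describe one genome of a synthetic mixture
#'
#' Composition is an order-1 Markov chain over A/C/G/T. By default the
#' transition matrix is built so that every row places exactly `gc`
#' probability mass on G+C (hence the chain's GC content equals `gc`
#' exactly in expectation), while the split within G/C and within A/T is
#' jittered per genome, giving each genome a distinctive higher-order
#' k-mer signature beyond its GC content. A full 4x4 `transition` matrix
#' (rows = from A,C,G,T; columns = to A,C,G,T) may be supplied instead.
#'
#' @param name genome name (prefix of its contig ids).
#' @param taxid synthetic taxid used in homology hits.
#' @param lineage named character vector rank -> taxon label (ranks from
#'   [canonical_ranks()]).
#' @param n_contigs number of contigs to fragment the genome into.
#' @param contig_meanlog,contig_sdlog log-normal contig-length
#'   parameters (nt); lengths are floored at `min_contig`.
#' @param min_contig minimum contig length (default 200 nt).
#' @param gc target GC content.
#' @param coverage_multiplier relative sequencing depth of this genome.
#' @param has_16s whether one contig (the longest) carries a 16S gene.
#' @param transition optional 4x4 Markov transition matrix.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(name, taxid, lineage, n_contigs = 150,
                        contig_meanlog = log(1800), contig_sdlog = 0.6,
                        min_contig = 200, gc = 0.45,
                        coverage_multiplier = 1, has_16s = FALSE,
                        transition = NULL) {
  stopifnot(nzchar(name), coverage_multiplier > 0, n_contigs >= 2,
            gc > 0, gc < 1)
  bad <- setdiff(names(lineage), canonical_ranks())
  if (length(bad)) stop("unknown rank(s) in lineage: ", paste(bad, collapse = ", "))
  structure(list(name = name, taxid = as.integer(taxid), lineage = lineage,
                 n_contigs = as.integer(n_contigs),
                 contig_meanlog = contig_meanlog, contig_sdlog = contig_sdlog,
                 min_contig = as.integer(min_contig), gc = gc,
                 coverage_multiplier = coverage_multiplier,
                 has_16s = isTRUE(has_16s), transition = transition),
            class = "genome_spec")
}

#' Describe a synthetic host-symbiont mixture
#'
#' Global generation parameters around a list of [genome_spec()]s. The
#' defaults emulate the sequencing conditions the workflow is designed
#' for: fragments are drawn per genome at `frag_rate` fragments per
#' nucleotide per coverage unit; a fraction `single_rate` are merged
#' single-end fragments; consecutive contigs of a genome are bridged by
#' junction-spanning read pairs with probability `junction_rate`, with
#' Poisson(`junction_strength` x coverage multiplier) supporting pairs;
#' `cross_noise` is the probability that a junction pair is rerouted to a
#' contig of another genome (chimeric link). A fraction `label_rate` of
#' contigs receive homology hits, of which a fraction `label_error`
#' point to a decoy taxon; two below-threshold spike-in hits per genome
#' exercise the HSP/identity filter.
#'
#' @param genomes list of [genome_spec()].
#' @param cross_noise chimeric-link rate (default 0).
#' @param label_rate fraction of contigs with homology hits (default 0.3).
#' @param label_error per-hit wrong-taxon rate (default 0).
#' @param frag_rate fragments per nt per coverage unit (default 0.02).
#' @param single_rate merged single-end fraction (default 0.2).
#' @param junction_rate probability a contig junction is bridged
#'   (default 0.3).
#' @param junction_strength mean supporting pairs per bridged junction at
#'   coverage multiplier 1 (default 15).
#' @param seed integer seed; the whole mixture is reproducible from it.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(genomes, cross_noise = 0, label_rate = 0.3,
                         label_error = 0, frag_rate = 0.02,
                         single_rate = 0.2, junction_rate = 0.3,
                         junction_strength = 15, seed = 1L) {
  stopifnot(length(genomes) >= 1,
            all(vapply(genomes, inherits, logical(1), "genome_spec")))
  for (r in c(cross_noise, label_rate, label_error, single_rate, junction_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(genomes = genomes, cross_noise = cross_noise,
                 label_rate = label_rate, label_error = label_error,
                 frag_rate = frag_rate, single_rate = single_rate,
                 junction_rate = junction_rate,
                 junction_strength = junction_strength,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Default two-genome study mixture
#'
#' A eukaryote-like host and an AT-rich bacterial endosymbiont with
#' divergent composition (GC 0.45 vs 0.30), the bacterium at 9x the
#' host's coverage, 30% homology label rate and no chimeric links. The
#' bacterium's longest contig carries a 16S gene.
#'
#' @param seed seed passed to [mixture_spec()].
#' @return A `mixture_spec`.
#' @export
default_mixture_spec <- function(seed = 1L) {
  host <- genome_spec(
    name = "host", taxid = 1001L,
    lineage = c(superkingdom = "Eukaryota", phylum = "Ascomycota",
                class = "Saccharomycetes", order = "Saccharomycetales",
                family = "Saccharomycetaceae", genus = "Saccharomyces",
                species = "Saccharomyces cerevisiae"),
    n_contigs = 150L, contig_meanlog = log(2200), contig_sdlog = 0.6,
    gc = 0.45, coverage_multiplier = 1)
  symbiont <- genome_spec(
    name = "symbiont", taxid = 2002L,
    lineage = c(superkingdom = "Bacteria", phylum = "Proteobacteria",
                class = "Alphaproteobacteria", order = "Rickettsiales",
                family = "Midichloriaceae", genus = "Fokinia",
                species = "Fokinia solitaria"),
    n_contigs = 120L, contig_meanlog = log(1600), contig_sdlog = 0.6,
    gc = 0.30, coverage_multiplier = 9, has_16s = TRUE)
  mixture_spec(list(host, symbiont), seed = seed)
}

# Build a GC-exact jittered transition matrix for one genome.
build_transition <- function(gc) {
  rows <- t(vapply(1:4, function(i) {
    w_gc <- stats::runif(1, 0.3, 0.7)   # split of gc mass between C and G
    w_at <- stats::runif(1, 0.3, 0.7)   # split of (1-gc) mass between A and T
    c(A = (1 - gc) * w_at, C = gc * w_gc, G = gc * (1 - w_gc),
      T = (1 - gc) * (1 - w_at))
  }, numeric(4)))
  dimnames(rows) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  rows
}

# Sample n states from an order-1 chain given cumulative transition rows.
sim_chain <- function(n, cum) {
  u <- stats::runif(n)
  s <- integer(n)
  st <- sample.int(4L, 1L)
  for (i in seq_len(n)) {
    row <- cum[st, ]
    st <- 1L + (u[i] > row[1L]) + (u[i] > row[2L]) + (u[i] > row[3L])
    s[i] <- st
  }
  s
}

#' Generate a complete truth-annotated synthetic mixture
#'
#' Produces every input the deconvolution pipeline consumes: contigs,
#' per-fragment mate links, raw (unfiltered) homology hits including two
#' below-threshold spike-ins per genome, a lineage table (genome taxids
#' plus a decoy Archaea taxon used for wrong-taxon hits), 16S gene
#' records, and a truth map covering every contig. Contigs carrying a
#' 16S gene always receive homology hits (in the real workflow that
#' contig has an rRNA-database hit by construction). Byte-identical
#' output for identical seeds.
#'
#' @param spec a [mixture_spec()].
#' @return List with elements `contigs` ([Biostrings::DNAStringSet]),
#'   `links`, `hits`, `lineage`, `s16` (16S records with NA coverage, to
#'   be joined with a computed coverage table), `truth`
#'   (`data.frame(contig_id, genome, <rank columns>)`) and `spec`.
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  ranks <- canonical_ranks()
  decoy <- c(superkingdom = "Archaea", phylum = "Euryarchaeota",
             class = "Methanomicrobia", order = "Methanosarcinales",
             family = "Methanosarcinaceae", genus = "Methanosarcina",
             species = "Methanosarcina decoy")
  decoy_taxid <- 9009L

  seqs <- character(0); contig_genome <- character(0)
  links <- list(); hits <- list(); s16 <- list()
  frag_counter <- 0L
  all_by_genome <- list()

  for (g in spec$genomes) {
    lens <- pmax(g$min_contig, round(stats::rlnorm(g$n_contigs, g$contig_meanlog,
                                                   g$contig_sdlog)))
    ids <- sprintf("%s_c%03d", g$name, seq_len(g$n_contigs))
    trans <- if (is.null(g$transition)) build_transition(g$gc) else g$transition
    cum <- t(apply(trans, 1, cumsum))
    gseqs <- vapply(lens, function(n)
      intToUtf8(c(65L, 67L, 71L, 84L)[sim_chain(n, cum)]), character(1))
    names(gseqs) <- ids
    seqs <- c(seqs, gseqs)
    contig_genome <- c(contig_genome, stats::setNames(rep(g$name, length(ids)), ids))
    all_by_genome[[g$name]] <- ids

    # intra-contig fragments
    n_frag <- round(spec$frag_rate * g$coverage_multiplier * sum(lens))
    if (n_frag > 0) {
      on <- sample(ids, n_frag, replace = TRUE, prob = lens)
      single <- stats::runif(n_frag) < spec$single_rate
      links[[length(links) + 1L]] <- data.frame(
        fragment_id = sprintf("frag%07d", frag_counter + seq_len(n_frag)),
        contig_a = on,
        contig_b = ifelse(single, NA_character_, on),
        type = ifelse(single, "single", "paired"),
        stringsAsFactors = FALSE)
      frag_counter <- frag_counter + n_frag
    }

    # junction-spanning pairs between consecutive contigs
    for (i in seq_len(g$n_contigs - 1L)) {
      if (stats::runif(1) >= spec$junction_rate) next
      w <- max(1L, stats::rpois(1, spec$junction_strength * g$coverage_multiplier))
      b <- rep(ids[i + 1L], w)
      chim <- stats::runif(w) < spec$cross_noise
      if (any(chim)) {
        others <- setdiff(names(contig_genome), ids)
        if (length(others)) b[chim] <- sample(others, sum(chim), replace = TRUE)
        else chim[] <- FALSE
      }
      links[[length(links) + 1L]] <- data.frame(
        fragment_id = sprintf("frag%07d", frag_counter + seq_len(w)),
        contig_a = rep(ids[i], w), contig_b = b, type = "paired",
        stringsAsFactors = FALSE)
      frag_counter <- frag_counter + w
    }

    # homology hits
    s16_contig <- if (g$has_16s) ids[which.max(lens)] else NULL
    labeled <- ids[stats::runif(g$n_contigs) < spec$label_rate]
    labeled <- union(labeled, s16_contig)
    if (length(labeled)) {
      hit_rows <- lapply(labeled, function(cid) {
        nh <- 1L + stats::rpois(1, 3)
        wrong <- stats::runif(nh) < spec$label_error
        data.frame(query_id = cid, contig_id = cid,
                   taxid = ifelse(wrong, decoy_taxid, g$taxid),
                   pident = round(stats::runif(nh, 75, 100), 2),
                   hsp_len = round(stats::runif(nh, 250, 2000)),
                   source = "nucleotide", stringsAsFactors = FALSE)
      })
      hits[[length(hits) + 1L]] <- do.call(rbind, hit_rows)
    }
    # below-threshold spike-ins (must be removed by the hit filter)
    spike <- sample(ids, 2)
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = spike, contig_id = spike, taxid = g$taxid,
      pident = c(50, 85), hsp_len = c(500, 100), source = "nucleotide",
      stringsAsFactors = FALSE)

    if (g$has_16s) {
      li <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
      li[names(g$lineage)] <- g$lineage
      s16[[length(s16) + 1L]] <- data.frame(
        contig_id = s16_contig, start = 99L,
        end = min(lens[which.max(lens)], 1600L), strand = "+",
        as.list(li), coverage = NA_real_, stringsAsFactors = FALSE)
    }
  }

  contigs <- Biostrings::DNAStringSet(seqs)
  if (any(vapply(spec$genomes, function(g) g$n_contigs, integer(1)) < 2))
    stop("each genome needs at least 2 contigs")

  lineage <- do.call(rbind, c(
    lapply(spec$genomes, function(g) {
      li <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
      li[names(g$lineage)] <- g$lineage
      data.frame(taxid = g$taxid, as.list(li), stringsAsFactors = FALSE)
    }),
    list(data.frame(taxid = decoy_taxid, as.list(decoy), stringsAsFactors = FALSE))))

  truth <- do.call(rbind, lapply(spec$genomes, function(g) {
    li <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
    li[names(g$lineage)] <- g$lineage
    data.frame(contig_id = all_by_genome[[g$name]], genome = g$name,
               as.list(li), stringsAsFactors = FALSE)
  }))

  list(contigs = contigs,
       links = do.call(rbind, links),
       hits = do.call(rbind, hits),
       lineage = lineage,
       s16 = if (length(s16)) do.call(rbind, s16) else NULL,
       truth = truth,
       spec = spec)
}

#' Write a synthetic mixture in the pipeline's input file formats
#'
#' FASTA contigs, mate-TSV links, BLAST-outfmt-6-with-staxid nucleotide
#' hits, headered lineage TSV, GFF3 16S calls (1-based inclusive
#' coordinates, as GFF3 requires) and a truth TSV.
#'
#' @param mix a [generate_mixture()] result.
#' @param dir output directory (created).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_mixture <- function(mix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(contigs = file.path(dir, "contigs.fasta"),
             links = file.path(dir, "mate_links.tsv"),
             hits = file.path(dir, "hits_nt.tsv"),
             lineage = file.path(dir, "lineage.tsv"),
             gff = file.path(dir, "rrna_16s.gff3"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(mix$contigs, paths["contigs"])
  lk <- mix$links
  lk$contig_a[is.na(lk$contig_a)] <- "."
  lk$contig_b[is.na(lk$contig_b)] <- "."
  utils::write.table(lk, paths["links"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  h <- mix$hits
  blast <- data.frame(qseqid = h$query_id, sseqid = paste0("subj_", h$taxid),
                      pident = h$pident, length = h$hsp_len, mismatch = 0,
                      gapopen = 0, qstart = 1, qend = h$hsp_len, sstart = 1,
                      send = h$hsp_len, evalue = 1e-30, bitscore = 100,
                      staxid = h$taxid, stringsAsFactors = FALSE)
  utils::write.table(blast, paths["hits"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(mix$lineage, paths["lineage"])
  con <- file(paths["gff"], "w")
  writeLines("##gff-version 3", con)
  if (!is.null(mix$s16))
    for (i in seq_len(nrow(mix$s16)))
      writeLines(paste(mix$s16$contig_id[i], "synthetic", "rRNA",
                       mix$s16$start[i] + 1L, mix$s16$end[i], ".",
                       mix$s16$strand[i], ".",
                       "Name=16S_rRNA;product=16S ribosomal RNA",
                       sep = "\t"), con)
  close(con)
  write_tsv(mix$truth, paths["truth"])
  invisible(paths)
}
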