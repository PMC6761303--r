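#' Assign per-contig taxonomy labels by TaxonDensity consensus
#'
#' Pools each contig's (already threshold-filtered) nucleotide and
#' protein hits, maps every hit's taxid to its taxon label at `rank`
#' (hits whose lineage lacks that rank drop out of the pool), and
#' computes TaxonDensity(label) = hits carrying that label / pooled
#' hits. The most frequent label is kept iff its density reaches
#' `taxon_density_min` (inclusive) and is the unique maximum; ties or a
#' low density leave the contig unlabeled, which removes contigs with
#' incongruent taxonomic signals.
#'
#' @param hits hit table ([read_hits()] / [filter_hits()]).
#' @param lineage lineage table ([read_lineage()]).
#' @param rank rank at which to label, one of [canonical_ranks()].
#' @param cfg an [run_config()] supplying `taxon_density_min`.
#' @return A label table: `data.frame(contig_id, rank, label,
#'   taxon_density, source)` with `source = "homology"`; contigs that end
#'   up unlabeled are simply absent.
#' @export
assign_taxonomy <- function(hits, lineage, rank, cfg = run_config()) {
  if (!rank %in% canonical_ranks()) stop("unknown rank: ", rank)
  if (!rank %in% names(lineage))
    stop("lineage table has no '", rank, "' column")
  idx <- match(hits$taxid, lineage$taxid)
  n_unknown <- sum(is.na(idx))
  if (n_unknown > 0)
    warning(n_unknown, " hit(s) with taxid absent from the lineage table dropped")
  lab <- lineage[[rank]][idx]
  keep <- !is.na(idx) & !is.na(lab)
  if (!any(keep)) return(empty_labels())
  df <- data.frame(contig_id = hits$contig_id[keep], label = lab[keep],
                   stringsAsFactors = FALSE)
  res <- lapply(split(df$label, df$contig_id), function(ls) {
    tab <- sort(table(ls), decreasing = TRUE)
    dens <- as.numeric(tab[1]) / length(ls)
    tied <- sum(tab == tab[1]) > 1
    if (!tied && dens >= cfg$taxon_density_min)
      data.frame(label = names(tab)[1], taxon_density = dens,
                 stringsAsFactors = FALSE)
    else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_labels())
  out <- data.frame(contig_id = names(res),
                    rank = rank,
                    label = vapply(res, `[[`, character(1), "label"),
                    taxon_density = vapply(res, `[[`, numeric(1), "taxon_density"),
                    source = "homology", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_labels <- function() {
  data.frame(contig_id = character(), rank = character(), label = character(),
             taxon_density = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' Per-contig TaxonDensity spectrum
#'
#' Densities of every candidate label for one contig's pooled hits at a
#' rank; they sum to 1 when every pooled hit resolves at that rank.
#' Mostly a diagnostic companion to [assign_taxonomy()].
#'
#' @inheritParams assign_taxonomy
#' @param contig_id contig to inspect.
#' @return Named numeric vector of densities (may be empty).
#' @export
taxon_density <- function(hits, lineage, rank, contig_id) {
  h <- hits[hits$contig_id == contig_id, , drop = FALSE]
  idx <- match(h$taxid, lineage$taxid)
  lab <- lineage[[rank]][idx]
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(lab)
  stats::setNames(as.numeric(tab) / length(lab), names(tab))
}

#' Attach taxon labels and coverage to 16S gene calls
#'
#' Joins GFF-derived 16S gene coordinates with per-gene taxonomy (e.g.
#' from a BLAST comparison to an rRNA database, resolved through the
#' lineage table) and the contig coverage table.
#'
#' @param gff `data.frame(contig_id, start, end, strand)` from
#'   [read_16s_gff()] (0-based half-open coordinates).
#' @param taxids named integer vector: contig id of a 16S-carrying contig
#'   -> taxid of its best rRNA-database hit.
#' @param lineage lineage table.
#' @param coverage coverage table from [compute_coverage()].
#' @return `data.frame(contig_id, start, end, strand, <rank columns>,
#'   coverage)` -- one row per 16S gene call with a resolvable taxid.
#' @export
sixteen_s_records <- function(gff, taxids, lineage, coverage) {
  idx <- match(gff$contig_id, names(taxids))
  keep <- !is.na(idx)
  g <- gff[keep, , drop = FALSE]
  li <- lineage[match(taxids[idx[keep]], lineage$taxid), , drop = FALSE]
  ranks <- intersect(canonical_ranks(), names(lineage))
  out <- cbind(g, li[, ranks, drop = FALSE])
  out$coverage <- coverage$coverage[match(out$contig_id, coverage$contig_id)]
  rownames(out) <- NULL
  out
}

#' Pick the target 16S contig
#'
#' Among 16S records whose taxon at `rank` equals `target_label`, returns
#' the contig with the highest coverage (the endosymbiont is expected at
#' much higher copy number than contaminant bacteria). Ties are broken
#' deterministically by contig-id sort order, with a warning.
#'
#' @param records 16S record table ([sixteen_s_records()] or the
#'   generator's equivalent): needs `contig_id`, `coverage` and a column
#'   named `rank`.
#' @param target_label taxon label of the target organism.
#' @param rank rank at which `target_label` is defined.
#' @return The selected contig id (length-1 character).
#' @export
identify_16s_targets <- function(records, target_label, rank) {
  if (!rank %in% names(records))
    stop("16S records carry no '", rank, "' column")
  hit <- records[!is.na(records[[rank]]) & records[[rank]] == target_label, , drop = FALSE]
  if (nrow(hit) == 0) {
    found <- sort(unique(stats::na.omit(records[[rank]])))
    stop("no 16S gene labeled '", target_label, "' at rank ", rank,
         "; labels found: ", paste(found, collapse = ", "))
  }
  best <- hit[hit$coverage == max(hit$coverage), , drop = FALSE]
  if (nrow(best) > 1) {
    warning("coverage tie among target 16S contigs; keeping the lexicographically first")
    best <- best[order(best$contig_id), , drop = FALSE]
  }
  best$contig_id[1]
}
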