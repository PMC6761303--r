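#' Per-contig coverage in fragments per nucleotide
#'
#' Each sequenced fragment contributes one count: a same-contig pair or a
#' merged single-end read gives 1 to its contig; a pair whose mates map
#' on two different contigs gives half a count to each; a pair with one
#' unmapped mate gives 1 to the mapped contig. Coverage is the fragment
#' count divided by contig length, so total fragment count over all
#' contigs equals the number of fragments with at least one placed mate.
#'
#' @param links mate-link table from [read_mate_links()] or
#'   [generate_mixture()].
#' @param contigs named [Biostrings::DNAStringSet]; every contig named in
#'   `links` must be present.
#' @return `data.frame(contig_id, length, fragment_count, coverage)` with
#'   one row per contig (zero-fragment contigs included), sorted by
#'   contig id.
#' @export
compute_coverage <- function(links, contigs) {
  ids <- names(contigs)
  named <- stats::na.omit(c(links$contig_a, links$contig_b))
  missing <- setdiff(unique(named), ids)
  if (length(missing))
    stop("contig(s) named in mate links but absent from the assembly: ",
         paste(utils::head(missing, 5), collapse = ", "))
  counts <- stats::setNames(numeric(length(ids)), ids)
  a <- links$contig_a
  b <- links$contig_b
  same <- !is.na(a) & (is.na(b) | a == b)         # single-end, one-mate, same-contig pair
  cross <- !is.na(a) & !is.na(b) & a != b
  only_b <- is.na(a) & !is.na(b)
  t1 <- table(a[same])
  counts[names(t1)] <- counts[names(t1)] + as.numeric(t1)
  t2 <- table(b[only_b])
  counts[names(t2)] <- counts[names(t2)] + as.numeric(t2)
  ta <- table(a[cross]); tb <- table(b[cross])
  counts[names(ta)] <- counts[names(ta)] + 0.5 * as.numeric(ta)
  counts[names(tb)] <- counts[names(tb)] + 0.5 * as.numeric(tb)
  len <- stats::setNames(Biostrings::width(contigs), ids)
  out <- data.frame(contig_id = ids, length = as.integer(len),
                    fragment_count = as.numeric(counts),
                    coverage = as.numeric(counts) / as.numeric(len),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
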