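#' Size of the raw k-mer space
#'
#' Number of distinct DNA words of length `k` before collapsing
#' reverse-complement pairs: `4^k` (1,024 for 5-mers).
#'
#' @param k word length.
#' @return Integer-valued numeric, `4^k`.
#' @export
kmer_space_size <- function(k) {
  stopifnot(k >= 1)
  4^k
}

#' Canonical k-mers
#'
#' The canonical representative of a k-mer is the lexicographic minimum
#' of the k-mer and its reverse complement; collapsing to canonical form
#' makes composition strand-independent. For odd `k` there are no
#' reverse-complement palindromes and the space halves exactly; for even
#' `k` the `p` palindromes stay, giving `(4^k - p)/2 + p` canonical
#' words.
#'
#' @param k word length (>= 1).
#' @return Lexicographically sorted character vector of canonical k-mers.
#' @export
canonical_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer")
  all_k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- revcomp(all_k)
  sort(unique(pmin(all_k, rc)))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mer frequencies of one sequence
#'
#' Slides over the forward strand, skips windows containing N, maps each
#' window to its canonical form and normalises by the number of counted
#' windows. Counting on both strands and combining complementary k-mers
#' (palindromes included) is exactly proportional to this forward-strand
#' canonical count, so the two are interchangeable; the equivalence is
#' exercised in the test suite against an explicit both-strand counter.
#'
#' @param seq DNA string.
#' @param k word length.
#' @return Named numeric vector over [canonical_kmers()]; if the sequence
#'   has no countable window (too short, or all windows contain N) the
#'   vector is all zero with attribute `flagged = TRUE`.
#' @export
kmer_frequencies <- function(seq, k) {
  canon <- canonical_kmers(k)
  out <- stats::setNames(numeric(length(canon)), canon)
  if (nchar(seq) < k) {
    attr(out, "flagged") <- TRUE
    return(out)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
  total <- sum(counts)
  if (total == 0) {
    attr(out, "flagged") <- TRUE
    return(out)
  }
  canon_of <- pmin(names(counts), revcomp(names(counts)))
  collapsed <- tapply(counts, canon_of, sum)
  out[names(collapsed)] <- collapsed / total
  attr(out, "flagged") <- FALSE
  out
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N is excluded from the denominator.
#'
#' @param seq DNA string (nonempty).
#' @return Fraction in `[0, 1]`, or `NA` for a sequence with no
#'   unambiguous base.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  s <- Biostrings::DNAString(seq)
  acgt <- sum(Biostrings::letterFrequency(s, c("A", "C", "G", "T")))
  if (acgt == 0) return(NA_real_)
  unname(Biostrings::letterFrequency(s, "GC")) / acgt
}

#' Canonical k-mer matrix of an assembly
#'
#' One row per contig passing the length filter (`length >=
#' min_contig_len`, inclusive), in sorted contig-id order; one column per
#' canonical k-mer, plus GC content carried alongside.
#'
#' @param contigs named [Biostrings::DNAStringSet] from [read_contigs()].
#' @param cfg an [run_config()] supplying `k` and `min_contig_len`.
#' @return An object of class `kmer_matrix`: list with `kmers` (numeric
#'   matrix, rownames = contig ids), `gc` (named vector), `flagged`
#'   (named logical, TRUE where a contig had no countable window) and
#'   `k`.
#' @export
build_kmer_matrix <- function(contigs, cfg = run_config()) {
  keep <- Biostrings::width(contigs) >= cfg$min_contig_len
  if (!any(keep))
    stop("no contig passes the length filter (min_contig_len = ",
         cfg$min_contig_len, "); lower it or check the assembly")
  ids <- sort(names(contigs)[keep])
  canon <- canonical_kmers(cfg$k)
  seqs <- as.character(contigs[ids])
  mat <- matrix(0, nrow = length(ids), ncol = length(canon),
                dimnames = list(ids, canon))
  flagged <- stats::setNames(logical(length(ids)), ids)
  gc <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    f <- kmer_frequencies(seqs[i], cfg$k)
    mat[i, ] <- f
    flagged[i] <- isTRUE(attr(f, "flagged"))
    gc[i] <- gc_content(seqs[i])
  }
  structure(list(kmers = mat, gc = gc, flagged = flagged, k = cfg$k),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("kmer_matrix: %d contigs x %d canonical %d-mers (%d flagged)\n",
              nrow(x$kmers), ncol(x$kmers), x$k, sum(x$flagged)))
  invisible(x)
}

#' Write the composition/coverage table to the Coverage/ folder layout
#'
#' Columns: contig_id, length, gc, fragment_count, coverage, then one
#' column per canonical k-mer.
#'
#' @param km a [build_kmer_matrix()] result.
#' @param cov a [compute_coverage()] table.
#' @param dir output directory (a `Coverage` subfolder is created).
#' @return Path of the written TSV, invisibly.
#' @export
write_composition <- function(km, cov, dir) {
  ids <- rownames(km$kmers)
  covi <- cov[match(ids, cov$contig_id), ]
  out <- data.frame(contig_id = ids, length = covi$length, gc = km$gc[ids],
                    fragment_count = covi$fragment_count,
                    coverage = covi$coverage, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(km$kmers))
  write_tsv(out, file.path(dir, "Coverage", "composition_coverage.tsv"))
}
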