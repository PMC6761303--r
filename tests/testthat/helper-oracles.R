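# Independent oracles, deliberately naive, used to cross-check the
# implementation.

# Count k-mers explicitly on BOTH strands (skipping windows with N),
# then combine each reverse-complement pair into the canonical column.
oracle_kmer_freq_bothstrands <- function(seq, k) {
  count_strand <- function(s) {
    n <- nchar(s)
    words <- if (n < k) character(0) else
      substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    words[!grepl("N", words, fixed = TRUE)]
  }
  words <- c(count_strand(seq), count_strand(endobin::revcomp(seq)))
  canon <- endobin::canonical_kmers(k)
  out <- stats::setNames(numeric(length(canon)), canon)
  if (!length(words)) return(out)
  cw <- pmin(words, endobin::revcomp(words))
  tab <- table(cw)
  out[names(tab)] <- as.numeric(tab) / length(words)
  out
}

# Tally coverage one fragment at a time.
oracle_coverage <- function(links, lens) {
  counts <- stats::setNames(numeric(length(lens)), names(lens))
  for (i in seq_len(nrow(links))) {
    a <- links$contig_a[i]; b <- links$contig_b[i]
    if (is.na(a) && is.na(b)) next
    if (is.na(a)) { counts[b] <- counts[b] + 1; next }
    if (is.na(b) || a == b) { counts[a] <- counts[a] + 1; next }
    counts[a] <- counts[a] + 0.5
    counts[b] <- counts[b] + 0.5
  }
  counts
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else NULL
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

random_mate_table <- function(n_frag, contig_ids, p_single = 0.2, p_unmapped = 0.1) {
  a <- sample(contig_ids, n_frag, replace = TRUE)
  b <- sample(contig_ids, n_frag, replace = TRUE)
  type <- ifelse(stats::runif(n_frag) < p_single, "single", "paired")
  b[type == "single"] <- NA
  drop_b <- type == "paired" & stats::runif(n_frag) < p_unmapped
  b[drop_b] <- NA
  data.frame(fragment_id = sprintf("r%05d", seq_len(n_frag)),
             contig_a = a, contig_b = b, type = type,
             stringsAsFactors = FALSE)
}
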