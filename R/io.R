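#' Read assembly contigs from FASTA
#'
#' Contig ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased and any character outside {A,C,G,T,N} is
#' replaced by N (with a warning giving the substitution count).
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id; this is the
#'   contig-set container used throughout the package (the assembly
#'   universe A).
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty id")
  if (anyDuplicated(ids))
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  n_bad <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN character(s) replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read and filter BLAST-style tabular homology hits
#'
#' Expects outfmt-6-style columns `qseqid sseqid pident length ... staxid`
#' (subject taxid in the last column; the standard 12 columns plus
#' `staxid` work as-is). Rows failing the source-appropriate identity and
#' HSP-length thresholds (inclusive) are dropped. For `source =
#' "protein"` the query id is a gene-caller id `<contig>_<n>` and is
#' mapped back to its contig.
#'
#' @param path tabular hits file (no header).
#' @param source `"nucleotide"` or `"protein"`.
#' @param cfg an [run_config()] object supplying the thresholds.
#' @param contigs optional contig set; hits to unknown contigs are then
#'   rejected with a warning count.
#' @return A hit table: `data.frame(query_id, contig_id, taxid, pident,
#'   hsp_len, source)`.
#' @export
read_hits <- function(path, source = c("nucleotide", "protein"), cfg = run_config(),
                      contigs = NULL) {
  source <- match.arg(source)
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("unparsable hits file ", path, ": ", conditionMessage(e)))
  if (ncol(tab) < 5)
    stop("hits file must have >= 5 tab-separated columns (qseqid sseqid pident length ... staxid)")
  pident <- suppressWarnings(as.numeric(tab[[3]]))
  hsp <- suppressWarnings(as.numeric(tab[[4]]))
  taxid <- suppressWarnings(as.integer(tab[[ncol(tab)]]))
  bad <- which(is.na(pident) | is.na(hsp) | is.na(taxid))
  if (length(bad))
    stop("unparsable hit row(s) at line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  hits <- data.frame(query_id = as.character(tab[[1]]),
                     contig_id = as.character(tab[[1]]),
                     taxid = taxid, pident = pident, hsp_len = hsp,
                     source = source, stringsAsFactors = FALSE)
  if (source == "protein")
    hits$contig_id <- sub("_[^_]*$", "", hits$query_id)
  hits <- filter_hits(hits, cfg)
  if (!is.null(contigs)) {
    unknown <- !(hits$contig_id %in% names(contigs))
    if (any(unknown)) {
      warning(sum(unknown), " hit row(s) to contigs absent from the assembly rejected")
      hits <- hits[!unknown, , drop = FALSE]
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Apply the identity / HSP-length thresholds to a hit table
#'
#' Inclusive comparisons; idempotent. Exposed separately so
#' programmatically built hit tables go through the same filter as ones
#' read from disk.
#'
#' @param hits a hit table as returned by [read_hits()].
#' @param cfg an [run_config()].
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, cfg = run_config()) {
  stopifnot(all(c("contig_id", "taxid", "pident", "hsp_len", "source") %in% names(hits)))
  min_pid <- ifelse(hits$source == "protein", cfg$prot_min_pident, cfg$nt_min_pident)
  min_len <- ifelse(hits$source == "protein", cfg$prot_min_hsp, cfg$nt_min_hsp)
  keep <- hits$pident >= min_pid & hits$hsp_len >= min_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read per-fragment mate mappings
#'
#' Accepts either the mate-TSV dialect (one row per sequenced fragment,
#' columns `read_id contig_a contig_b type`, with `.` for an unplaced
#' mate and `type` in `{paired, single}`) or SAM/BAM, from which the
#' identical table is derived: secondary (0x100) and supplementary
#' (0x800) alignments are ignored, fragments are grouped by read name,
#' and unmapped mates become `.`.
#'
#' @param path TSV, SAM or BAM file (format inferred from the extension:
#'   `.sam`/`.bam` vs anything else).
#' @return A mate-link table: `data.frame(fragment_id, contig_a,
#'   contig_b, type)` with `NA` for unplaced mates.
#' @export
read_mate_links <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) read_mate_links_sam(path, ext) else read_mate_links_tsv(path)
}

read_mate_links_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fragment_id", "contig_a", "contig_b", "type"))
  if (!all(tab$type %in% c("paired", "single")))
    stop("mate-TSV type column must be 'paired' or 'single'")
  tab$contig_a[tab$contig_a == "."] <- NA_character_
  tab$contig_b[tab$contig_b == "."] <- NA_character_
  if (anyDuplicated(tab$fragment_id))
    stop("duplicate fragment id(s) in mate table")
  if (any(tab$type == "single" & !is.na(tab$contig_b)))
    stop("single-end fragments must not name a second contig")
  tab
}

read_mate_links_sam <- function(path, ext) {
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"), flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  qname <- b$qname
  flag <- b$flag
  rname <- as.character(b$rname)
  rname[bitwAnd(flag, 4L) != 0L] <- NA_character_  # unmapped
  paired <- bitwAnd(flag, 1L) != 0L
  first <- bitwAnd(flag, 64L) != 0L
  out <- lapply(split(seq_along(qname), qname), function(i) {
    if (any(paired[i])) {
      a <- rname[i][first[i]][1]
      b2 <- rname[i][!first[i]][1]
      if (is.na(a) && !is.na(b2)) { a <- b2; b2 <- NA_character_ }
      data.frame(fragment_id = qname[i][1], contig_a = a, contig_b = b2,
                 type = "paired", stringsAsFactors = FALSE)
    } else {
      data.frame(fragment_id = qname[i][1], contig_a = rname[i][1],
                 contig_b = NA_character_, type = "single",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  res <- res[order(res$fragment_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a taxid-to-lineage table
#'
#' A headered TSV with a `taxid` column followed by rank columns drawn
#' from [canonical_ranks()]. Empty strings are treated as missing ranks.
#'
#' @param path TSV file.
#' @return `data.frame` with integer `taxid` and one character column per
#'   rank present in the file.
#' @export
read_lineage <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"taxid" %in% names(tab)) stop("lineage table needs a 'taxid' column")
  bad <- setdiff(setdiff(names(tab), "taxid"), canonical_ranks())
  if (length(bad))
    stop("unknown rank column(s) in lineage table: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$taxid)) stop("duplicate taxid(s) in lineage table")
  tab$taxid <- as.integer(tab$taxid)
  for (r in setdiff(names(tab), "taxid"))
    tab[[r]][!is.na(tab[[r]]) & tab[[r]] == ""] <- NA_character_
  tab
}

#' Read 16S rRNA gene calls from GFF3
#'
#' Keeps rRNA features whose attributes mention 16S. Input coordinates
#' are 1-based inclusive (GFF3); they are converted to 0-based half-open
#' `start`/`end` internally, as everywhere in this package.
#'
#' @param path GFF3 file.
#' @return `data.frame(contig_id, start, end, strand)`.
#' @export
read_16s_gff <- function(path) {
  g <- rtracklayer::import(path)
  md <- as.data.frame(S4Vectors::mcols(g))
  txt <- if (ncol(md)) apply(md, 1, function(r) paste(r, collapse = " ")) else character(length(g))
  g <- g[grepl("16S", txt, ignore.case = TRUE)]
  data.frame(contig_id = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write a data frame as a headered TSV
#'
#' Canonical writer used for every tabular output so that reading a table
#' back reproduces it row-for-row.
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
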