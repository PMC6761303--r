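#' Binning performance against truth labels
#'
#' Confusion partition of the evaluated universe (every contig with a
#' truth label): TP = predicted target and truly target, FP = predicted
#' but other, FN = missed target, TN = correctly left out. Rates are
#' reported twice from the same partition: weighting each contig equally
#' (counts) and weighting by contig length in nucleotides, since
#' misclassifying a long contig is a worse error than misclassifying a
#' short one. Division-by-zero rates are `NA`, not 0.
#'
#' @param predicted_target character vector of contig ids called target.
#' @param truth named character vector contig id -> `"target"`/`"other"`
#'   covering the evaluated universe.
#' @param lengths named numeric vector contig id -> length in nt.
#' @return Object of class `performance_report`: list of two blocks
#'   (`counts`, `lengths`), each with tp/fp/tn/fn and sensitivity,
#'   precision, accuracy, f1.
#' @export
score_binning <- function(predicted_target, truth, lengths) {
  univ <- names(truth)
  missing <- setdiff(predicted_target, univ)
  if (length(missing))
    stop("predicted contig(s) missing from truth: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!all(univ %in% names(lengths)))
    stop("lengths missing for some evaluated contigs")
  pred <- univ %in% predicted_target
  is_t <- truth[univ] == "target"
  cells <- list(tp = pred & is_t, fp = pred & !is_t,
                fn = !pred & is_t, tn = !pred & !is_t)
  block <- function(w) {
    conf <- vapply(cells, function(idx) sum(w[idx]), numeric(1))
    rate <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- rate(conf["tp"], conf["tp"] + conf["fn"])
    prec <- rate(conf["tp"], conf["tp"] + conf["fp"])
    f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    c(lapply(as.list(conf), unname),
      list(sensitivity = unname(sens), precision = unname(prec),
           accuracy = unname(rate(conf["tp"] + conf["tn"], sum(conf))),
           f1 = unname(f1)))
  }
  w_len <- as.numeric(lengths[univ])
  structure(list(counts = block(rep(1, length(univ))), lengths = block(w_len)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(b) sprintf(
    "TP=%g FP=%g TN=%g FN=%g | sens=%.4f prec=%.4f acc=%.4f F1=%.4f",
    b$tp, b$fp, b$tn, b$fn, b$sensitivity, b$precision, b$accuracy, b$f1)
  cat("performance (contig counts):      ", fmt(x$counts), "\n")
  cat("performance (nucleotide lengths): ", fmt(x$lengths), "\n")
  invisible(x)
}

#' Flatten a performance report to a one-row-per-block data frame
#'
#' @param report a [score_binning()] result.
#' @return `data.frame` with a `weighting` column (`counts`/`lengths`).
#' @export
performance_table <- function(report) {
  rows <- lapply(c("counts", "lengths"), function(nm) {
    b <- report[[nm]]
    data.frame(weighting = nm, tp = b$tp, fp = b$fp, tn = b$tn, fn = b$fn,
               sensitivity = b$sensitivity, precision = b$precision,
               accuracy = b$accuracy, f1 = b$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
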