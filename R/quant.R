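# Relative quantification of qPCR data by the 2^-ddCt method, with
# deregulation calling against mean +/- 3 SD cutoffs fit on normal controls.

#' Relative expression by the 2^-ddCt method
#'
#' Computes ddCt = (Ct_target - Ct_reference)_sample -
#' (Ct_target - Ct_reference)_calibrator and the fold change 2^-ddCt.
#' Amplification efficiency is assumed to be exactly 2 (no efficiency
#' correction). All arguments are vectorized and recycled.
#'
#' @param ct_target_sample,ct_ref_sample Ct of the target and reference
#'   assay in the sample of interest (cycles).
#' @param ct_target_calibrator,ct_ref_calibrator Ct of the same assays in
#'   the calibrator (normal control); replicate Cts should be averaged
#'   beforehand (arithmetic mean).
#' @return data.frame with columns `delta_delta_ct` and `fold_change`.
#' @examples
#' ddct(25, 20, 27, 20)  # ddCt = -2, fold = 4
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  vals <- cbind(ct_target_sample, ct_ref_sample,
                ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(vals))) stop("all four Ct terms must be finite")
  dd <- (vals[, 1L] - vals[, 2L]) - (vals[, 3L] - vals[, 4L])
  data.frame(delta_delta_ct = dd, fold_change = 2^(-dd))
}

#' Relative expression for a long-format Ct table
#'
#' Aggregates replicate Cts (arithmetic mean), normalizes each target assay
#' to the reference assay within each sample (dCt), and calibrates against
#' the mean dCt of the calibrator samples, yielding one fold change per
#' (sample, target assay). With several calibrator samples their dCt values
#' are averaged before differencing.
#'
#' @param ct data.frame with columns `sample_id`, `assay_id`, `ct`;
#'   replicate wells are extra rows.
#' @param reference_assay Name of the endogenous reference assay
#'   (e.g. `"U6B"`, `"HPRT"`).
#' @param calibrator_samples Character vector of control sample ids used as
#'   the calibrator.
#' @param qc_sd Replicate-Ct standard deviation above which a measurement
#'   is flagged (never rejected); default 0.5 cycles.
#' @return data.frame: `sample_id`, `assay_id`, `delta_delta_ct`,
#'   `fold_change`, `reference_assay`, `calibrator`, `qc_flag`.
#' @export
relative_expression <- function(ct, reference_assay, calibrator_samples,
                                qc_sd = 0.5) {
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% names(ct))) {
    stop("'ct' needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0) || any(ct$ct >= 50)) {
    stop("Ct values must be finite and in (0, 50)")
  }
  if (!any(ct$assay_id == reference_assay)) {
    stop("reference assay '", reference_assay, "' absent from table")
  }
  if (!all(calibrator_samples %in% ct$sample_id)) {
    stop("calibrator sample(s) absent from table")
  }
  agg <- stats::aggregate(ct["ct"],
                          ct[c("sample_id", "assay_id")],
                          function(v) c(m = mean(v), s = stats::sd(v)))
  agg <- data.frame(agg[c("sample_id", "assay_id")],
                    ct = agg$ct[, "m"],
                    rep_sd = ifelse(is.na(agg$ct[, "s"]), 0, agg$ct[, "s"]))
  ref <- agg[agg$assay_id == reference_assay, ]
  tgt <- agg[agg$assay_id != reference_assay, ]
  idx <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(idx)) stop("sample(s) missing a reference-assay measurement")
  tgt$dct <- tgt$ct - ref$ct[idx]
  cal <- tgt[tgt$sample_id %in% calibrator_samples, ]
  cal_dct <- tapply(cal$dct, cal$assay_id, mean)
  if (!all(unique(tgt$assay_id) %in% names(cal_dct))) {
    stop("assay(s) not measured in any calibrator sample")
  }
  dd <- tgt$dct - as.numeric(cal_dct[tgt$assay_id])
  out <- data.frame(
    sample_id = tgt$sample_id,
    assay_id = tgt$assay_id,
    delta_delta_ct = dd,
    fold_change = 2^(-dd),
    reference_assay = reference_assay,
    calibrator = paste(calibrator_samples, collapse = ","),
    qc_flag = tgt$rep_sd > qc_sd
  )
  rownames(out) <- NULL
  out[order(out$assay_id, out$sample_id), ]
}

#' Deregulation cutoffs from normal controls
#'
#' Fits the mean and (n-1)-denominator standard deviation of an assay's
#' expression values in normal controls and derives the two-sided 3-SD
#' deregulation boundaries: `low_cut = mean - 3*SD` (clipped at 0) and
#' `high_cut = mean + 3*SD`.
#'
#' @param normal_values Numeric vector of expression values (fold changes)
#'   in >= 2 normal controls; all positive.
#' @param assay_id Optional assay label carried in the result.
#' @return Object of class `"dereg_cutoff"`: list with `assay_id`,
#'   `mean_normal`, `sd_normal`, `low_cut`, `high_cut`, `n_normals`.
#' @examples
#' compute_cutoffs(c(0.8, 1, 1.2))  # cuts (0.4, 1.6)
#' @export
compute_cutoffs <- function(normal_values, assay_id = NA_character_) {
  normal_values <- normal_values[!is.na(normal_values)]
  if (length(normal_values) < 2L) {
    stop("need >= 2 normal-control values (SD undefined otherwise)")
  }
  if (any(!is.finite(normal_values)) || any(normal_values <= 0)) {
    stop("normal-control expression values must be finite and positive")
  }
  m <- mean(normal_values)
  s <- stats::sd(normal_values)
  structure(list(assay_id = assay_id, mean_normal = m, sd_normal = s,
                 low_cut = max(0, m - 3 * s), high_cut = m + 3 * s,
                 n_normals = length(normal_values)),
            class = "dereg_cutoff")
}

#' @export
print.dereg_cutoff <- function(x, ...) {
  cat(sprintf(
    "Deregulation cutoff%s: mean %.4g, SD %.4g (n = %d normals)\n",
    if (is.na(x$assay_id)) "" else paste0(" [", x$assay_id, "]"),
    x$mean_normal, x$sd_normal, x$n_normals))
  cat(sprintf("  down if value < %.4g; up if value > %.4g\n",
              x$low_cut, x$high_cut))
  invisible(x)
}

#' Call expression deregulation against 3-SD cutoffs
#'
#' A value strictly below `low_cut` is called `"down"`, strictly above
#' `high_cut` `"up"`, otherwise `"normal"` (boundary values are normal).
#' `NA` values yield `NA` calls.
#'
#' @param value Numeric vector of expression values (>= 0).
#' @param cutoff A `"dereg_cutoff"` from [compute_cutoffs()].
#' @return Character vector of calls in `{"down", "normal", "up"}`.
#' @export
call_deregulation <- function(value, cutoff) {
  if (!inherits(cutoff, "dereg_cutoff")) {
    stop("'cutoff' must come from compute_cutoffs()")
  }
  if (any(value < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- "normal"
  out[ok & value < cutoff$low_cut] <- "down"
  out[ok & value > cutoff$high_cut] <- "up"
  out
}

#' Genomic copy-number ratio by qPCR
#'
#' The same ddCt arithmetic as [ddct()] applied to a genomic target locus
#' against a diploid reference locus (e.g. NF1 vs RAG2), calibrated on
#' normal DNA. A diploid sample gives a ratio near 1, a hemizygous
#' deletion near 0.5; the locus is called deleted when the ratio falls
#' below `deletion_threshold`.
#'
#' @param ct_locus_sample,ct_ref_sample,ct_locus_calibrator,ct_ref_calibrator
#'   Ct values (cycles), vectorized.
#' @param deletion_threshold Ratio below which the locus is called deleted.
#'   Default 0.75, the midpoint between diploid (1.0) and hemizygous (0.5);
#'   this threshold is a package choice, not a community standard, and
#'   should be reviewed for each assay.
#' @return data.frame with `delta_delta_ct`, `ratio`, `deleted`.
#' @export
cn_qpcr <- function(ct_locus_sample, ct_ref_sample,
                    ct_locus_calibrator, ct_ref_calibrator,
                    deletion_threshold = 0.75) {
  dd <- ddct(ct_locus_sample, ct_ref_sample,
             ct_locus_calibrator, ct_ref_calibrator)
  data.frame(delta_delta_ct = dd$delta_delta_ct,
             ratio = dd$fold_change,
             deleted = dd$fold_change < deletion_threshold)
}
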