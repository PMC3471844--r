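# Patient-level analysis: prevalence of NF1 downregulation, miR-370
# overexpression and NF1 locus deletion; their cross-association; and
# per-patient attribution of the downregulation mechanism.

#' Prevalence of a binary call with a Wilson interval
#'
#' @param x Logical vector (or a character vector of deregulation calls
#'   together with `positive`, the level counted as positive). `NA` values
#'   are excluded from the denominator, mirroring per-assay missingness.
#' @param positive Level counted as positive when `x` is character.
#' @param conf_level Confidence level of the Wilson score interval
#'   (default 0.95).
#' @return list with `count`, `n`, `proportion`, `conf_low`, `conf_high`.
#' @examples
#' prevalence(c(rep(TRUE, 21), rep(FALSE, 47)))  # 21/68 = 0.308
#' @export
prevalence <- function(x, positive = "down", conf_level = 0.95) {
  if (is.character(x) || is.factor(x)) x <- as.character(x) == positive
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("no non-missing observations")
  k <- sum(x)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(count = k, n = n, proportion = p,
       conf_low = max(0, center - half), conf_high = min(1, center + half))
}

#' Association between two binary aberrations
#'
#' Cross-tabulates two paired binary calls (pairs with any missing value
#' are excluded), computes the odds ratio (with a Haldane 0.5 correction
#' when any cell is zero) and a two-sided Fisher exact p-value.
#'
#' @param call_a,call_b Logical vectors of equal length.
#' @return list with `table` (2x2 matrix, rows = `call_a` TRUE/FALSE,
#'   columns = `call_b` TRUE/FALSE), `odds_ratio` (NA with
#'   `degenerate = TRUE` when a margin is empty), `p_value`, `n`.
#' @export
crosstab_association <- function(call_a, call_b) {
  if (length(call_a) != length(call_b)) stop("paired vectors required")
  ok <- !is.na(call_a) & !is.na(call_b)
  a <- call_a[ok]
  b <- call_b[ok]
  if (!length(a)) stop("no complete pairs")
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(a = c("TRUE", "FALSE"),
                                b = c("TRUE", "FALSE")))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                n = length(a), degenerate = TRUE))
  }
  ct <- if (any(tab == 0L)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p, n = length(a),
       degenerate = FALSE)
}

#' Attribute the mechanism of NF1 downregulation per patient
#'
#' Restricted to patients called expression-down, assigns each to exactly
#' one category: `both` (locus deleted and miR-370 up), `deletion_only`,
#' `mir370_only`, or `unknown` (neither aberration). Patients missing the
#' deletion or miR-370 measurement go to a separate `unevaluable` bucket,
#' never silently dropped; categories plus that bucket always sum to the
#' number of down-called patients.
#'
#' @param patients data.frame with columns `patient_id`, `nf1_call`
#'   (`"down"`/`"normal"`/`"up"`, NA allowed), `mir370_call` (same coding)
#'   and `nf1_deleted` (logical, NA allowed).
#' @return list with `patients` (the down-called subset plus a `mechanism`
#'   column), `counts` (named integer vector over `deletion_only`,
#'   `mir370_only`, `both`, `unknown`, `unevaluable`) and `n_down`.
#' @export
attribute_mechanism <- function(patients) {
  need <- c("patient_id", "nf1_call", "mir370_call", "nf1_deleted")
  if (!all(need %in% names(patients))) {
    stop("'patients' needs columns: ", paste(need, collapse = ", "))
  }
  down <- patients[!is.na(patients$nf1_call) &
                     patients$nf1_call == "down", , drop = FALSE]
  del <- down$nf1_deleted
  up <- down$mir370_call == "up"
  mech <- rep("unknown", nrow(down))
  mech[is.na(del) | is.na(up)] <- "unevaluable"
  ok <- !(is.na(del) | is.na(up))
  mech[ok & del & up] <- "both"
  mech[ok & del & !up] <- "deletion_only"
  mech[ok & !del & up] <- "mir370_only"
  down$mechanism <- mech
  cats <- c("deletion_only", "mir370_only", "both", "unknown", "unevaluable")
  counts <- stats::setNames(
    vapply(cats, function(k) sum(mech == k), integer(1)), cats)
  list(patients = down, counts = counts, n_down = nrow(down))
}

#' Full patient-cohort analysis
#'
#' Fits 3-SD deregulation cutoffs for NF1 and miR-370 expression on the
#' normal controls, calls every patient, calls NF1 locus deletion from the
#' genomic qPCR ratio, and reports prevalences (with pairwise-complete
#' denominators), the miR-370/NF1-down cross-association, and the
#' mechanism attribution of the down-called patients.
#'
#' @param patients data.frame with columns `patient_id`, `nf1_fold`,
#'   `mir370_fold`, `nf1_cn_ratio` (NA where an assay was not done).
#' @param normals data.frame with columns `nf1_fold`, `mir370_fold`
#'   measured in normal controls (>= 2 rows).
#' @param deletion_threshold CN ratio below which the locus is called
#'   deleted (default 0.75; see [cn_qpcr()]).
#' @return list of class `"cohort_analysis"`: `patients` (with call
#'   columns), `cutoffs` (per assay), `prev_nf1_down`, `prev_mir370_up`,
#'   `prev_nf1_del` (each a [prevalence()] result), `association`
#'   (miR-370 up vs NF1 down, from [crosstab_association()]), and
#'   `mechanism` (from [attribute_mechanism()]).
#' @export
cohort_analysis <- function(patients, normals, deletion_threshold = 0.75) {
  need <- c("patient_id", "nf1_fold", "mir370_fold", "nf1_cn_ratio")
  if (!all(need %in% names(patients))) {
    stop("'patients' needs columns: ", paste(need, collapse = ", "))
  }
  cut_nf1 <- compute_cutoffs(normals$nf1_fold, "NF1")
  cut_mir <- compute_cutoffs(normals$mir370_fold, "miR-370")
  patients$nf1_call <- call_deregulation(patients$nf1_fold, cut_nf1)
  patients$mir370_call <- call_deregulation(patients$mir370_fold, cut_mir)
  patients$nf1_deleted <- ifelse(is.na(patients$nf1_cn_ratio), NA,
                                 patients$nf1_cn_ratio < deletion_threshold)
  res <- list(
    patients = patients,
    cutoffs = list(nf1 = cut_nf1, mir370 = cut_mir),
    prev_nf1_down = prevalence(patients$nf1_call, "down"),
    prev_mir370_up = prevalence(patients$mir370_call, "up"),
    prev_nf1_del = prevalence(patients$nf1_deleted),
    association = crosstab_association(patients$mir370_call == "up",
                                       patients$nf1_call == "down"),
    mechanism = attribute_mechanism(patients)
  )
  class(res) <- "cohort_analysis"
  res
}

#' @export
print.cohort_analysis <- function(x, ...) {
  fmt <- function(p, what) {
    cat(sprintf("  %-22s %d/%d (%.1f%%, 95%% CI %.1f-%.1f%%)\n", what,
                p$count, p$n, 100 * p$proportion, 100 * p$conf_low,
                100 * p$conf_high))
  }
  cat("Cohort analysis of", nrow(x$patients), "patients\n")
  fmt(x$prev_nf1_down, "NF1 downregulated:")
  fmt(x$prev_mir370_up, "miR-370 overexpressed:")
  fmt(x$prev_nf1_del, "NF1 locus deleted:")
  cat(sprintf("  miR-370 up vs NF1 down: OR %.3g, Fisher p = %.3g\n",
              x$association$odds_ratio, x$association$p_value))
  cm <- x$mechanism$counts
  cat(sprintf(
    "  mechanism of %d down-called: %d deletion only, %d miR-370 only, %d both, %d unknown, %d unevaluable\n",
    x$mechanism$n_down, cm["deletion_only"], cm["mir370_only"], cm["both"],
    cm["unknown"], cm["unevaluable"]))
  invisible(x)
}
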