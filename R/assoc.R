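# Per-miRNA association of expression with locus copy-number state:
# the integrative step crossing segmented CNV calls with the qPCR panel.

#' Split samples into altered and neutral groups for one miRNA
#'
#' For the amplification analysis the altered group holds samples whose
#' locus is amplified (CN > 3) and the comparison group those with a
#' neutral locus; deleted samples are excluded from that analysis (and
#' vice versa for the deletion analysis). Samples flagged `no_data` are
#' always excluded.
#'
#' @param calls data.frame of locus CN calls for one miRNA (`sample_id`,
#'   `cn`, `state`, optional `no_data`), one row per sample.
#' @param class `"amplification"` or `"deletion"`.
#' @return list with `altered` and `neutral` (character vectors of sample
#'   ids) and `class`.
#' @export
label_samples <- function(calls, class = c("amplification", "deletion")) {
  class <- match.arg(class)
  if (anyDuplicated(calls$sample_id)) {
    stop("one call per sample expected")
  }
  no_data <- if (is.null(calls$no_data)) rep(FALSE, nrow(calls)) else
    calls$no_data
  calls <- calls[!no_data, , drop = FALSE]
  altered <- if (class == "amplification") {
    calls$state == "amplification"
  } else {
    calls$state %in% c("hemizygous_deletion", "homozygous_deletion",
                       "deletion_unclassified")
  }
  neutral <- calls$state == "neutral"
  list(altered = calls$sample_id[altered],
       neutral = calls$sample_id[neutral],
       class = class)
}

#' Two-sample t-test of expression between CN groups
#'
#' Compares (log-scale) expression of copy-number-altered samples against
#' copy-number-neutral samples with a two-sample t-test, Welch by default
#' or pooled-variance (`var_equal = TRUE`) for the classic test.
#' Degenerate zero-variance inputs are resolved explicitly: equal group
#' means give t = 0, p = 1; unequal means give p = 0 with
#' `degenerate = TRUE`.
#'
#' @param expr_altered,expr_neutral Numeric vectors (>= 2 values each),
#'   typically log2 fold changes.
#' @param var_equal Logical; pooled-variance test when TRUE (default FALSE,
#'   Welch).
#' @return list with `t_statistic`, `df`, `p_value`, `mean_altered`,
#'   `mean_neutral`, `n_altered`, `n_neutral`, `degenerate`.
#' @export
mirna_cnv_ttest <- function(expr_altered, expr_neutral, var_equal = FALSE) {
  if (length(expr_altered) < 2L || length(expr_neutral) < 2L) {
    stop("insufficient group size: need >= 2 values per group")
  }
  m1 <- mean(expr_altered)
  m2 <- mean(expr_neutral)
  if (stats::var(expr_altered) == 0 && stats::var(expr_neutral) == 0) {
    if (m1 == m2) {
      return(list(t_statistic = 0, df = NA_real_, p_value = 1,
                  mean_altered = m1, mean_neutral = m2,
                  n_altered = length(expr_altered),
                  n_neutral = length(expr_neutral), degenerate = TRUE))
    }
    return(list(t_statistic = sign(m1 - m2) * Inf, df = NA_real_,
                p_value = 0, mean_altered = m1, mean_neutral = m2,
                n_altered = length(expr_altered),
                n_neutral = length(expr_neutral), degenerate = TRUE))
  }
  tt <- stats::t.test(expr_altered, expr_neutral, var.equal = var_equal)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_altered = m1, mean_neutral = m2,
       n_altered = length(expr_altered), n_neutral = length(expr_neutral),
       degenerate = FALSE)
}

#' Screen all miRNAs for copy-number-driven expression
#'
#' For every miRNA with both an expression measurement and a locus CN
#' call, tests whether expression differs between altered and neutral
#' samples (one analysis per alteration class present), flags direction
#' consistency (amplified loci should be expressed higher, deleted loci
#' lower), and marks results significant when the raw p-value is below
#' `alpha` *and* the direction is consistent — the dosage-effect rule.
#' Benjamini-Hochberg adjusted p-values are reported alongside but do not
#' drive the significance flag.
#'
#' @param calls Locus CN calls as from [assign_locus_cn()] (`sample_id`,
#'   `mirna_id`, `cn`, `state`, `no_data`).
#' @param expr Expression table with columns `sample_id`, `mirna_id` and
#'   `fold_change` (linear scale) or `log2_expr`.
#' @param alpha Raw p-value threshold (default 0.05).
#' @param test `"welch"` (default) or `"pooled"`.
#' @param adjust Multiple-testing method for the reported `p_adjusted`
#'   column (default `"BH"`; `"none"` to skip).
#' @param min_group Minimum samples per group to run a test (default 2).
#' @return data.frame with one row per (miRNA, alteration class) analysis:
#'   `mirna_id`, `alteration_class`, `n_altered`, `n_neutral`,
#'   `mean_altered`, `mean_neutral` (log2 scale), `t_statistic`,
#'   `p_value`, `direction_consistent`, `significant`, `p_adjusted`,
#'   `tested`, `reason` (why an analysis was skipped). Untested analyses
#'   are retained with `tested = FALSE`, never dropped silently.
#' @export
cnv_expression_screen <- function(calls, expr, alpha = 0.05,
                                  test = c("welch", "pooled"),
                                  adjust = c("BH", "none"),
                                  min_group = 2L) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (is.null(expr$log2_expr)) {
    if (is.null(expr$fold_change)) {
      stop("'expr' needs a fold_change or log2_expr column")
    }
    if (any(expr$fold_change <= 0)) stop("fold changes must be positive")
    expr$log2_expr <- log2(expr$fold_change)
  }
  expr_split <- split(expr[c("sample_id", "log2_expr")], expr$mirna_id)
  calls_split <- split(calls, calls$mirna_id)
  rows <- list()
  for (mid in names(calls_split)) {
    ex <- expr_split[[mid]]
    if (is.null(ex)) next
    cl <- calls_split[[mid]]
    lv <- stats::setNames(ex$log2_expr, ex$sample_id)
    for (class in c("amplification", "deletion")) {
      grp <- label_samples(cl, class)
      xa <- lv[grp$altered[grp$altered %in% names(lv)]]
      xn <- lv[grp$neutral[grp$neutral %in% names(lv)]]
      if (!length(xa)) next   # class absent: no analysis for it
      base <- list(mirna_id = mid, alteration_class = class,
                   n_altered = length(xa), n_neutral = length(xn))
      if (length(xa) < min_group || length(xn) < min_group) {
        rows[[length(rows) + 1L]] <- c(base, list(
          mean_altered = if (length(xa)) mean(xa) else NA_real_,
          mean_neutral = if (length(xn)) mean(xn) else NA_real_,
          t_statistic = NA_real_, p_value = NA_real_,
          direction_consistent = NA, significant = FALSE,
          tested = FALSE, reason = "insufficient group size"))
        next
      }
      tt <- mirna_cnv_ttest(xa, xn, var_equal = test == "pooled")
      consistent <- if (class == "amplification") {
        tt$mean_altered > tt$mean_neutral
      } else {
        tt$mean_altered < tt$mean_neutral
      }
      rows[[length(rows) + 1L]] <- c(base, list(
        mean_altered = tt$mean_altered, mean_neutral = tt$mean_neutral,
        t_statistic = tt$t_statistic, p_value = tt$p_value,
        direction_consistent = consistent,
        significant = tt$p_value < alpha && consistent,
        tested = TRUE,
        reason = if (tt$degenerate) "degenerate variance" else ""))
    }
  }
  if (!length(rows)) {
    stop("no miRNA had both a CN call and an expression measurement")
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$p_adjusted <- NA_real_
  if (adjust == "BH") {
    out$p_adjusted[out$tested] <- adjust_pvalues(out$p_value[out$tested])
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment preserving input order
#'
#' Thin wrapper over [stats::p.adjust()] kept as an explicit pipeline step;
#' adjusted values are monotone (>= raw) and returned in input order.
#'
#' @param p Numeric vector of raw p-values.
#' @param method Adjustment method (default `"BH"`).
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (!length(p)) stop("need >= 1 p-value")
  stats::p.adjust(p, method = method)
}
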