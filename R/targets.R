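# Moderated-t differential expression (empirical-Bayes variance shrinkage
# with a log-odds B statistic) and nomination of miRNA targets whose
# expression change is anti-correlated with the miRNA's.

# Invert trigamma by Newton iteration (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# Method-of-moments estimate of the prior degrees of freedom d0 from the
# spread of log sample variances: var(log s^2) ~ trigamma(d/2) + trigamma(d0/2).
.estimate_prior_df <- function(s2, df) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2L) return(Inf)
  excess <- stats::var(log(s2)) - trigamma(df / 2)
  if (excess <= 0) return(Inf)
  2 * .trigamma_inverse(excess)
}

#' Moderated two-group differential expression
#'
#' Per-gene two-group contrast on a log2 expression matrix with
#' empirical-Bayes variance moderation: the posterior gene variance is
#' `(prior_df * s0^2 + df * s^2) / (prior_df + df)` where `s0^2` is the
#' mean of the gene-wise pooled variances and `df` the residual degrees of
#' freedom; the moderated t uses `prior_df + df` degrees of freedom. A
#' log-odds B statistic is derived from the moderated t under a
#' two-component mixture in which a proportion `prior_prop` of genes are
#' differentially expressed with prior effect standard deviation
#' `effect_sd` (log2 units); B > 0 means the odds favor differential
#' expression. Genes are selected by B > 0, by p < `p_cut`, or by either
#' rule (the default).
#'
#' With `prior_df = 0` the procedure reduces exactly to the ordinary
#' gene-wise pooled t-test; with `prior_df = Inf` all genes share the
#' common variance `s0^2`.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns, log2 scale.
#' @param groups Two-level factor (or coercible) over the columns. The
#'   reported `log2_fc` is mean(level 2) - mean(level 1).
#' @param prior_df Prior degrees of freedom for variance shrinkage;
#'   `"auto"` (default) estimates it from the spread of the gene-wise log
#'   variances, falling back to `Inf` when variances are homogeneous.
#' @param prior_prop Prior proportion of differentially expressed genes
#'   (default 0.01).
#' @param effect_sd Prior SD of true log2 fold changes under differential
#'   expression (default 1).
#' @param p_cut p-value route threshold (default 0.001).
#' @param rule Selection rule: `"either"` (default), `"b"` (B > 0 only) or
#'   `"p"` (p < `p_cut` only).
#' @return data.frame: `gene_id`, `log2_fc`, `t_statistic`, `df_total`,
#'   `p_value`, `b_statistic`, `selected`, ordered as the input rows.
#' @export
moderated_diff_expr <- function(expr, groups, prior_df = "auto",
                                prior_prop = 0.01, effect_sd = 1,
                                p_cut = 0.001,
                                rule = c("either", "b", "p")) {
  rule <- match.arg(rule)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(expr)) {
    stop("'groups' length must match the number of columns")
  }
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  x1 <- expr[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- expr[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- ss / df
  s02 <- mean(s2)
  if (identical(prior_df, "auto")) prior_df <- .estimate_prior_df(s2, df)
  if (!is.numeric(prior_df) || length(prior_df) != 1L || prior_df < 0) {
    stop("'prior_df' must be \"auto\" or a single number >= 0")
  }
  if (is.infinite(prior_df)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (prior_df * s02 + df * s2) / (prior_df + df)
    df_total <- rep(prior_df + df, length(s2))
  }
  cfac <- 1 / n1 + 1 / n2
  fc <- m2 - m1
  se <- sqrt(s2_post * cfac)
  tstat <- ifelse(se > 0, fc / se,
                  ifelse(fc == 0, 0, sign(fc) * Inf))
  pval <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df_total),
                 ifelse(tstat == 0, 1, 0))
  pval[tstat == 0] <- 1
  # Two-component log odds: under DE, t is inflated by the prior effect
  # variance relative to the sampling variance of the contrast.
  k <- sqrt(1 + effect_sd^2 / (s2_post * cfac))
  k[!is.finite(k)] <- Inf
  t_b <- ifelse(is.finite(tstat), tstat, sign(tstat) * 1e6)
  logf1 <- ifelse(is.finite(k),
                  stats::dt(t_b / k, df_total, log = TRUE) - log(k),
                  -Inf)
  logf0 <- stats::dt(t_b, df_total, log = TRUE)
  b <- log(prior_prop / (1 - prior_prop)) + logf1 - logf0
  b[is.infinite(tstat)] <- Inf  # unbounded evidence
  selected <- switch(rule,
                     either = (b > 0) | (pval < p_cut),
                     b = b > 0,
                     p = pval < p_cut)
  gene_id <- rownames(expr)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(expr)))
  data.frame(gene_id = gene_id, log2_fc = fc, t_statistic = tstat,
             df_total = df_total, p_value = pval, b_statistic = b,
             selected = selected, row.names = NULL)
}

#' Collapse probeset-level results to genes
#'
#' Keeps, for each gene, the probeset with the largest absolute moderated
#' t-statistic.
#'
#' @param results data.frame from [moderated_diff_expr()] whose `gene_id`
#'   column holds probeset ids.
#' @param gene_map data.frame with columns `probeset_id`, `gene_id`.
#' @return data.frame in the same shape, one row per gene.
#' @export
collapse_probesets <- function(results, gene_map) {
  if (!all(c("probeset_id", "gene_id") %in% names(gene_map))) {
    stop("'gene_map' needs columns probeset_id, gene_id")
  }
  idx <- match(results$gene_id, gene_map$probeset_id)
  keep <- !is.na(idx)
  res <- results[keep, , drop = FALSE]
  res$gene_id <- gene_map$gene_id[idx[keep]]
  res <- res[order(-abs(res$t_statistic)), ]
  res <- res[!duplicated(res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Nominate coherent miRNA targets
#'
#' Intersects predicted miRNA-target pairs with differential-expression
#' results: a pair is a candidate when the gene is predicted for the miRNA
#' in at least `min_sources` databases, the gene is selected as
#' differentially expressed, and the directions are opposite (miRNA up and
#' gene down, or vice versa). Candidates are ranked by the number of
#' supporting databases, then by absolute gene t-statistic.
#'
#' @param mirna_calls data.frame with columns `mirna_id` and `direction`
#'   (`"up"`/`"down"`).
#' @param predictions data.frame with columns `mirna_id`, `gene_id`,
#'   `source` (database label).
#' @param diffexpr data.frame from [moderated_diff_expr()].
#' @param min_sources Minimum supporting databases (default 1).
#' @return data.frame: `mirna_id`, `gene_id`, `mirna_direction`,
#'   `gene_direction`, `n_sources`, `t_statistic`, `coherent` (all TRUE in
#'   the returned set). Zero rows (with a warning) when nothing overlaps.
#' @export
coherent_targets <- function(mirna_calls, predictions, diffexpr,
                             min_sources = 1L) {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      mirna_direction = character(),
                      gene_direction = character(),
                      n_sources = integer(), t_statistic = numeric(),
                      coherent = logical())
  if (!all(c("mirna_id", "direction") %in% names(mirna_calls))) {
    stop("'mirna_calls' needs columns mirna_id, direction")
  }
  if (!all(c("mirna_id", "gene_id", "source") %in% names(predictions))) {
    stop("'predictions' needs columns mirna_id, gene_id, source")
  }
  pred <- unique(predictions[c("mirna_id", "gene_id", "source")])
  agg <- stats::aggregate(list(n_sources = pred$source),
                          pred[c("mirna_id", "gene_id")],
                          function(s) length(unique(s)))
  agg$mirna_direction <-
    mirna_calls$direction[match(agg$mirna_id, mirna_calls$mirna_id)]
  di <- match(agg$gene_id, diffexpr$gene_id)
  agg$gene_selected <- diffexpr$selected[di]
  agg$gene_direction <- ifelse(diffexpr$log2_fc[di] > 0, "up", "down")
  agg$t_statistic <- diffexpr$t_statistic[di]
  keep <- !is.na(agg$mirna_direction) & !is.na(di) &
    agg$gene_selected & agg$n_sources >= min_sources &
    agg$mirna_direction != agg$gene_direction
  out <- agg[keep, c("mirna_id", "gene_id", "mirna_direction",
                     "gene_direction", "n_sources", "t_statistic")]
  if (!nrow(out)) {
    warning("no coherent targets: predictions and expression do not overlap")
    return(empty)
  }
  out$coherent <- TRUE
  out <- out[order(-out$n_sources, -abs(out$t_statistic)), ]
  rownames(out) <- NULL
  out
}
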