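sim_matrix <- function(seed, n_genes = 300, n_per_group = 6, n_de = 20,
                       lfc = 1, sd = 0.5) {
  set.seed(seed)
  groups <- rep(c("A", "B"), each = n_per_group)
  x <- matrix(rnorm(n_genes * 2 * n_per_group, 7, sd), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes), NULL))
  x[seq_len(n_de), groups == "B"] <- x[seq_len(n_de), groups == "B"] + lfc
  list(x = x, groups = groups, de = rownames(x)[seq_len(n_de)])
}

test_that("with prior_df = 0 the moderated t is the ordinary pooled t", {
  s <- sim_matrix(1)
  res <- moderated_diff_expr(s$x, s$groups, prior_df = 0)
  ref_t <- apply(s$x, 1, function(v) {
    unname(t.test(v[s$groups == "B"], v[s$groups == "A"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(res$t_statistic, unname(ref_t), tolerance = 1e-9)
  expect_equal(res$df_total, rep(10, nrow(s$x)))
})

test_that("with prior_df = Inf all genes share the common variance", {
  s <- sim_matrix(2)
  res <- moderated_diff_expr(s$x, s$groups, prior_df = Inf)
  s2 <- apply(s$x, 1, function(v) {
    (sum((v[s$groups == "A"] - mean(v[s$groups == "A"]))^2) +
       sum((v[s$groups == "B"] - mean(v[s$groups == "B"]))^2)) / 10
  })
  shared_se <- sqrt(mean(s2) * (2 / 6))
  expect_equal(res$t_statistic, unname(res$log2_fc / shared_se),
               tolerance = 1e-9)
})

test_that("moderated t tracks limma on simulated data", {
  skip_if_not_installed("limma")
  s <- sim_matrix(3)
  res <- moderated_diff_expr(s$x, s$groups)
  design <- cbind(1, as.integer(s$groups == "B"))
  fit <- limma::eBayes(limma::lmFit(s$x, design))
  expect_gt(cor(res$t_statistic, fit$t[, 2], method = "spearman"), 0.99)
  expect_equal(res$log2_fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-9)
})

test_that("planted two-fold changes are recovered at the p < 0.001 route", {
  s <- sim_matrix(4, n_genes = 1000, n_per_group = 8, n_de = 50, lfc = 1)
  res <- moderated_diff_expr(s$x, s$groups, rule = "p")
  recovered <- mean(res$selected[match(s$de, res$gene_id)])
  # large-n oracle: per-gene z = 1 / (0.5 * sqrt(2/8)) = 4, so power at
  # the two-sided 0.001 level is P(|Z + 4| > 3.29) = 0.761; allow 3
  # binomial SEs around it (n = 50 planted genes)
  power_oracle <- pnorm(4 - qnorm(1 - 0.001 / 2))
  expect_lt(abs(recovered - power_oracle),
            3 * sqrt(power_oracle * (1 - power_oracle) / 50))
  fp <- mean(res$selected[!res$gene_id %in% s$de])
  expect_lt(fp, 0.01)
  # B statistic is a monotone transform of |t| within constant-variance sets
  r0 <- moderated_diff_expr(s$x, s$groups, prior_df = Inf, rule = "b")
  o <- order(abs(r0$t_statistic))
  expect_true(all(diff(r0$b_statistic[o]) >= -1e-12))
})

test_that("selection by p is monotone in the threshold", {
  s <- sim_matrix(5)
  loose <- moderated_diff_expr(s$x, s$groups, rule = "p", p_cut = 0.01)
  tight <- moderated_diff_expr(s$x, s$groups, rule = "p", p_cut = 0.001)
  expect_true(all(which(tight$selected) %in% which(loose$selected)))
})

test_that("a constant matrix yields no differential expression", {
  x <- matrix(5, 20, 8, dimnames = list(sprintf("G%02d", 1:20), NULL))
  res <- moderated_diff_expr(x, rep(c("A", "B"), each = 4))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$selected))
})

test_that("probeset collapsing keeps the strongest probeset per gene", {
  res <- data.frame(gene_id = c("p1", "p2", "p3"),
                    log2_fc = c(1, -2, 0.1),
                    t_statistic = c(2, -5, 0.3),
                    df_total = 10, p_value = c(0.05, 0.001, 0.8),
                    b_statistic = c(-1, 2, -5),
                    selected = c(FALSE, TRUE, FALSE))
  map <- data.frame(probeset_id = c("p1", "p2", "p3"),
                    gene_id = c("NF1", "NF1", "OTHER"))
  col <- collapse_probesets(res, map)
  expect_equal(nrow(col), 2L)
  expect_equal(col$t_statistic[col$gene_id == "NF1"], -5)
})

test_that("coherent targets require prediction, selection and opposition", {
  mirna_calls <- data.frame(mirna_id = c("miR-370", "miR-99"),
                            direction = c("up", "up"))
  predictions <- data.frame(
    mirna_id = c("miR-370", "miR-370", "miR-370", "miR-99", "miR-370"),
    gene_id = c("NF1", "NF1", "UPGENE", "NF1", "GHOST"),
    source = c("dbA", "dbB", "dbA", "dbA", "dbA"))
  diffexpr <- data.frame(
    gene_id = c("NF1", "UPGENE"),
    log2_fc = c(-1.2, 1.5), t_statistic = c(-6, 5),
    df_total = 10, p_value = c(1e-5, 1e-4), b_statistic = c(3, 2),
    selected = c(TRUE, TRUE))
  ct <- coherent_targets(mirna_calls, predictions, diffexpr)
  # miR-370 up + NF1 predicted (2 sources) + NF1 selected down -> coherent
  expect_true(any(ct$mirna_id == "miR-370" & ct$gene_id == "NF1"))
  expect_equal(ct$n_sources[ct$mirna_id == "miR-370" &
                              ct$gene_id == "NF1"], 2L)
  # gene moving the same way as the miRNA is excluded
  expect_false("UPGENE" %in% ct$gene_id)
  # predictions absent from the expression results are excluded
  expect_false("GHOST" %in% ct$gene_id)
  # output pairs are a subset of the prediction list
  expect_true(all(paste(ct$mirna_id, ct$gene_id) %in%
                    paste(predictions$mirna_id, predictions$gene_id)))
  # idempotent under re-run
  expect_identical(ct, coherent_targets(mirna_calls, predictions, diffexpr))
  # min_sources filter: emptied result comes with a warning
  expect_warning(
    empty <- coherent_targets(mirna_calls, predictions, diffexpr,
                              min_sources = 3),
    "no coherent targets")
  expect_equal(nrow(empty), 0L)
})

test_that("the cell-line pipeline surfaces the planted repressed targets", {
  # low-noise array so the 4-vs-12 contrast is well powered: this checks
  # the join/direction/selection machinery, not screen power
  cfg <- simulation_config(seed = 17, mrna_noise_sd = 0.2)
  d <- gen_cell_line_data(cfg, what = c("mrna", "predictions"))
  # contrast lines carrying the large amplified cluster vs the rest
  amp <- strsplit(d$truth$loci$lines[d$truth$loci$cluster == "amp_14q32"][1],
                  ",")[[1]]
  groups <- ifelse(colnames(d$expr_matrix) %in% amp, "amp", "neutral")
  de <- moderated_diff_expr(d$expr_matrix, factor(groups,
                                                  c("neutral", "amp")))
  mirna_calls <- data.frame(
    mirna_id = d$truth$loci$mirna_id[d$truth$loci$cluster == "amp_14q32"],
    direction = "up")
  ct <- coherent_targets(mirna_calls, d$predictions, de)
  planted <- d$truth$targets[d$truth$targets$mirna_id %in%
                               mirna_calls$mirna_id, ]
  found <- paste(ct$mirna_id, ct$gene_id)
  expect_gte(mean(paste(planted$mirna_id, planted$gene_id) %in% found),
             0.9)
})
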