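# Synthetic data generators. Everything is drawn from the config's seed, so
# a fixed config yields identical tables on every run.

#' Generate a synthetic cell-line panel
#'
#' Builds the full multi-omics input set for the cell-line arm of the
#' pipeline: SNP-marker copy-number profiles with planted
#' amplicons/deletions over miRNA clusters, a qPCR Ct panel whose miRNA
#' expression follows the dosage model fold = (CN/2)^gamma with log-normal
#' noise, normal-control baselines, a log2 mRNA matrix carrying one
#' repressed target gene per amplified-cluster miRNA, a target-prediction
#' table (planted pairs plus random decoys), and a truth ledger listing
#' every planted event.
#'
#' Ct values are back-computed so that the 2^-ddCt method against the
#' normal-control calibrator recovers the planted fold changes exactly
#' when `expr_noise_sd = 0`.
#'
#' @param config A [simulation_config()].
#' @param what Components to generate besides expression and truth:
#'   any of `"markers"`, `"ct"`, `"mrna"`, `"predictions"`. Generating a
#'   subset changes nothing in the components that are produced.
#' @return list with elements `loci` (annotation), `locus_cn` (true
#'   per-sample locus CN calls, same shape as [assign_locus_cn()] output),
#'   `mirna_expr` (long table `sample_id`, `mirna_id`, `fold_change` for
#'   cell lines and normals), `markers`, `mirna_ct`, `expr_matrix`,
#'   `predictions` (NULL when not requested), `truth`
#'   (list: `loci`, `targets`), `samples`, `normals`, `config`.
#' @export
gen_cell_line_data <- function(config,
                               what = c("markers", "ct", "mrna",
                                        "predictions")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(what)) {
    what <- match.arg(what, several.ok = TRUE)
  }
  set.seed(config$seed)
  cl <- config$clusters
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  normals <- sprintf("NC%02d", seq_len(config$n_normals))
  chroms <- sort(unique(cl$chrom))

  # planted loci evenly spaced inside their cluster; nulls scattered
  # outside cluster regions (with a margin clear of breakpoint smear)
  margin <- 5L * config$marker_spacing
  loci_list <- list()
  for (i in seq_len(nrow(cl))) {
    k <- cl$n_mirnas[i]
    at <- round(seq(cl$start[i] + margin, cl$end[i] - margin,
                    length.out = k))
    loci_list[[i]] <- data.frame(
      mirna_id = sprintf("mir-%s-%02d", sub("_", "", cl$name[i]),
                         seq_len(k)),
      chrom = cl$chrom[i], start = at, end = at + 79L,
      cytoband = cl$name[i], cluster = cl$name[i]
    )
  }
  n_null <- config$n_mirnas - sum(cl$n_mirnas)
  null_pos <- matrix(NA_real_, n_null, 2L)
  ch <- sample(chroms, n_null, replace = TRUE)
  for (j in seq_len(n_null)) {
    repeat {
      p <- round(stats::runif(1, 1, config$chrom_length - 80))
      cc <- cl[cl$chrom == ch[j], , drop = FALSE]
      if (!nrow(cc) ||
          all(p + 79 < cc$start - margin | p > cc$end + margin)) break
    }
    null_pos[j, ] <- c(p, p + 79)
  }
  loci_list[[length(loci_list) + 1L]] <- data.frame(
    mirna_id = sprintf("mir-null-%03d", seq_len(n_null)),
    chrom = ch, start = null_pos[, 1L], end = null_pos[, 2L],
    cytoband = NA_character_, cluster = NA_character_
  )
  loci <- do.call(rbind, loci_list)
  rownames(loci) <- NULL

  # which lines carry each event
  cl$lines <- lapply(seq_len(nrow(cl)), function(i) {
    sort(sample(lines, cl$n_lines[i]))
  })

  # true CN per (line, locus)
  cn_true <- matrix(2, nrow = length(lines), ncol = nrow(loci),
                    dimnames = list(lines, loci$mirna_id))
  for (i in seq_len(nrow(cl))) {
    in_cluster <- !is.na(loci$cluster) & loci$cluster == cl$name[i]
    cn_true[cl$lines[[i]], in_cluster] <- cl$cn[i]
  }
  locus_cn <- data.frame(
    sample_id = rep(lines, times = nrow(loci)),
    mirna_id = rep(loci$mirna_id, each = length(lines)),
    cn = as.vector(cn_true),
    stringsAsFactors = FALSE
  )
  locus_cn$state <- classify_cn(locus_cn$cn)
  locus_cn$no_data <- FALSE

  # expression: dosage model with log-normal noise; normals at baseline
  gamma <- config$dosage_exponent
  fold_lines <- (cn_true / 2)^gamma *
    2^matrix(stats::rnorm(length(cn_true), 0, config$expr_noise_sd),
             nrow(cn_true))
  fold_norm <- 2^matrix(
    stats::rnorm(length(normals) * nrow(loci), 0, config$expr_noise_sd),
    length(normals), dimnames = list(normals, loci$mirna_id))
  mirna_expr <- rbind(
    data.frame(sample_id = rep(lines, nrow(loci)),
               mirna_id = rep(loci$mirna_id, each = length(lines)),
               fold_change = as.vector(fold_lines)),
    data.frame(sample_id = rep(normals, nrow(loci)),
               mirna_id = rep(loci$mirna_id, each = length(normals)),
               fold_change = as.vector(fold_norm))
  )

  markers <- NULL
  if ("markers" %in% what) {
    pos <- seq(config$marker_spacing, config$chrom_length,
               by = config$marker_spacing)
    grids <- expand.grid(pos = pos, chrom = chroms, sample_id = lines,
                         stringsAsFactors = FALSE)
    cn <- rep(2, nrow(grids))
    for (i in seq_len(nrow(cl))) {
      hit <- grids$chrom == cl$chrom[i] & grids$pos >= cl$start[i] &
        grids$pos <= cl$end[i] & grids$sample_id %in% cl$lines[[i]]
      cn[hit] <- cl$cn[i]
    }
    cn <- pmax(cn + stats::rnorm(length(cn), 0, config$marker_noise_sd), 0)
    markers <- data.frame(sample_id = grids$sample_id,
                          chrom = grids$chrom, pos = grids$pos, cn = cn)
  }

  mirna_ct <- NULL
  if ("ct" %in% what) {
    offs <- stats::setNames(stats::runif(nrow(loci), 3, 10), loci$mirna_id)
    all_fold <- rbind(fold_lines, fold_norm)
    ct_ref <- stats::setNames(
      stats::rnorm(nrow(all_fold), 20, 0.2), rownames(all_fold))
    tgt <- data.frame(
      sample_id = rep(rownames(all_fold), times = ncol(all_fold)),
      assay_id = rep(colnames(all_fold), each = nrow(all_fold)),
      ct = ct_ref[rep(rownames(all_fold), times = ncol(all_fold))] +
        offs[rep(colnames(all_fold), each = nrow(all_fold))] -
        log2(as.vector(all_fold)),
      role = "target"
    )
    ref <- data.frame(sample_id = names(ct_ref), assay_id = "U6B",
                      ct = unname(ct_ref), role = "reference")
    mirna_ct <- rbind(ref, tgt)
    rownames(mirna_ct) <- NULL
  }

  planted <- loci[!is.na(loci$cluster), ]
  planted_dir <- ifelse(
    cl$cn[match(planted$cluster, cl$name)] > 2, "up", "down")
  target_truth <- data.frame(
    mirna_id = planted$mirna_id[planted_dir == "up"],
    gene_id = paste0("TGT-", planted$mirna_id[planted_dir == "up"])
  )

  expr_matrix <- NULL
  if ("mrna" %in% what) {
    gene_ids <- c(target_truth$gene_id,
                  sprintf("G%04d", seq_len(config$n_genes -
                                             nrow(target_truth))))
    base <- stats::rnorm(length(gene_ids), 7, 1)
    expr_matrix <- matrix(
      base + stats::rnorm(length(gene_ids) * length(lines), 0,
                          config$mrna_noise_sd),
      nrow = length(gene_ids), dimnames = list(gene_ids, lines))
    # planted targets: repressed one-for-one (slope 1) by their miRNA
    for (i in seq_len(nrow(target_truth))) {
      expr_matrix[target_truth$gene_id[i], ] <-
        expr_matrix[target_truth$gene_id[i], ] -
        log2(fold_lines[, target_truth$mirna_id[i]])
    }
  }

  predictions <- NULL
  if ("predictions" %in% what) {
    dbs <- c("dbA", "dbB", "dbC", "dbD", "dbE")
    planted_pred <- do.call(rbind, lapply(seq_len(nrow(target_truth)),
      function(i) {
        src <- sample(dbs, sample(1:3, 1))
        data.frame(mirna_id = target_truth$mirna_id[i],
                   gene_id = target_truth$gene_id[i], source = src)
      }))
    decoy_genes <- sprintf("G%04d", sample.int(
      config$n_genes - nrow(target_truth),
      config$n_decoy_predictions, replace = TRUE))
    decoys <- data.frame(
      mirna_id = sample(loci$mirna_id, config$n_decoy_predictions,
                        replace = TRUE),
      gene_id = decoy_genes,
      source = sample(dbs, config$n_decoy_predictions, replace = TRUE))
    predictions <- unique(rbind(planted_pred, decoys))
    rownames(predictions) <- NULL
  }

  truth_loci <- data.frame(
    mirna_id = planted$mirna_id, cluster = planted$cluster,
    chrom = planted$chrom, start = planted$start, end = planted$end,
    cn = cl$cn[match(planted$cluster, cl$name)],
    direction = planted_dir,
    n_lines = cl$n_lines[match(planted$cluster, cl$name)],
    lines = vapply(match(planted$cluster, cl$name),
                   function(i) paste(cl$lines[[i]], collapse = ","),
                   character(1))
  )

  list(loci = loci[setdiff(names(loci), "cluster")],
       locus_cn = locus_cn, mirna_expr = mirna_expr, markers = markers,
       mirna_ct = mirna_ct, expr_matrix = expr_matrix,
       predictions = predictions,
       truth = list(loci = truth_loci, targets = target_truth),
       samples = lines, normals = normals, config = config)
}

#' Generate a synthetic patient cohort
#'
#' Draws, per patient, NF1 locus deletion status (Bernoulli `p_nf1_del`,
#' expressed in the genomic qPCR ratio as ~0.5 vs ~1) and miR-370
#' overexpression status (Bernoulli `p_mir370_up`, expressed as a
#' `mir370_up_fold`-fold miR-370 level). NF1 expression of miR-370-up
#' patients is repressed by `repression_strength`; additional
#' unknown-mechanism downregulation (`unknown_down_strength`) is injected
#' among the remaining patients at the rate needed to reach the planted
#' overall prevalence `p_nf1_down`. Deletion is modelled as
#' transcriptionally compensated (it moves the genomic ratio, not
#' expression), matching the observed near-independence of deletion and
#' expression-down status; see the methods vignette. Assay missingness is
#' MCAR at the configured per-assay rates.
#'
#' @param config A [simulation_config()].
#' @return list with `patients` (`patient_id`, `nf1_fold`, `mir370_fold`,
#'   `nf1_cn_ratio`, `sex`, `age_group`; NA where an assay is missing),
#'   `normals` (`sample_id`, `nf1_fold`, `mir370_fold`), `truth`
#'   (`patient_id`, `nf1_deleted`, `mir370_up`, `nf1_down_true`) and
#'   `config`.
#' @export
gen_cohort_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  del <- stats::rbinom(n, 1L, config$p_nf1_del) == 1L
  mir <- stats::rbinom(n, 1L, config$p_mir370_up) == 1L
  repressive <- config$repression_strength < 1
  attributable <- if (repressive) config$p_mir370_up else 0
  q <- if (attributable < 1) {
    max(0, (config$p_nf1_down - attributable) / (1 - attributable))
  } else 0
  extra <- stats::rbinom(n, 1L, q) == 1L
  if (repressive) extra <- extra & !mir
  down_true <- (repressive & mir) | extra

  lnoise <- function(k, sd) 2^stats::rnorm(k, 0, sd)
  nf1_fold <- lnoise(n, config$cohort_noise_sd) *
    ifelse(mir, config$repression_strength, 1) *
    ifelse(extra, config$unknown_down_strength, 1)
  mir370_fold <- lnoise(n, config$cohort_noise_sd) *
    ifelse(mir, config$mir370_up_fold, 1)
  nf1_cn_ratio <- ifelse(del, 0.5, 1) *
    lnoise(n, config$cn_ratio_noise_sd)

  mir370_fold[stats::runif(n) < config$p_missing_mir370] <- NA
  nf1_cn_ratio[stats::runif(n) < config$p_missing_cn] <- NA

  patients <- data.frame(
    patient_id = ids, nf1_fold = nf1_fold, mir370_fold = mir370_fold,
    nf1_cn_ratio = nf1_cn_ratio,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3)),
    age_group = sample(c("<60", ">=60"), n, replace = TRUE,
                       prob = c(0.35, 0.65))
  )
  normals <- data.frame(
    sample_id = sprintf("NC%02d", seq_len(config$n_normals)),
    nf1_fold = lnoise(config$n_normals, config$cohort_noise_sd),
    mir370_fold = lnoise(config$n_normals, config$cohort_noise_sd)
  )
  truth <- data.frame(patient_id = ids, nf1_deleted = del,
                      mir370_up = mir, nf1_down_true = down_true)
  list(patients = patients, normals = normals, truth = truth,
       config = config)
}

#' Write generated data sets to TSV files
#'
#' Serializes every tabular component of a [gen_cell_line_data()] or
#' [gen_cohort_data()] result into `dir`, one TSV per table (matrices gain
#' a leading id column). File names follow the component names.
#'
#' @param data Result list from a generator.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_synthetic_data <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x), x, check.names = FALSE)
    } else if (nm == "truth") {
      for (tn in names(x)) {
        if (is.data.frame(x[[tn]])) {
          p <- file.path(dir, paste0("truth_", tn, ".tsv"))
          utils::write.table(x[[tn]], p, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          paths <- c(paths, p)
        }
      }
      next
    }
    if (!is.data.frame(x)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
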