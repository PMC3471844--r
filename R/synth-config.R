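# Configuration for the synthetic multi-omics generator. Defaults encode
# the study design the pipeline targets: 16 myeloid cell lines, a 250-miRNA
# qPCR panel with recurrent amplicons/deletions over miRNA clusters, and a
# 68-patient cohort with planted prevalences of NF1 downregulation, NF1
# locus deletion and miR-370 overexpression.

#' Default copy-number cluster specification
#'
#' Five planted events over four synthetic chromosomes, echoing the
#' recurrent alterations of the 16-cell-line panel: two small amplified
#' miRNA clusters, one large 12-miRNA amplified cluster, and two deleted
#' loci, totalling 19 dosage-affected miRNAs (16 amplified, 3 deleted).
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `n_mirnas`, `n_lines`, `cn`.
#' @export
default_cluster_spec <- function() {
  data.frame(
    name = c("amp_11q13", "amp_11q24", "amp_14q32", "del_9q", "del_13q"),
    chrom = c("chr11", "chr11", "chr14", "chr9", "chr13"),
    start = c(200001L, 900001L, 500001L, 600001L, 600001L),
    end = c(500000L, 1200000L, 1100000L, 900000L, 900000L),
    n_mirnas = c(2L, 2L, 12L, 1L, 2L),
    n_lines = c(8L, 5L, 4L, 5L, 2L),
    cn = c(3.365, 3.099, 3.671, 0.96, 1.071)
  )
}

#' Build a simulation configuration
#'
#' Collects and validates every tunable of the synthetic-data generator.
#' Defaults are the study conditions the pipeline is designed for; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generated table
#'   reproducible.
#' @param n_cell_lines Number of cell lines (default 16).
#' @param n_mirnas Size of the miRNA qPCR panel (default 250).
#' @param clusters Planted copy-number events, as in
#'   [default_cluster_spec()]; regions must not overlap.
#' @param chrom_length Length of each synthetic chromosome in bp
#'   (default 1.5e6).
#' @param marker_spacing SNP-marker spacing in bp (default 5000).
#' @param marker_noise_sd Gaussian SD of per-marker CN noise (default
#'   0.15, typical array probe-level scatter).
#' @param dosage_exponent Exponent gamma of the dosage model: true
#'   expression fold = (CN/2)^gamma (default 1; 0 gives a null panel).
#' @param expr_noise_sd Log2-scale SD of miRNA expression noise
#'   (default 0.25).
#' @param mrna_noise_sd Log2-scale SD of mRNA array noise (default 0.5).
#' @param n_genes Genes on the synthetic mRNA array (default 1000).
#' @param n_decoy_predictions Random non-planted prediction pairs
#'   (default 200).
#' @param n_normals Normal-control samples (default 10).
#' @param n_patients Cohort size (default 68).
#' @param p_nf1_down,p_mir370_up,p_nf1_del Planted cohort prevalences
#'   (defaults 0.31, 0.12, 0.24).
#' @param repression_strength Multiplicative NF1 fold in miR-370-up
#'   patients (default 0.15, i.e. ~6.7-fold repression; must be < 1 for
#'   the repression to be operative).
#' @param unknown_down_strength Multiplicative NF1 fold in
#'   unknown-mechanism downregulated patients (default 0.15).
#' @param mir370_up_fold miR-370 fold in overexpressing patients
#'   (default 8).
#' @param cohort_noise_sd Log2-scale SD of cohort qPCR noise
#'   (default 0.15).
#' @param cn_ratio_noise_sd Log2-scale SD of the genomic qPCR ratio
#'   (default 0.1).
#' @param p_missing_mir370,p_missing_cn MCAR missingness rates of the
#'   miR-370 and genomic assays (defaults 18/68 and 13/68, mirroring the
#'   cohort denominators 50/68 and 55/68).
#' @return list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cell_lines = 16L,
                              n_mirnas = 250L,
                              clusters = default_cluster_spec(),
                              chrom_length = 1.5e6,
                              marker_spacing = 5000L,
                              marker_noise_sd = 0.15,
                              dosage_exponent = 1,
                              expr_noise_sd = 0.25,
                              mrna_noise_sd = 0.5,
                              n_genes = 1000L,
                              n_decoy_predictions = 200L,
                              n_normals = 10L,
                              n_patients = 68L,
                              p_nf1_down = 0.31,
                              p_mir370_up = 0.12,
                              p_nf1_del = 0.24,
                              repression_strength = 0.15,
                              unknown_down_strength = 0.15,
                              mir370_up_fold = 8,
                              cohort_noise_sd = 0.15,
                              cn_ratio_noise_sd = 0.1,
                              p_missing_mir370 = 18 / 68,
                              p_missing_cn = 13 / 68) {
  cfg <- as.list(environment())
  probs <- c(p_nf1_down, p_mir370_up, p_nf1_del,
             p_missing_mir370, p_missing_cn)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (sum(clusters$n_mirnas) > n_mirnas) {
    stop("cluster miRNAs exceed the panel size")
  }
  if (any(clusters$start < 1) || any(clusters$end <= clusters$start) ||
      any(clusters$end > chrom_length)) {
    stop("cluster regions must fit inside the chromosomes")
  }
  for (chr in unique(clusters$chrom)) {
    cc <- clusters[clusters$chrom == chr, ]
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1L && any(cc$start[-1L] <= cc$end[-nrow(cc)])) {
      stop("cluster regions overlap on ", chr)
    }
  }
  if (repression_strength < 1 && p_nf1_down < p_mir370_up) {
    stop("inconsistent probabilities: p_nf1_down must be >= p_mir370_up ",
         "when miR-370 repression is operative")
  }
  class(cfg) <- "sim_config"
  cfg
}
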