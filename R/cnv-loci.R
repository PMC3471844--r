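#' Assign a copy-number call to each miRNA locus
#'
#' For every sample and every annotated miRNA locus, looks up the segmented
#' copy-number profile and assigns a CN value and state. A locus fully inside
#' one segment takes that segment's mean CN; a locus straddling several
#' segments takes the coverage-weighted mean over the overlapped bases; a
#' locus on an uncovered gap or absent chromosome is reported with state
#' `neutral` and `no_data = TRUE`.
#'
#' All coordinates are 1-based closed intervals.
#'
#' @param segments SEG-style data.frame (`sample_id`, `chrom`, `start`,
#'   `end`, `mean_cn`), non-overlapping within a sample/chromosome.
#' @param loci data.frame of miRNA loci (`mirna_id`, `chrom`, `start`,
#'   `end`; optional `cytoband`).
#' @return data.frame with one row per (sample, locus): `sample_id`,
#'   `mirna_id`, `cn`, `state`, `no_data`. `cn` is NA when `no_data`.
#' @export
assign_locus_cn <- function(segments, loci) {
  if (!all(c("sample_id", "chrom", "start", "end", "mean_cn") %in%
           names(segments))) {
    stop("'segments' needs sample_id, chrom, start, end, mean_cn")
  }
  if (!all(c("mirna_id", "chrom", "start", "end") %in% names(loci))) {
    stop("'loci' needs mirna_id, chrom, start, end")
  }
  if (anyDuplicated(loci$mirna_id)) stop("duplicate mirna_id in 'loci'")
  samples <- unique(segments$sample_id)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    seg_s <- segments[segments$sample_id == s, ]
    cn <- rep(NA_real_, nrow(loci))
    for (li in seq_len(nrow(loci))) {
      ss <- seg_s[seg_s$chrom == loci$chrom[li], ]
      if (!nrow(ss)) next
      w <- pmin(ss$end, loci$end[li]) - pmax(ss$start, loci$start[li]) + 1
      hit <- w > 0
      if (!any(hit)) next
      cn[li] <- sum(ss$mean_cn[hit] * w[hit]) / sum(w[hit])
    }
    no_data <- is.na(cn)
    out[[si]] <- data.frame(
      sample_id = s,
      mirna_id = loci$mirna_id,
      cn = cn,
      state = ifelse(no_data, "neutral", classify_cn(ifelse(no_data, 2, cn))),
      no_data = no_data
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find recurrently altered regions across samples
#'
#' Sweeps the altered segments of all samples and reports, separately for
#' amplifications (CN > 3) and deletions (CN < 1.5), the maximal genomic
#' intervals where at least `min_samples` samples are altered. Within each
#' reported interval the peak per-base sample count is returned.
#'
#' @param segments SEG-style data.frame (`sample_id`, `chrom`, `start`,
#'   `end`, `mean_cn`).
#' @param min_samples Minimum number of altered samples (default 4).
#' @return data.frame with columns `chrom`, `start`, `end`, `direction`
#'   (`"amplification"` or `"deletion"`), `n_samples` (peak per-base count
#'   of altered samples in the interval). Empty input gives zero rows.
#' @export
recurrent_regions <- function(segments, min_samples = 4L) {
  if (min_samples < 1L) stop("'min_samples' must be >= 1")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_samples = integer())
  if (is.null(segments) || !nrow(segments)) return(empty)
  pieces <- list()
  for (direction in c("amplification", "deletion")) {
    sel <- if (direction == "amplification") {
      is_amplified(segments$mean_cn)
    } else {
      is_deleted(segments$mean_cn)
    }
    alt <- segments[sel, , drop = FALSE]
    if (!nrow(alt)) next
    for (chr in unique(alt$chrom)) {
      a <- alt[alt$chrom == chr, ]
      # per-sample reduce so adjacent altered segments count once
      per_sample <- lapply(split(a, a$sample_id), function(d) {
        IRanges::reduce(IRanges::IRanges(d$start, d$end))
      })
      cov <- IRanges::coverage(do.call(c, unname(per_sample)))
      hi <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
      if (!length(hi)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chr,
        start = IRanges::start(hi),
        end = IRanges::end(hi),
        direction = direction,
        n_samples = as.integer(
          IRanges::viewMaxs(IRanges::Views(cov, hi))
        )
      )
    }
  }
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$direction, out$chrom, out$start), ]
}
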