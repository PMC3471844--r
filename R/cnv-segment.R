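# Recursive t-based binary segmentation of per-marker copy-number profiles.
# Documented stand-in for proprietary SNP-array segmenters: at each step the
# breakpoint maximizing the pooled two-sample t between flanks is tested and
# the split accepted when p < alpha and both flanks hold >= min_markers.

# Best split of cn[i..j]; returns NULL or list(k = last index of left flank,
# on the local 1..n scale, p = split p-value).
.best_split <- function(x, min_markers, alpha) {
  n <- length(x)
  if (n < 2L * min_markers) return(NULL)
  cs <- cumsum(x)
  css <- cumsum(x * x)
  k <- min_markers:(n - min_markers)          # candidate left-flank sizes
  n1 <- k
  n2 <- n - k
  s1 <- cs[k]
  s2 <- cs[n] - s1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss1 <- pmax(css[k] - s1^2 / n1, 0)          # within-flank sums of squares
  ss2 <- pmax(css[n] - css[k] - s2^2 / n2, 0)
  df <- n - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m1 - m2) / se,
               ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  at <- abs(tt)
  best <- which.max(at)                        # which.max: leftmost tie
  if (!is.finite(at[best]) && at[best] > 0) {
    p <- 0
  } else {
    # Bonferroni over the scanned breakpoints: the max-t over candidates
    # is anti-conservative at the pointwise level
    p <- min(1, 2 * stats::pt(-at[best], df) * length(k))
  }
  if (is.na(p) || p >= alpha) return(NULL)
  list(k = k[best], p = p)
}

#' Segment a per-marker copy-number profile
#'
#' Recursive binary segmentation of one sample/chromosome marker track:
#' at each step the breakpoint maximizing the pooled two-sample t-statistic
#' between the two flanks is chosen (ties broken toward the leftmost
#' position), and the split is accepted when its p-value — Bonferroni
#' adjusted for the number of candidate breakpoints scanned — is below
#' `alpha` and both flanks retain at least `min_markers` markers. Each resulting
#' segment carries the arithmetic mean copy number of its member markers,
#' so segments tile the marker range and conserve the grand mean.
#'
#' @param pos Integer/numeric vector of marker positions, sorted ascending.
#' @param cn Numeric vector of marker copy-number estimates, same length.
#' @param min_markers Minimum markers per segment (>= 2; default 5).
#' @param alpha Split acceptance p-value threshold (default 0.01).
#' @return A data.frame with columns `start`, `end` (positions of the first
#'   and last member marker), `n_markers`, `mean_cn`, and `flagged` (TRUE
#'   when the whole profile held fewer than `min_markers` markers and a
#'   single unsplit segment was returned).
#' @examples
#' set.seed(1)
#' segment_markers(1:40, c(rnorm(20, 2, 0.1), rnorm(20, 3.7, 0.1)))
#' @export
segment_markers <- function(pos, cn, min_markers = 5L, alpha = 0.01) {
  if (length(pos) != length(cn)) stop("'pos' and 'cn' lengths differ")
  if (length(pos) == 0L) stop("empty marker profile")
  if (is.unsorted(pos)) stop("'pos' must be sorted ascending")
  if (min_markers < 2L) stop("'min_markers' must be >= 2")
  if (any(!is.finite(cn)) || any(cn < 0)) {
    stop("marker copy-number values must be finite and non-negative")
  }
  n <- length(cn)
  flagged <- n < min_markers
  bounds <- list(c(1L, n))
  out <- list()
  while (length(bounds)) {
    b <- bounds[[1L]]
    bounds <- bounds[-1L]
    sp <- if (flagged) NULL else
      .best_split(cn[b[1L]:b[2L]], min_markers, alpha)
    if (is.null(sp)) {
      out[[length(out) + 1L]] <- b
    } else {
      cut <- b[1L] + sp$k - 1L
      # keep left-to-right output order: process left before right
      bounds <- c(list(c(b[1L], cut), c(cut + 1L, b[2L])), bounds)
    }
  }
  out <- out[order(vapply(out, `[`, integer(1), 1L))]
  data.frame(
    start = pos[vapply(out, `[`, integer(1), 1L)],
    end = pos[vapply(out, `[`, integer(1), 2L)],
    n_markers = vapply(out, function(b) b[2L] - b[1L] + 1L, integer(1)),
    mean_cn = vapply(out, function(b) mean(cn[b[1L]:b[2L]]), numeric(1)),
    flagged = flagged
  )
}

#' Segment all samples and chromosomes of a marker table
#'
#' Applies [segment_markers()] to each (sample, chromosome) track of a long
#' marker table and returns a SEG-style table.
#'
#' @param markers data.frame with columns `sample_id`, `chrom`, `pos`, `cn`.
#' @inheritParams segment_markers
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_markers`, `mean_cn`, `flagged`.
#' @export
segment_profile <- function(markers, min_markers = 5L, alpha = 0.01) {
  need <- c("sample_id", "chrom", "pos", "cn")
  if (!all(need %in% names(markers))) {
    stop("'markers' needs columns: ", paste(need, collapse = ", "))
  }
  parts <- split(markers, list(markers$sample_id, markers$chrom), drop = TRUE)
  res <- lapply(parts, function(mk) {
    mk <- mk[order(mk$pos), ]
    seg <- segment_markers(mk$pos, mk$cn, min_markers, alpha)
    cbind(sample_id = mk$sample_id[1L], chrom = mk$chrom[1L], seg)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$sample_id, out$chrom, out$start), ]
}
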