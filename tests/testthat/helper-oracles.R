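# Independent brute-force oracles used to validate the fast implementations.

# Per-base locus copy number: mean over covered bases of the covering
# segment's CN; NA when no base is covered.
oracle_locus_cn <- function(segments, chrom, start, end) {
  vals <- rep(NA_real_, end - start + 1L)
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    lo <- max(seg$start[i], start)
    hi <- min(seg$end[i], end)
    if (lo > hi) next
    vals[(lo:hi) - start + 1L] <- seg$mean_cn[i]
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Per-position recurrence: count altered samples at every base of 1..len,
# return runs with count >= min_samples and each run's peak count.
oracle_recurrent <- function(altered_segments, len, min_samples) {
  count <- integer(len)
  for (s in unique(altered_segments$sample_id)) {
    seg <- altered_segments[altered_segments$sample_id == s, , drop = FALSE]
    hit <- logical(len)
    for (i in seq_len(nrow(seg))) {
      hit[seg$start[i]:seg$end[i]] <- TRUE
    }
    count <- count + hit
  }
  ok <- count >= min_samples
  if (!any(ok)) {
    return(data.frame(start = integer(), end = integer(),
                      n_samples = integer()))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = starts[keep], end = ends[keep],
    n_samples = vapply(which(keep), function(i) {
      max(count[starts[i]:ends[i]])
    }, integer(1))
  )
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  ks <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
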