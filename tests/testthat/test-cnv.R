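test_that("copy-number classification follows the published thresholds", {
  # values drawn from the published cell-line table
  expect_identical(classify_cn(3.671), "amplification")
  expect_identical(classify_cn(0.9596), "hemizygous_deletion")
  expect_identical(classify_cn(1.071), "hemizygous_deletion")
  expect_identical(classify_cn(2.0), "neutral")
  expect_identical(classify_cn(0.3), "homozygous_deletion")
  expect_identical(classify_cn(0.6), "deletion_unclassified")
  # boundary strictness: 3 and 1.5 are neutral, 0.8 is hemizygous
  expect_identical(classify_cn(c(3, 1.5, 0.8, 0.5)),
                   c("neutral", "neutral", "hemizygous_deletion",
                     "deletion_unclassified"))
  expect_error(classify_cn(-1), "non-negative")
  expect_error(classify_cn(NaN), "finite")
})

test_that("the five states partition [0, Inf) and predicates are exclusive", {
  cn <- c(seq(0, 6, by = 0.01), 0.7999, 0.8, 1.4999, 1.5, 3, 3.0001)
  st <- classify_cn(cn)
  expect_true(all(st %in% cn_states()))
  expect_false(any(is_deleted(cn) & is_amplified(cn)))
  expect_identical(is_deleted(cn), cn < 1.5)
  expect_identical(is_amplified(cn), cn > 3)
  # every deletion state satisfies is_deleted and vice versa
  del_states <- c("hemizygous_deletion", "homozygous_deletion",
                  "deletion_unclassified")
  expect_identical(st %in% del_states, unname(is_deleted(cn)))
})

test_that("segmentation recovers a planted breakpoint and mean levels", {
  set.seed(101)
  cn <- c(rnorm(20, 2.0, 0.1), rnorm(20, 3.7, 0.1))
  seg <- segment_markers(1:40, cn, min_markers = 5, alpha = 0.01)
  expect_equal(nrow(seg), 2L)
  expect_lt(abs(seg$end[1] - 20), 2.5)  # breakpoint within 2 markers
  expect_lt(abs(seg$mean_cn[1] - 2.0), 0.1)
  expect_lt(abs(seg$mean_cn[2] - 3.7), 0.1)
})

test_that("segmentation leaves flat and constant profiles unsplit", {
  set.seed(102)
  flat <- segment_markers(1:40, rnorm(40, 2, 0.1))
  expect_equal(nrow(flat), 1L)
  const <- segment_markers(1:40, rep(2, 40))
  expect_equal(nrow(const), 1L)
  expect_equal(const$mean_cn, 2)
  # fewer markers than min_markers: single flagged segment
  small <- segment_markers(1:3, c(2, 2, 2), min_markers = 5)
  expect_equal(nrow(small), 1L)
  expect_true(small$flagged)
})

test_that("segment means conserve the per-marker grand mean", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(20:120, 1)
    # one or two random levels, so some profiles split and some do not
    lev <- sample(c(1, 2, 3.7), 2)
    cut <- sample(n, 1)
    cn <- pmax(0, rnorm(n, rep(lev, c(cut, n - cut)), 0.2))
    seg <- segment_markers(seq_len(n), cn)
    expect_equal(sum(seg$mean_cn * seg$n_markers) / sum(seg$n_markers),
                 mean(cn), tolerance = 1e-9)
    expect_equal(sum(seg$n_markers), n)
  }
})

test_that("locus CN assignment matches the per-base oracle", {
  set.seed(7)
  for (rep in 1:20) {
    # random small genome: tiling non-overlapping segments with gaps
    bounds <- sort(sample(1:10000, sample(4:20, 1)))
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1L]
    keep <- runif(length(starts)) < 0.8   # drop some: uncovered gaps
    segs <- data.frame(sample_id = "S1", chrom = "c1",
                       start = starts[keep], end = ends[keep],
                       mean_cn = round(runif(sum(keep), 0, 5), 3))
    loci <- data.frame(mirna_id = paste0("m", 1:8), chrom = "c1",
                       start = sample(1:9800, 8))
    loci$end <- loci$start + sample(10:400, 8)
    calls <- assign_locus_cn(segs, loci)
    for (i in 1:8) {
      exp_cn <- oracle_locus_cn(segs, "c1", loci$start[i], loci$end[i])
      got <- calls[calls$mirna_id == loci$mirna_id[i], ]
      if (is.na(exp_cn)) {
        expect_true(got$no_data)
        expect_identical(got$state, "neutral")
      } else {
        expect_equal(got$cn, exp_cn, tolerance = 1e-9)
        expect_identical(got$state, classify_cn(exp_cn))
      }
    }
  }
})

test_that("locus CN assignment handles straddling and missing chromosomes", {
  segs <- data.frame(sample_id = "S1", chrom = "c1",
                     start = c(1, 101), end = c(100, 200),
                     mean_cn = c(2, 4))
  loci <- data.frame(mirna_id = c("mid", "inA", "off"),
                     chrom = c("c1", "c1", "c9"),
                     start = c(51, 10, 1), end = c(150, 20, 100))
  calls <- assign_locus_cn(segs, loci)
  # half in CN 2, half in CN 4: weighted mean 3 -> neutral (not "over 3")
  expect_equal(calls$cn[calls$mirna_id == "mid"], 3)
  expect_identical(calls$state[calls$mirna_id == "mid"], "neutral")
  expect_equal(calls$cn[calls$mirna_id == "inA"], 2)
  expect_true(calls$no_data[calls$mirna_id == "off"])
})

test_that("recurrent regions match the per-position counting oracle", {
  set.seed(11)
  for (rep in 1:10) {
    len <- 500L
    segs <- do.call(rbind, lapply(1:16, function(s) {
      k <- sample(0:3, 1)
      if (!k) return(NULL)
      st <- sort(sample(seq(1, len - 60, by = 20), k))
      data.frame(sample_id = paste0("S", s), chrom = "c1", start = st,
                 end = pmin(st + sample(20:80, k, TRUE), len),
                 mean_cn = sample(c(3.7, 1.0, 2.0), k, TRUE))
    }))
    for (ms in c(1L, 2L, 4L)) {
      got <- recurrent_regions(segs, min_samples = ms)
      for (dir in c("amplification", "deletion")) {
        sel <- if (dir == "amplification") is_amplified(segs$mean_cn)
               else is_deleted(segs$mean_cn)
        # merge per-sample before counting, as the oracle does implicitly
        exp <- oracle_recurrent(segs[sel, , drop = FALSE], len, ms)
        g <- got[got$direction == dir, ]
        expect_equal(g$start, exp$start)
        expect_equal(g$end, exp$end)
        expect_equal(g$n_samples, exp$n_samples)
      }
    }
  }
})

test_that("recurrence threshold behaves at and below the cut", {
  segs <- do.call(rbind, lapply(1:16, function(s) {
    data.frame(sample_id = paste0("S", s), chrom = "c1",
               start = 100L, end = 200L,
               mean_cn = if (s <= 5) 3.7 else 2.0)
  }))
  hit <- recurrent_regions(segs, min_samples = 4)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_samples, 5L)
  expect_identical(hit$direction, "amplification")
  # only 3 altered samples: below the default threshold
  segs3 <- segs
  segs3$mean_cn[segs3$sample_id %in% c("S4", "S5")] <- 2.0
  expect_equal(nrow(recurrent_regions(segs3, min_samples = 4)), 0L)
  expect_equal(nrow(recurrent_regions(segs3, min_samples = 1)), 1L)
  expect_equal(nrow(recurrent_regions(segs[0, ], 4)), 0L)
})

test_that("marker, SEG and locus files round-trip through the readers", {
  dir <- withr::local_tempdir()
  mk <- data.frame(sample_id = "S1", chrom = "c1", pos = c(10L, 20L),
                   cn = c(2.1, 1.9))
  write.table(mk, file.path(dir, "mk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_markers(file.path(dir, "mk.tsv")), mk)
  seg <- segment_profile(data.frame(sample_id = "S1", chrom = "c1",
                                    pos = 1:10, cn = rep(2, 10)))
  write_seg(seg, file.path(dir, "s.seg"))
  expect_equal(read_seg(file.path(dir, "s.seg"))$mean_cn, 2)
  # BED is 0-based half-open: start shifts by one on read
  writeLines("c1\t99\t200\tmiR-x", file.path(dir, "l.bed"))
  bed <- read_mirna_loci(file.path(dir, "l.bed"), bed = TRUE)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 200L)
  expect_identical(bed$mirna_id, "miR-x")
})
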