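# small helper: annotations object built from simulated reads
annotate_sim <- function(sim) {
  fl <- default_flanks()
  annotate_reads(extract_complete_reads(sim, flank_anchors(fl$flank5, fl$flank3)))
}

test_that("summarize_sample reports span statistics and the TCTG fraction", {
  al <- dm2_allele(cctg = 100, label = "a")
  sim <- simulate_read_set(list(a = al), n_reads = 1, seed = 1)
  s <- summarize_sample(annotate_sim(sim))
  expect_equal(unname(s$span_bp), rep(400, 3))        # single read: min=median=max
  expect_equal(unname(s$span_units), rep(100, 3))

  # 50 expanded reads, exactly one carrying the 3' TCTG block -> 2%
  sim <- simulate_read_set(
    list(tctg = dm2_allele(cctg = 100, tctg3 = 20, label = "tctg"),
         pure = dm2_allele(cctg = 100, label = "pure")),
    n_reads = 50, counts = c(tctg = 1, pure = 49), seed = 2)
  s <- summarize_sample(annotate_sim(sim))
  expect_equal(s$n_expanded_reads, 50L)
  expect_equal(s$fraction_tctg_reads, 0.02)
  expect_equal(sum(s$histogram$count), s$n_expanded_reads)

  # no expanded reads: fraction is an explicit NA, not 0
  sim <- simulate_read_set(list(n = dm2_allele(cctg = 20, label = "n")),
                           n_reads = 5, seed = 3)
  s <- summarize_sample(annotate_sim(sim))
  expect_equal(s$n_expanded_reads, 0L)
  expect_true(is.na(s$fraction_tctg_reads))
})

test_that("recovered fraction sits inside the binomial interval of the weight", {
  sim <- simulate_read_set(
    list(tctg = dm2_allele(cctg = 90, tctg3 = 15, label = "tctg"),
         pure = dm2_allele(cctg = 90, label = "pure")),
    n_reads = 500, weights = c(tctg = 0.6, pure = 0.4), seed = 4)
  s <- summarize_sample(annotate_sim(sim))
  ci <- 1.96 * sqrt(0.6 * 0.4 / 500)
  expect_lt(abs(s$fraction_tctg_reads - 0.6), ci + 1e-9)
})

test_that("statistics are invariant to read order and duplication", {
  sim <- simulate_read_set(
    list(tctg = dm2_allele(cctg = 80, tctg3 = 10, label = "tctg"),
         pure = dm2_allele(cctg = 80, label = "pure")),
    n_reads = 30, counts = c(tctg = 12, pure = 18), seed = 5)
  ann <- annotate_sim(sim)
  s <- summarize_sample(ann)

  shuf <- ann
  set.seed(6)
  ord <- sample(nrow(shuf$per_read))
  shuf$per_read <- shuf$per_read[ord, ]
  expect_equal(summarize_sample(shuf)$fraction_tctg_reads, s$fraction_tctg_reads)
  expect_equal(summarize_sample(shuf)$span_bp, s$span_bp)

  dup <- ann
  dup$per_read <- rbind(dup$per_read, dup$per_read)
  dup$segments <- rbind(dup$segments, dup$segments)
  expect_equal(summarize_sample(dup)$fraction_tctg_reads, s$fraction_tctg_reads)
})

test_that("binned_abundance uses right-open 500 bp bins and a unit-mass KDE", {
  h <- binned_abundance(c(10, 120, 499))$histogram
  expect_equal(nrow(h[h$count > 0, ]), 1L)
  expect_equal(sum(h$count), 3L)

  h <- binned_abundance(8750)$histogram
  expect_equal(h$bin_start[h$count == 1], 8500)      # floor(8750/500) = 17
  expect_equal(h$bin_end[h$count == 1], 9000)

  expect_equal(nrow(binned_abundance(numeric())$histogram), 0L)

  # histogram mass conservation on random inputs
  set.seed(7)
  spans <- rlnorm(400, log(8000), 0.3)
  res <- binned_abundance(spans)
  expect_equal(sum(res$histogram$count), 400L)
  # KDE integrates to ~1 on its grid
  area <- sum(diff(res$density$x) * (head(res$density$y, -1) + tail(res$density$y, -1)) / 2)
  expect_lt(abs(area - 1), 0.01)

  # a bimodal mixture shows two kde maxima separated by the simulated gap
  spans <- c(rnorm(300, 4000, 300), rnorm(300, 12000, 300))
  d <- binned_abundance(spans)$density
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  peaks <- peaks[d$y[peaks] > 0.1 * max(d$y)]
  expect_equal(length(peaks), 2L)
  expect_lt(abs(d$x[peaks[1]] - 4000), 1000)
  expect_lt(abs(d$x[peaks[2]] - 12000), 1000)
})

test_that("motif length distributions follow Tukey's rule", {
  fake_ann <- function(lengths, motif = "CCTG") {
    segs <- data.frame(read_id = sprintf("r%d", seq_along(lengths)),
                       start = 0L, end = as.integer(lengths), label = motif,
                       match_ratio = 1, units = as.integer(lengths) %/% 4L,
                       stringsAsFactors = FALSE)
    structure(list(per_read = data.frame(read_id = segs$read_id),
                   segments = segs, params = annotator_params()),
              class = "read_annotations")
  }
  d <- motif_length_distribution(fake_ann(c(4, 8, 12, 16, 20)), "CCTG")
  expect_equal(d$median, 12)
  expect_equal(d$q1, unname(quantile(c(4, 8, 12, 16, 20), 0.25)))
  expect_equal(d$q3, unname(quantile(c(4, 8, 12, 16, 20), 0.75)))

  d <- motif_length_distribution(fake_ann(42), "CCTG")
  expect_equal(d$iqr, 0)
  expect_equal(length(d$outliers), 0L)

  lengths <- c(rep(40, 49), 4000)      # one value 100x the median
  d <- motif_length_distribution(fake_ann(lengths), "CCTG")
  expect_equal(d$outliers, 4000)
  expect_equal(d$whisker_high, 40)

  d <- motif_length_distribution(fake_ann(c(4, 8)), "TCTG")   # absent motif
  expect_equal(d$n, 0L)

  # quantiles agree with a sort-based oracle on random inputs
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1000, 37, replace = TRUE)
    d <- motif_length_distribution(fake_ann(x), "CCTG")
    sx <- sort(x)
    expect_equal(d$median, unname(quantile(sx, 0.5)))
    expect_equal(d$q1, unname(quantile(sx, 0.25)))
    fences <- c(d$q1 - 1.5 * d$iqr, d$q3 + 1.5 * d$iqr)
    expect_setequal(d$outliers, x[x < fences[1] | x > fences[2]])
  }
})

test_that("detection floor is the reciprocal coverage in percent", {
  expect_equal(detection_floor(50), 2)
  expect_equal(detection_floor(1), 100)
  expect_equal(round(detection_floor(84), 2), 1.19)
  expect_error(detection_floor(0))
})

test_that("compare_generations reports deltas and TCTG retention", {
  mk <- function(counts, seed) {
    sim <- simulate_read_set(
      list(tctg = dm2_allele(cctg = 100, tctg3 = 20, label = "tctg"),
           pure = dm2_allele(cctg = 100, label = "pure")),
      n_reads = sum(counts), counts = counts, seed = seed)
    summarize_sample(annotate_sim(sim))
  }
  parent <- mk(c(tctg = 10, pure = 10), seed = 9)
  self_delta <- compare_generations(parent, parent)
  expect_true(all(self_delta$delta_units[, -1] == 0))
  expect_true(self_delta$motif_retained)
  expect_false(self_delta$motif_lost)

  child <- mk(c(tctg = 0, pure = 20), seed = 10)
  d <- compare_generations(parent, child)
  expect_true(d$motif_lost)
  expect_false(d$motif_retained)
})

test_that("a simulated contraction shows up as the expected max-unit delta", {
  mk <- function(median_units, seed) {
    sim <- simulate_read_set(
      list(e = dm2_allele(cctg = 100, label = "e")), n_reads = 60,
      mosaic = mosaic_model("lognormal", median_units, 0.1,
                            min_units = 75, max_units = 20000),
      seed = seed)
    summarize_sample(annotate_sim(sim))
  }
  parent <- mk(7500, seed = 11)
  child <- mk(4000, seed = 12)
  d <- compare_generations(parent, child)
  got <- d$delta_units$d_max_units[d$delta_units$motif == "CCTG"]
  truth <- child$per_motif_units$max_units[1] - parent$per_motif_units$max_units[1]
  expect_equal(got, truth)
  expect_lt(got, 0)                                   # contraction
  # recovered medians track the simulated medians
  expect_lt(abs(parent$span_units["median"] - 7500) / 7500, 0.1)
  expect_lt(abs(child$span_units["median"] - 4000) / 4000, 0.1)
})

test_that("parameter recovery: median and TCTG fraction from a mixed sample", {
  sim <- simulate_read_set(
    list(tctg = dm2_allele(cctg = 100, tctg3 = 30, label = "tctg"),
         pure = dm2_allele(cctg = 100, label = "pure")),
    n_reads = 500, weights = c(tctg = 0.56, pure = 0.44),
    mosaic = mosaic_model("lognormal", 5000, 0.2, min_units = 75, max_units = 20000),
    seed = 13)
  s <- summarize_sample(annotate_sim(sim))
  expect_lt(abs(s$span_units["median"] - 5000) / 5000, 0.03)
  expect_lt(abs(s$fraction_tctg_reads - 0.56), 0.05)
})
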