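test_that("phase_profile matches substring-search coverage", {
  expect_true(all(phase_profile(strrep("CCTG", 5), "CCTG")))
  expect_false(any(phase_profile("CCTGCCTGCCTG", "TCTG")))

  # one substitution inside (CCTG)x8 uncovers exactly its quadruplet
  s <- strsplit(strrep("CCTG", 8), "")[[1]]
  s[14] <- "A"                       # inside the 4th quadruplet
  s <- paste(s, collapse = "")
  expect_equal(phase_profile(s, "CCTG"), oracle_mask(s, "CCTG"))
  expect_equal(sum(!phase_profile(s, "CCTG")), 4L)

  # random sequences agree with the oracle
  set.seed(21)
  for (i in 1:25) {
    r <- fuzz_read()
    for (m in c("CCTG", "TCTG")) {
      expect_equal(phase_profile(r, m), oracle_mask(r, m))
    }
  }
})

test_that("unit conversion and allele classification follow the field's rules", {
  expect_equal(unit_count(8750), 2187L)
  expect_equal(unit_count(40290), 10072L)
  expect_equal(unit_count(0), 0L)
  expect_error(unit_count(-4), "non-negative")

  expect_equal(classify_allele(24), "normal")
  expect_equal(classify_allele(50), "grey")
  expect_equal(classify_allele(75), "expanded")
  expect_equal(classify_allele(c(0, 25, 26, 27, 74, 11000)),
               c("normal", "grey", "grey", "grey", "grey", "expanded"))
  expect_equal(grey_boundary(c(24, 25, 26, 27)), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("segment_read applies run-length and ratio thresholds", {
  # pure run: one segment, ratio 1, exact units
  segs <- segment_region(strrep("CCTG", 8))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$end - segs$start, 32L)
  expect_equal(segs$match_ratio, 1)
  expect_equal(segs$units, 8L)

  # 3-unit TCTG tail (12 bp) stays unclassified; 4 units (16 bp) classify
  segs <- segment_region(paste0(strrep("CCTG", 8), strrep("TCTG", 3)))
  expect_equal(segs$label, "CCTG")
  segs <- segment_region(paste0(strrep("CCTG", 8), strrep("TCTG", 4)))
  expect_equal(segs$label, c("CCTG", "TCTG"))
  expect_equal(segs$start[segs$label == "TCTG"], 32L)

  # behaviour just above/below the match-ratio threshold: two (CCTG)x4
  # blocks joined by a gap; ratio 32/42 = 0.762 merges, 32/43 = 0.744 splits
  two_blocks <- function(gap) paste0(strrep("CCTG", 4), strrep("A", gap), strrep("CCTG", 4))
  segs <- segment_region(two_blocks(10), max_bridge = 12)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$end - segs$start, 42L)
  segs <- segment_region(two_blocks(11), max_bridge = 12)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$match_ratio, c(1, 1))

  # bridging is also capped by max_bridge regardless of ratio
  segs <- segment_region(two_blocks(10), max_bridge = 8)
  expect_equal(nrow(segs), 2L)

  # empty inter-flank region: zero segments, allele class normal
  ann <- segment_read(wrap_read(""))
  expect_equal(nrow(ann$segments), 0L)
  expect_equal(ann$allele_class, "normal")
})

test_that("classified and unclassified segments tile the inter-flank region", {
  set.seed(31)
  for (i in 1:30) {
    region <- fuzz_read(max_len = 200L)
    ann <- segment_read(wrap_read(region))
    segs <- ann$segments[order(ann$segments$start), ]
    if (nrow(segs) == 0L) {
      expect_equal(nchar(region), 0L)
      next
    }
    expect_equal(segs$start[1], 300L)
    expect_equal(segs$end[nrow(segs)], 300L + nchar(region))
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])   # no gaps, no overlap
    # per-motif totals equal the sum over that motif's segments
    for (m in c("CCTG", "TCTG")) {
      expect_equal(unname(ann$units[m]),
                   sum(segs$units[segs$label == m], na.rm = TRUE))
    }
  }
})

test_that("3'-TCTG flag requires a classified TCTG run past the CCTG array", {
  has3 <- function(region) segment_read(wrap_read(region))$has_3prime_tctg
  expect_true(has3(paste0(strrep("CCTG", 10), strrep("TCTG", 5))))
  expect_false(has3(strrep("CCTG", 10)))
  # wild-type-style 5' TCTG block only
  expect_false(has3(paste0(strrep("TCTG", 5), strrep("CCTG", 10))))
  # both: still true
  expect_true(has3(paste0(strrep("TCTG", 5), strrep("CCTG", 10), strrep("TCTG", 4))))
})

test_that("segmentation is invariant to read orientation", {
  fl <- default_flanks()
  anc <- flank_anchors(fl$flank5, fl$flank3)
  set.seed(41)
  for (i in 1:10) {
    region <- fuzz_read(max_len = 120L)
    read <- paste0(fl$flank5, region, fl$flank3)
    a_plus <- segment_read(orient_read(read, anc))
    a_minus <- segment_read(orient_read(revcomp(read), anc))
    expect_equal(a_plus$segments, a_minus$segments)
    expect_equal(a_plus$units, a_minus$units)
  }
})

test_that("raising minlength or minratio never adds classified bases", {
  # stricter thresholds shrink the feasible segment set, so the maximal
  # classified footprint can only shrink (segment counts may split up:
  # a merged run failing a stricter ratio decomposes into its sub-runs)
  classified_bp <- function(segs) sum(segs$end - segs$start)
  set.seed(51)
  regions <- replicate(8, fuzz_read(max_len = 150L))
  for (region in regions) {
    bp_prev <- Inf
    for (minlength in c(8, 16, 24, 32)) {
      bp <- classified_bp(segment_region(region, minlength = minlength))
      expect_lte(bp, bp_prev)
      bp_prev <- bp
    }
    bp_prev <- Inf
    for (minratio in c(0.5, 0.65, 0.75, 0.9, 1)) {
      bp <- classified_bp(segment_region(region, minratio = minratio))
      expect_lte(bp, bp_prev)
      bp_prev <- bp
    }
  }
})

test_that("segmentation equals the exhaustive reference on short reads", {
  set.seed(61)
  for (i in 1:300) {
    region <- fuzz_read(max_len = 64L)
    got <- segment_region(region)
    want <- oracle_segment(region)
    expect_equal(got$start, want$start, info = region)
    expect_equal(got$end, want$end, info = region)
    expect_equal(got$label, want$label, info = region)
  }
})

test_that("annotator defaults mirror the published parameters", {
  p <- annotator_params()
  expect_equal(p$minlength, 16L)
  expect_equal(p$minratio, 0.75)
  # the command-line percent convention maps onto the same fraction
  expect_equal(annotator_params(minratio = 75)$minratio, 0.75)
  expect_error(annotator_params(minlength = 2), "minlength")
  expect_error(annotator_params(minratio = 0), "minratio")
})
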