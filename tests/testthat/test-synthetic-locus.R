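test_that("build_allele assembles flanks and blocks with per-block truth", {
  spec <- allele_spec(list(), flank5 = strrep("A", 30), flank3 = strrep("G", 30))
  b <- build_allele(spec)
  expect_equal(b$sequence, paste0(strrep("A", 30), strrep("G", 30)))
  expect_equal(nrow(b$truth), 0L)

  spec <- allele_spec(motif_block("CCTG", 75), strrep("A", 30), strrep("G", 30))
  b <- build_allele(spec)
  expect_equal(nchar(b$sequence) - 60L, 300L)          # 75 x 4 bp
  expect_equal(b$truth$end - b$truth$start, 4L * b$truth$units)

  spec <- allele_spec(list(motif_block("CCTG", 10), motif_block("TCTG", 4)),
                      strrep("A", 30), strrep("G", 30))
  b <- build_allele(spec)
  expect_equal(nrow(b$truth), 2L)
  expect_equal(b$truth$motif[which.max(b$truth$start)], "TCTG")  # 3'-most

  expect_error(motif_block("CCUG", 5), "alphabet")
  expect_error(motif_block("CCT", 5), "length 4")
})

test_that("literal blocks contribute sequence but no truth segments", {
  spec <- allele_spec(list(literal_block(strrep("TG", 10)), motif_block("CCTG", 5)),
                      strrep("A", 30), strrep("G", 30))
  b <- build_allele(spec)
  expect_equal(nrow(b$truth), 1L)
  expect_equal(b$truth$start, 30L + 20L)
  expect_match(b$sequence, "^A{30}(TG){10}(CCTG){5}G{30}$")
})

test_that("expansion-length sampling honours family, truncation and seed", {
  m <- mosaic_model("fixed", location = 2000)
  expect_equal(sample_expansion_lengths(m, 5, seed = 1), rep(2000L, 5))

  m <- mosaic_model("lognormal", location = 5000, dispersion = 0.3, seed = 9)
  x <- sample_expansion_lengths(m, 1e4)
  expect_equal(x, sample_expansion_lengths(m, 1e4))            # reproducible
  expect_lt(abs(median(x) - 5000) / 5000, 0.02)                # Monte-Carlo

  m <- mosaic_model("lognormal", location = 100, dispersion = 0.5,
                    min_units = 75, max_units = 200)
  x <- sample_expansion_lengths(m, 2000, seed = 2)
  expect_true(all(x >= 75 & x <= 200))

  m <- mosaic_model("nbinom", location = 300, dispersion = 0.1)
  x <- sample_expansion_lengths(m, 5000, seed = 3)
  expect_lt(abs(mean(x) - 300) / 300, 0.1)

  expect_error(mosaic_model("weibull", 100))
  expect_error(sample_expansion_lengths(mosaic_model("fixed", 10), 0))
})

test_that("apply_errors matches binomial expectations and maps coordinates", {
  s <- strrep("CCTG", 50)
  id <- apply_errors(s, error_model(0, 0, 0), seed = 1)
  expect_equal(id$sequence, s)
  expect_equal(id$map, 0:(nchar(s) - 1L))

  # substitution-only at rate 1: every base differs
  mut <- apply_errors(s, error_model(1, 0, 0), seed = 2)
  expect_equal(nchar(mut$sequence), nchar(s))
  a <- strsplit(s, "")[[1]]; b <- strsplit(mut$sequence, "")[[1]]
  expect_equal(sum(a != b), nchar(s))

  # balanced indels: mean length change ~ 0 within 3 SE of the binomial
  set.seed(4)
  L <- 1e4
  s2 <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  deltas <- vapply(1:30, function(i) {
    nchar(apply_errors(s2, error_model(0, 0.02, 0.02), seed = i)$sequence) - L
  }, numeric(1))
  se <- sqrt(2 * L * 0.02 * 0.98 / 30)   # var of (ins - del) per replicate
  expect_lt(abs(mean(deltas)), 3 * se)

  # the coordinate map carries surviving bases to their mutated positions
  mut <- apply_errors(s, error_model(0, 0.05, 0.05), seed = 5)
  kept <- which(!is.na(mut$map))
  mb <- strsplit(mut$sequence, "")[[1]]
  expect_equal(mb[mut$map[kept] + 1L], strsplit(s, "")[[1]][kept])

  expect_error(error_model(-0.1, 0, 0), "rates")
})

test_that("simulate_read_set records assignment, strand and truth per read", {
  al <- dm2_allele(cctg = 100, tctg3 = 10, label = "expanded")
  sim <- simulate_read_set(list(expanded = al), n_reads = 50, seed = 1)
  expect_equal(nrow(sim$reads), 50L)
  expect_true(all(sim$reads$allele == "expanded"))

  # length conservation: pre-error read length = 4 * units + flanks + literals
  expect_true(all(nchar(sim$reads$sequence) ==
                    600L + 4L * (sim$reads$units_cctg_true + sim$reads$units_tctg_true)))

  # minus-strand truth is flipped and labels reverse-complemented
  minus_ids <- sim$reads$read_id[sim$reads$strand == "-"]
  tr <- sim$truth[sim$truth$read_id %in% minus_ids, ]
  expect_true(all(tr$motif %in% c("CAGG", "CAGA")))
  one <- sim$reads[sim$reads$strand == "-", ][1, ]
  t1 <- sim$truth[sim$truth$read_id == one$read_id, ]
  seg <- substring(one$sequence, t1$start + 1L, t1$end)
  expect_equal(seg, strrep(t1$motif, t1$units))

  # seeded determinism extends to the FASTQ bytes
  sim2 <- simulate_read_set(list(expanded = al), n_reads = 50, seed = 1)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_simulated_fastq(sim, f1); write_simulated_fastq(sim2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # strand fraction behaves binomially
  sim3 <- simulate_read_set(list(expanded = dm2_allele(cctg = 10, label = "expanded")),
                            n_reads = 1e4, strand_fraction = 0.5, seed = 7)
  expect_lt(abs(mean(sim3$reads$strand == "-") - 0.5), 3 * sqrt(0.25 / 1e4))

  # exact-count stratified assignment
  al2 <- dm2_allele(cctg = 100, label = "pure")
  sim4 <- simulate_read_set(list(expanded = al, pure = al2), n_reads = 50,
                            counts = c(expanded = 1, pure = 49), seed = 1)
  expect_equal(sum(sim4$reads$allele == "expanded"), 1L)
  expect_error(simulate_read_set(list(expanded = al), n_reads = 0), "n_reads")
  expect_error(simulate_read_set(list(expanded = al), n_reads = 10,
                                 weights = c(expanded = 0.5)), "sum to 1")
})

test_that("zero-error round trip: segmentation recovers simulator truth", {
  al <- list(a = dm2_allele(cctg = 40, tctg3 = 8, label = "a"),
             b = dm2_allele(cctg = 90, label = "b"))
  sim <- simulate_read_set(al, n_reads = 20, seed = 3)
  fl <- default_flanks()
  cr <- extract_complete_reads(sim, flank_anchors(fl$flank5, fl$flank3))
  expect_equal(length(cr$kept), 20L)
  ann <- annotate_reads(cr)
  m <- merge(ann$per_read, sim$reads[, c("read_id", "units_cctg_true", "units_tctg_true")])
  expect_equal(m$units_cctg, m$units_cctg_true)
  expect_equal(m$units_tctg, m$units_tctg_true)
})
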