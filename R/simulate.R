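#' Simulate a set of locus-spanning long reads with known ground truth
#'
#' Draws each read from one of the supplied alleles (multinomial `weights`
#' or exact per-allele `counts`), optionally redraws the mosaic-flagged
#' block's unit count from a [mosaic_model()], assigns a strand, truncates a
#' configurable fraction of reads so that they no longer span both flanks,
#' and finally applies an [error_model()].
#'
#' Ground truth is reported on the error-free read in its stored
#' orientation: for minus-strand reads the coordinates are flipped and motif
#' labels reverse-complemented. Per-read locus-frame unit totals
#' (`units_cctg_true`, `units_tctg_true`) are also recorded so downstream
#' recovery can be scored without coordinate arithmetic, and the per-read
#' pre- to post-error coordinate maps are kept so scoring tolerates indel
#' shifts.
#'
#' @param alleles named list of [allele_spec()] objects (a single spec is
#'   accepted).
#' @param n_reads number of reads (>= 1).
#' @param weights named numeric mixing weights summing to 1 (multinomial
#'   assignment); ignored when `counts` is given.
#' @param counts named integer vector of exact per-allele read counts
#'   summing to `n_reads` (deterministic, stratified assignment).
#' @param mosaic optional [mosaic_model()] applied to the mosaic-flagged
#'   block of each allele.
#' @param errors optional [error_model()]; `NULL` keeps reads error-free.
#' @param strand_fraction probability that a read is stored on the minus
#'   strand (reverse-complemented).
#' @param incomplete_fraction fraction of reads truncated inside the repeat
#'   region so that one flank is lost.
#' @param seed RNG seed for the whole simulation.
#' @return a `sim_read_set`: list with `reads` (data.frame: read_id,
#'   sequence, strand, allele, complete, units_cctg_true, units_tctg_true),
#'   `truth` (data.frame: read_id, start, end, motif, units; error-free read
#'   coordinates), and `maps` (per-read coordinate maps, `NULL` when no
#'   error model was applied).
#' @export
simulate_read_set <- function(alleles, n_reads, weights = NULL, counts = NULL,
                              mosaic = NULL, errors = NULL,
                              strand_fraction = 0.5,
                              incomplete_fraction = 0, seed = NULL) {
  if (inherits(alleles, "allele_spec")) alleles <- list(alleles)
  if (is.null(names(alleles)) || any(names(alleles) == "")) {
    names(alleles) <- vapply(alleles, function(a) a$label, "")
  }
  stopifnot(all(vapply(alleles, inherits, TRUE, "allele_spec")))
  if (length(n_reads) != 1L || is.na(n_reads) || n_reads < 1) {
    stop("n_reads must be >= 1", call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  if (!is.null(counts)) {
    if (!setequal(names(counts), names(alleles)) || sum(counts) != n_reads) {
      stop("counts must name every allele and sum to n_reads", call. = FALSE)
    }
  } else {
    if (is.null(weights)) weights <- stats::setNames(rep(1, length(alleles)) / length(alleles),
                                                     names(alleles))
    if (!setequal(names(weights), names(alleles))) {
      stop("weights must name every allele", call. = FALSE)
    }
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  }
  stopifnot(strand_fraction >= 0, strand_fraction <= 1,
            incomplete_fraction >= 0, incomplete_fraction <= 1)

  with_seed(seed, {
    assign_allele <- if (!is.null(counts)) {
      rep(names(counts), times = counts[names(counts)])
    } else {
      sample(names(alleles), n_reads, replace = TRUE, prob = weights[names(alleles)])
    }
    minus <- runif(n_reads) < strand_fraction
    truncate <- runif(n_reads) < incomplete_fraction

    seqs <- character(n_reads)
    ucctg <- utctg <- integer(n_reads)
    truths <- vector("list", n_reads)
    maps <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      spec <- alleles[[assign_allele[i]]]
      if (!is.null(mosaic)) {
        k <- which(vapply(spec$blocks, function(b) b$mosaic, TRUE))
        if (length(k) == 1L) {
          spec$blocks[[k]]$units <- .sample_units(mosaic, 1L)
        }
      }
      built <- build_allele(spec)
      seq_i <- built$sequence
      truth <- built$truth
      units_cctg <- sum(truth$units[truth$motif == "CCTG"])
      units_tctg <- sum(truth$units[truth$motif == "TCTG"])

      if (truncate[i]) {
        rep_start <- nchar(spec$flank5)
        rep_end <- nchar(seq_i) - nchar(spec$flank3)
        cut <- rep_start + floor(runif(1) * max(1L, rep_end - rep_start))
        if (runif(1) < 0.5) {          # lose 5' flank
          seq_i <- substr(seq_i, cut + 1L, nchar(seq_i))
          truth$start <- pmax(truth$start - cut, 0L)
          truth$end <- pmax(truth$end - cut, 0L)
        } else {                       # lose 3' flank
          seq_i <- substr(seq_i, 1L, cut)
          truth$start <- pmin(truth$start, cut)
          truth$end <- pmin(truth$end, cut)
        }
        truth <- truth[truth$end > truth$start, , drop = FALSE]
        truth$units <- (truth$end - truth$start) %/% 4L
      }

      if (minus[i]) {
        L <- nchar(seq_i)
        seq_i <- .revcomp1(seq_i)
        if (nrow(truth)) {
          new_start <- L - truth$end
          truth$end <- L - truth$start
          truth$start <- new_start
          truth$motif <- vapply(truth$motif, .revcomp1, "", USE.NAMES = FALSE)
          truth <- truth[order(truth$start), , drop = FALSE]
        }
      }

      map_i <- NULL
      if (!is.null(errors)) {
        mut <- .mutate(seq_i, errors)
        seq_i <- mut$sequence
        map_i <- mut$map
      }
      id <- sprintf("read_%05d", i)
      seqs[i] <- seq_i
      ucctg[i] <- units_cctg
      utctg[i] <- units_tctg
      if (nrow(truth)) truth <- cbind(read_id = id, truth)
      truths[[i]] <- truth
      maps[[i]] <- map_i
    }
    reads_df <- data.frame(read_id = sprintf("read_%05d", seq_len(n_reads)),
                           sequence = seqs,
                           strand = ifelse(minus, "-", "+"),
                           allele = assign_allele,
                           complete = !truncate,
                           units_cctg_true = ucctg,
                           units_tctg_true = utctg,
                           stringsAsFactors = FALSE)
    truth_all <- do.call(rbind, truths[vapply(truths, nrow, 1L) > 0])
    if (is.null(truth_all)) {
      truth_all <- data.frame(read_id = character(), start = integer(),
                              end = integer(), motif = character(),
                              units = integer(), stringsAsFactors = FALSE)
    }
    rownames(truth_all) <- NULL
    res <- list(reads = reads_df, truth = truth_all,
                maps = if (is.null(errors)) NULL else maps)
    class(res) <- "sim_read_set"
    res
  })
}

#' @export
print.sim_read_set <- function(x, ...) {
  cat(sprintf("sim_read_set: %d reads (%d complete), %d truth segments\n",
              nrow(x$reads), sum(x$reads$complete), nrow(x$truth)))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' One record per read with placeholder qualities (`I`, Phred 40). Gzip
#' output is selected by a `.gz` suffix.
#'
#' @param sim a `sim_read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulated_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "sim_read_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", sim$reads$read_id),
                           sim$reads$sequence,
                           "+",
                           strrep("I", nchar(sim$reads$sequence))))
  writeLines(lines, con)
  invisible(path)
}

#' Write simulator ground truth as BED-like TSV
#'
#' Columns: read_id, start, end (0-based half-open on the error-free read),
#' motif, units.
#'
#' @param sim a `sim_read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_read_set"))
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ (plain or gzip)
#'
#' @param path input path; the format is inferred from the file name
#'   (`.fq`/`.fastq` means FASTQ, anything else FASTA).
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Import reads overlapping a locus from SAM/BAM
#'
#' Returns the full read sequences (soft-clipped bases included) of primary
#' alignments overlapping the given interval. SAM input is converted with
#' Rsamtools on the fly.
#'
#' @param path SAM or BAM file.
#' @param region locus interval string `"chrom:start-end"` (1-based closed).
#' @return named character vector of read sequences.
#' @export
read_sam_reads <- function(path, region) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM input", call. = FALSE)
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must look like 'chrom:start-end'", call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)  # sorts + indexes
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  which <- GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]), as.integer(m[4])))
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq"), which = which,
                                   flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                                                 isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  stats::setNames(as.character(res$seq), res$qname)
}
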