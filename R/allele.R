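#' Describe a block of a simulated CNBP repeat allele
#'
#' An allele is an ordered list of blocks between two flanks. A quadruplet
#' block is `unit_count` tandem copies of a 4-letter motif (e.g. CCTG); a
#' literal block is an arbitrary stretch such as the dinucleotide (TG)v run
#' 5' of the repeat array. Only quadruplet blocks appear in simulator ground
#' truth.
#'
#' @param motif 4-letter motif over A/C/G/T (ignored for literal blocks).
#' @param units non-negative integer number of tandem copies.
#' @param mosaic logical; if `TRUE` the block's unit count is redrawn per
#'   simulated read from the mosaicism model (see [simulate_read_set()]).
#' @return a block object (list) for use in [allele_spec()].
#' @seealso [literal_block()], [allele_spec()], [dm2_allele()]
#' @export
motif_block <- function(motif, units, mosaic = FALSE) {
  motif <- .assert_dna(motif, "motif")
  if (nchar(motif) != 4L) stop("motif must have length 4", call. = FALSE)
  if (length(units) != 1L || is.na(units) || units < 0 || units != floor(units)) {
    stop("units must be a single non-negative integer", call. = FALSE)
  }
  structure(list(motif = motif, units = as.integer(units), literal = FALSE,
                 mosaic = isTRUE(mosaic)),
            class = "allele_block")
}

#' @param sequence literal nucleotide sequence of the block.
#' @rdname motif_block
#' @export
literal_block <- function(sequence) {
  sequence <- .assert_dna(sequence, "literal block sequence")
  structure(list(motif = sequence, units = 1L, literal = TRUE, mosaic = FALSE),
            class = "allele_block")
}

#' Ordered motif-block description of a simulated CNBP allele
#'
#' @param blocks list of blocks from [motif_block()] / [literal_block()],
#'   ordered 5' to 3'.
#' @param flank5,flank3 flanking sequences (required non-empty when reads are
#'   to be harvested by flank anchoring).
#' @param label text identifier carried through to simulated reads.
#' @return an `allele_spec` object.
#' @export
allele_spec <- function(blocks, flank5, flank3, label = "allele") {
  if (inherits(blocks, "allele_block")) blocks <- list(blocks)
  if (!is.list(blocks) || !all(vapply(blocks, inherits, TRUE, "allele_block"))) {
    stop("blocks must be a list of allele_block objects", call. = FALSE)
  }
  flank5 <- .assert_dna(flank5, "flank5")
  flank3 <- .assert_dna(flank3, "flank3")
  if (sum(vapply(blocks, function(b) b$mosaic, TRUE)) > 1L) {
    stop("at most one block may be flagged mosaic", call. = FALSE)
  }
  structure(list(blocks = blocks, flank5 = flank5, flank3 = flank3,
                 label = as.character(label)),
            class = "allele_spec")
}

#' Convenience constructor for DM2-locus allele structures
#'
#' Builds the conventional (TG)v (TCTG)w (CCTG)n \[(TCTG)m\] architecture of
#' the CNBP repeat locus: an optional dinucleotide run and wild-type-style 5'
#' TCTG block, the (optionally expanded) CCTG array, and an optional 3' TCTG
#' block of the kind found at the distal end of most expanded DM2 alleles.
#' The CCTG block is flagged `mosaic` so its per-read length can be drawn
#' from a mosaicism model.
#'
#' @param cctg units in the (CCTG)n array.
#' @param tctg3 units in the 3' (TCTG)m block (0 = "pure" CCTG allele).
#' @param tg,tctg5 units in the wild-type 5' (TG)v run and (TCTG)w block.
#' @param flank5,flank3 flank sequences; defaults to the packaged synthetic
#'   flank fixture (see [default_flanks()]).
#' @param label allele label.
#' @return an [allele_spec()] object.
#' @export
dm2_allele <- function(cctg, tctg3 = 0, tg = 0, tctg5 = 0,
                       flank5 = NULL, flank3 = NULL, label = "expanded") {
  if (is.null(flank5) || is.null(flank3)) {
    fl <- default_flanks()
    if (is.null(flank5)) flank5 <- fl$flank5
    if (is.null(flank3)) flank3 <- fl$flank3
  }
  blocks <- list()
  if (tg > 0) blocks <- c(blocks, list(literal_block(strrep("TG", tg))))
  if (tctg5 > 0) blocks <- c(blocks, list(motif_block("TCTG", tctg5)))
  blocks <- c(blocks, list(motif_block("CCTG", cctg, mosaic = TRUE)))
  if (tctg3 > 0) blocks <- c(blocks, list(motif_block("TCTG", tctg3)))
  allele_spec(blocks, flank5, flank3, label = label)
}

#' Synthetic default flanks for the simulated locus
#'
#' 300 bp random sequences shipped as a plain-text FASTA fixture
#' (`extdata/flanks_synthetic.fa`); they stand in for the real hg38 flanks,
#' which users can supply as FASTA instead.
#'
#' @return list with elements `flank5` and `flank3`.
#' @export
default_flanks <- function() {
  path <- system.file("extdata", "flanks_synthetic.fa", package = "cnbpmosaic")
  seqs <- Biostrings::readDNAStringSet(path)
  list(flank5 = as.character(seqs[["flank5"]]),
       flank3 = as.character(seqs[["flank3"]]))
}

#' Assemble an allele sequence and its ground-truth segments
#'
#' Concatenates `flank5 + blocks + flank3` and emits one truth segment per
#' quadruplet block with at least one unit. Truth coordinates are 0-based
#' half-open on the assembled (error-free) sequence.
#'
#' @param spec an [allele_spec()].
#' @return list with `sequence` (character scalar) and `truth` (data.frame
#'   with columns `start`, `end`, `motif`, `units`).
#' @export
build_allele <- function(spec) {
  stopifnot(inherits(spec, "allele_spec"))
  pos <- nchar(spec$flank5)
  pieces <- character(length(spec$blocks))
  truth <- vector("list", length(spec$blocks))
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    seq_i <- if (b$literal) b$motif else strrep(b$motif, b$units)
    pieces[i] <- seq_i
    if (!b$literal && b$units >= 1L) {
      truth[[i]] <- data.frame(start = pos, end = pos + 4L * b$units,
                               motif = b$motif, units = b$units,
                               stringsAsFactors = FALSE)
    }
    pos <- pos + nchar(seq_i)
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth)) {
    truth <- data.frame(start = integer(), end = integer(),
                        motif = character(), units = integer(),
                        stringsAsFactors = FALSE)
  }
  list(sequence = paste0(spec$flank5, paste(pieces, collapse = ""), spec$flank3),
       truth = truth)
}
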