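#' Quadruplet motif alphabet
#'
#' Ordered motif list with priority rank used to break residual ties during
#' segmentation. The wild-type CNBP locus is interrupted by NCTG variants
#' (GCTG, TCTG, ACTG), but the expanded-allele analysis uses only CCTG and
#' TCTG, so the variant motifs are opt-in.
#'
#' @param include_nctg also include the GCTG and ACTG variant motifs.
#' @return character vector of motifs in priority order (class
#'   `motif_alphabet`).
#' @export
motif_alphabet <- function(include_nctg = FALSE) {
  motifs <- if (include_nctg) c("CCTG", "TCTG", "GCTG", "ACTG") else c("CCTG", "TCTG")
  structure(motifs, class = "motif_alphabet")
}

#' Annotation thresholds for motif segmentation
#'
#' A run of a motif is classified only when it is at least `minlength` bp
#' long (four contiguous quadruplet units, >= 16 bp, under the default) and
#' at least a fraction `minratio` of its bases lie inside exact in-phase
#' occurrences of the motif. Uncovered gaps up to `max_bridge` bp are
#' absorbed inside a run provided the run's ratio stays above threshold;
#' the default of two quadruplets absorbs isolated sequencing errors without
#' merging distinct motif blocks.
#'
#' @param minlength minimum classified run length in bp (default 16).
#' @param minratio minimum in-phase match fraction (default 0.75); values
#'   above 1 are interpreted as percent, mirroring the `-minratio 75`
#'   command-line convention.
#' @param max_bridge maximum internal uncovered gap absorbed in a run (bp).
#' @param alphabet a [motif_alphabet()] (or character vector of distinct
#'   4-mers in priority order).
#' @return an `annotator_params` object.
#' @export
annotator_params <- function(minlength = 16, minratio = 0.75, max_bridge = 8,
                             alphabet = motif_alphabet()) {
  if (minratio > 1) minratio <- minratio / 100
  if (minlength < 4) stop("minlength must be >= 4 bp", call. = FALSE)
  if (minratio <= 0 || minratio > 1) stop("minratio must lie in (0, 1]", call. = FALSE)
  if (max_bridge < 0) stop("max_bridge must be >= 0", call. = FALSE)
  alphabet <- vapply(alphabet, .assert_dna, "", what = "motif")
  if (any(nchar(alphabet) != 4L) || anyDuplicated(alphabet)) {
    stop("alphabet motifs must be distinct 4-mers", call. = FALSE)
  }
  structure(list(minlength = as.integer(minlength), minratio = minratio,
                 max_bridge = as.integer(max_bridge),
                 alphabet = unname(alphabet)),
            class = "annotator_params")
}

#' Per-base motif coverage mask
#'
#' A position is covered iff it lies inside at least one exact occurrence of
#' the 4-mer motif, at any phase.
#'
#' @param sequence nucleotide sequence.
#' @param motif 4-mer motif.
#' @return logical vector of length `nchar(sequence)`.
#' @export
phase_profile <- function(sequence, motif) {
  sequence <- .assert_dna(sequence, "sequence")
  motif <- .assert_dna(motif, "motif")
  if (nchar(motif) != 4L) stop("motif must have length 4", call. = FALSE)
  cpp_motif_mask(sequence, motif)
}

#' Convert a span in bp to quadruplet units
#'
#' @param span_bp span in base pairs (>= 0).
#' @return `floor(span_bp / 4)` (vectorised).
#' @export
unit_count <- function(span_bp) {
  if (any(is.na(span_bp)) || any(span_bp < 0)) {
    stop("span must be non-negative", call. = FALSE)
  }
  as.integer(span_bp %/% 4)
}

#' Classify an allele by its CCTG unit count
#'
#' Stable normal alleles carry fewer than 25 CCTG units; the unstable "grey
#' area" spans 27-74 units; pathogenic expansions start at about 75 units.
#' The 25-26 unit gap left between the published class boundaries is
#' assigned to the grey class (flag it with [grey_boundary()]).
#'
#' @param units total CCTG units (vectorised, >= 0).
#' @return character vector: `"normal"`, `"grey"` or `"expanded"`.
#' @export
classify_allele <- function(units) {
  if (any(is.na(units)) || any(units < 0)) stop("units must be >= 0", call. = FALSE)
  ifelse(units < 25, "normal", ifelse(units < 75, "grey", "expanded"))
}

#' @rdname classify_allele
#' @return `grey_boundary()`: logical, `TRUE` for the 25-26 unit counts that
#'   fall between the published normal and grey-zone boundaries.
#' @export
grey_boundary <- function(units) units %in% c(25L, 26L)

# Segment a bare repeat-region sequence. Returns the full tiling (classified
# runs + UNCLASSIFIED gaps) with coordinates offset by `offset`.
segment_sequence <- function(sequence, params = annotator_params(), offset = 0L) {
  stopifnot(inherits(params, "annotator_params"))
  L <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), label = character(),
                      match_ratio = numeric(), units = integer(),
                      stringsAsFactors = FALSE)
  if (L == 0L) return(empty)
  masks <- lapply(params$alphabet, function(m) cpp_motif_mask(sequence, m))
  seg <- cpp_segment(masks, params$minlength, params$minratio, params$max_bridge)
  segs <- if (nrow(seg)) {
    data.frame(start = seg[, "start"], end = seg[, "end"],
               label = params$alphabet[seg[, "motif"]],
               match_ratio = seg[, "matched"] / (seg[, "end"] - seg[, "start"]),
               units = (seg[, "end"] - seg[, "start"]) %/% 4L,
               stringsAsFactors = FALSE)
  } else empty
  # tile the residue with UNCLASSIFIED segments
  bounds <- rbind(c(NA, 0L), cbind(segs$start, segs$end), c(L, NA))
  gaps <- data.frame(start = bounds[-nrow(bounds), 2], end = bounds[-1, 1])
  gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  if (nrow(gaps)) {
    gaps <- data.frame(start = gaps$start, end = gaps$end,
                       label = "UNCLASSIFIED", match_ratio = NA_real_,
                       units = NA_integer_, stringsAsFactors = FALSE)
    segs <- rbind(segs, gaps)
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  segs$start <- segs$start + offset
  segs$end <- segs$end + offset
  rownames(segs) <- NULL
  segs
}

#' Segment an oriented read into classified motif runs
#'
#' Segments the inter-flank region of an oriented read into maximal
#' classified quadruplet-motif runs and unclassified gaps, then derives the
#' per-read summary: per-motif unit totals, the 3'-TCTG flag and the allele
#' class (from total CCTG units).
#'
#' The segmentation is the optimum of an explicit objective: legal runs must
#' start and end on motif-covered bases, contain no uncovered gap longer
#' than `max_bridge`, satisfy the `minratio` and `minlength` thresholds, and
#' among legal tilings the annotator maximises total classified bp, then
#' total matched bp, then uses the fewest segments (residual ties prefer the
#' earlier, longer, higher-priority run).
#'
#' @param read an `oriented_read` from [orient_read()] (or any list with
#'   `sequence`, `anchor5`, `anchor3`, `read_id`).
#' @param params an [annotator_params()].
#' @return a `read_annotation`: list with `read_id`, `expansion_span_bp`,
#'   `segments` (data.frame tiling the inter-flank region), `units` (named
#'   per-motif totals), `unclassified_bp`, `has_3prime_tctg`, `allele_class`
#'   and `grey_boundary`.
#' @export
segment_read <- function(read, params = annotator_params()) {
  stopifnot(!is.null(read$sequence), !is.null(read$anchor5), !is.null(read$anchor3))
  from <- read$anchor5$end
  to <- read$anchor3$start
  if (to < from) stop("malformed read: anchors overlap", call. = FALSE)
  region <- substr(read$sequence, from + 1L, to)
  segs <- segment_sequence(region, params, offset = from)
  units <- vapply(params$alphabet, function(m) {
    sum(segs$units[segs$label == m], na.rm = TRUE)
  }, integer(1))
  ann <- structure(list(
    read_id = if (is.null(read$read_id)) "read" else read$read_id,
    expansion_span_bp = to - from,
    segments = segs,
    units = units,
    unclassified_bp = sum(segs$end[segs$label == "UNCLASSIFIED"] -
                            segs$start[segs$label == "UNCLASSIFIED"]),
    allele_class = classify_allele(sum(units["CCTG"], na.rm = TRUE)),
    grey_boundary = grey_boundary(sum(units["CCTG"], na.rm = TRUE))
  ), class = "read_annotation")
  ann$has_3prime_tctg <- has_3prime_tctg(ann)
  ann
}

#' Does a read carry a classified TCTG block 3' of the CCTG array?
#'
#' `TRUE` iff a classified TCTG segment starts 3' of the end of the 3'-most
#' classified CCTG segment. Wild-type-style 5' TCTG blocks therefore do not
#' count, and the flag is `FALSE` when no CCTG segment was classified (there
#' is then no array to be 3' of).
#'
#' @param annotation a `read_annotation` from [segment_read()].
#' @return logical scalar.
#' @export
has_3prime_tctg <- function(annotation) {
  segs <- annotation$segments
  cctg_end <- segs$end[segs$label == "CCTG"]
  if (length(cctg_end) == 0L) return(FALSE)
  any(segs$label == "TCTG" & segs$start >= max(cctg_end))
}

#' Annotate a set of complete reads
#'
#' @param reads a `complete_reads` object from [extract_complete_reads()]
#'   (or a list of `oriented_read`s).
#' @param params an [annotator_params()].
#' @return a `read_annotations` object: list with `per_read` (one row per
#'   read: read_id, expansion_span_bp, units per motif, unclassified_bp,
#'   has_3prime_tctg, allele_class, grey_boundary), `segments` (all segment
#'   rows with read_id) and `params`.
#' @export
annotate_reads <- function(reads, params = annotator_params()) {
  if (inherits(reads, "complete_reads")) reads <- reads$kept
  if (inherits(reads, "oriented_read")) reads <- list(reads)
  anns <- lapply(reads, segment_read, params = params)
  if (length(anns) == 0L) {
    per_read <- data.frame(read_id = character(), expansion_span_bp = integer(),
                           stringsAsFactors = FALSE)
    for (m in params$alphabet) per_read[[paste0("units_", tolower(m))]] <- integer()
    per_read$units_total <- integer()
    per_read$unclassified_bp <- integer()
    per_read$has_3prime_tctg <- logical()
    per_read$allele_class <- character()
    per_read$grey_boundary <- logical()
    return(structure(list(per_read = per_read,
                          segments = data.frame(read_id = character(),
                                                start = integer(), end = integer(),
                                                label = character(),
                                                match_ratio = numeric(),
                                                units = integer(),
                                                stringsAsFactors = FALSE),
                          params = params),
                     class = "read_annotations"))
  }
  per_read <- do.call(rbind, lapply(anns, function(a) {
    row <- data.frame(read_id = a$read_id,
                      expansion_span_bp = a$expansion_span_bp,
                      stringsAsFactors = FALSE)
    for (m in params$alphabet) row[[paste0("units_", tolower(m))]] <- a$units[[m]]
    row$units_total <- sum(a$units)
    row$unclassified_bp <- a$unclassified_bp
    row$has_3prime_tctg <- a$has_3prime_tctg
    row$allele_class <- a$allele_class
    row$grey_boundary <- a$grey_boundary
    row
  }))
  segments <- do.call(rbind, lapply(anns, function(a) {
    if (nrow(a$segments) == 0L) return(NULL)
    cbind(read_id = a$read_id, a$segments)
  }))
  if (is.null(segments)) {
    segments <- data.frame(read_id = character(), start = integer(),
                           end = integer(), label = character(),
                           match_ratio = numeric(), units = integer(),
                           stringsAsFactors = FALSE)
  }
  rownames(segments) <- NULL
  structure(list(per_read = per_read, segments = segments, params = params),
            class = "read_annotations")
}

#' @export
print.read_annotations <- function(x, ...) {
  cat(sprintf("read_annotations: %d reads, %d segments (params: minlength=%d, minratio=%g)\n",
              nrow(x$per_read), nrow(x$segments),
              x$params$minlength, x$params$minratio))
  invisible(x)
}
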