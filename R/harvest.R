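#' Flank anchor parameters for spanning-read extraction
#'
#' A read is "complete" when both flank sequences of the repeat region can
#' be placed in it (in one consistent orientation) by semi-global alignment
#' within an edit-distance budget proportional to the flank length.
#'
#' @param flank5,flank3 flank sequences (>= 20 bp each).
#' @param max_edit_fraction maximum edit distance as a fraction of the flank
#'   length, in \[0, 0.5).
#' @param search_both_strands also try the reverse complement of each read.
#' @return a `flank_anchors` object.
#' @export
flank_anchors <- function(flank5, flank3, max_edit_fraction = 0.2,
                          search_both_strands = TRUE) {
  flank5 <- .assert_dna(flank5, "flank5")
  flank3 <- .assert_dna(flank3, "flank3")
  if (nchar(flank5) < 20L || nchar(flank3) < 20L) {
    stop("flanks must be at least 20 bp", call. = FALSE)
  }
  if (max_edit_fraction < 0 || max_edit_fraction >= 0.5) {
    stop("max_edit_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(flank5 = flank5, flank3 = flank3,
                 max_edit_fraction = max_edit_fraction,
                 search_both_strands = isTRUE(search_both_strands)),
            class = "flank_anchors")
}

#' Locate a flank in a read by semi-global alignment
#'
#' Returns the minimum-edit-distance placement of `flank` inside
#' `sequence`, or `NULL` if the best distance exceeds
#' `max_edit_fraction * nchar(flank)`. Ties are broken towards the leftmost
#' placement (`prefer = "left"`, appropriate for a 5' flank) or the
#' rightmost (`prefer = "right"`, for a 3' flank), conservatively maximising
#' the enclosed span.
#'
#' @param sequence read sequence.
#' @param flank flank sequence.
#' @param max_edit_fraction edit-distance budget as a fraction of the flank
#'   length.
#' @param prefer tie-break direction.
#' @return list with `start`, `end` (0-based half-open) and `edit`, or
#'   `NULL` when no placement is within budget.
#' @export
find_anchor <- function(sequence, flank, max_edit_fraction = 0.2,
                        prefer = c("left", "right")) {
  prefer <- match.arg(prefer)
  hit <- cpp_semiglobal_anchor(flank, sequence, prefer == "right")
  if (anyNA(hit) || hit[3] > max_edit_fraction * nchar(flank)) return(NULL)
  list(start = hit[1], end = hit[2], edit = hit[3])
}

# Windowed anchor search: look only in the outer portion of the read
# (flanks of spanning reads sit near the ends); `window = FALSE` scans the
# whole read.
.find_anchor_windowed <- function(sequence, flank, max_edit_fraction, side,
                                  window = TRUE) {
  L <- nchar(sequence)
  w <- as.integer(max(4L * nchar(flank), ceiling(L * 0.25)))
  prefer <- if (side == "5") "left" else "right"
  if (!window || w >= L) {
    return(find_anchor(sequence, flank, max_edit_fraction, prefer))
  }
  if (side == "5") {
    find_anchor(substr(sequence, 1L, w), flank, max_edit_fraction, prefer)
  } else {
    off <- L - w
    hit <- find_anchor(substr(sequence, off + 1L, L), flank, max_edit_fraction, prefer)
    if (!is.null(hit)) {
      hit$start <- hit$start + off
      hit$end <- hit$end + off
    }
    hit
  }
}

.anchor_pair <- function(sequence, anchors, window = TRUE, prior = NULL) {
  a5 <- if (!is.null(prior$a5)) prior$a5 else
    .find_anchor_windowed(sequence, anchors$flank5, anchors$max_edit_fraction, "5", window)
  a3 <- if (!is.null(prior$a3)) prior$a3 else
    .find_anchor_windowed(sequence, anchors$flank3, anchors$max_edit_fraction, "3", window)
  list(a5 = a5, a3 = a3)
}

#' Orient a read on the plus strand of the repeat locus
#'
#' Searches for both flanks on the read as given and (optionally) on its
#' reverse complement. Minus-orientation reads are reverse-complemented so
#' that the 5' flank precedes the 3' flank. Reads whose anchors are found in
#' conflicting or ambiguous orientations, with a missing flank, or with
#' overlapping anchors are rejected with a reason code.
#'
#' @param sequence read sequence.
#' @param anchors a [flank_anchors()].
#' @param read_id identifier carried into the result.
#' @return an `oriented_read` (list: read_id, sequence, anchor5, anchor3,
#'   orientation, expansion_span_bp), or a list with a `reason` element when
#'   the read is rejected.
#' @export
orient_read <- function(sequence, anchors, read_id = "read") {
  stopifnot(inherits(anchors, "flank_anchors"))
  sequence <- .assert_dna(sequence, "sequence")
  rc <- if (anchors$search_both_strands) .revcomp1(sequence) else NULL
  # cheap pass over the outer windows of both orientations first; fall back
  # to full scans only when neither orientation anchors completely
  plus <- .anchor_pair(sequence, anchors)
  minus <- if (is.null(rc)) list(a5 = NULL, a3 = NULL) else .anchor_pair(rc, anchors)
  if ((is.null(plus$a5) || is.null(plus$a3)) &&
      (is.null(minus$a5) || is.null(minus$a3))) {
    plus <- .anchor_pair(sequence, anchors, window = FALSE, prior = plus)
    if (!is.null(rc)) minus <- .anchor_pair(rc, anchors, window = FALSE, prior = minus)
  }

  ok_plus <- !is.null(plus$a5) && !is.null(plus$a3)
  ok_minus <- !is.null(minus$a5) && !is.null(minus$a3)
  if (ok_plus && ok_minus) {
    return(list(read_id = read_id, reason = "ambiguous orientation"))
  }
  if (!ok_plus && !ok_minus) {
    any5 <- !is.null(plus$a5) || !is.null(minus$a5)
    any3 <- !is.null(plus$a3) || !is.null(minus$a3)
    reason <- if (!any5 && !any3) "no anchors"
      else if (any5 && !any3) "no 3' anchor"
      else if (!any5 && any3) "no 5' anchor"
      else "conflicting orientations"
    return(list(read_id = read_id, reason = reason))
  }
  if (ok_plus) {
    pair <- plus; seq_out <- sequence; orientation <- "+"
  } else {
    pair <- minus; seq_out <- rc; orientation <- "-"
  }
  if (pair$a5$end > pair$a3$start) {
    return(list(read_id = read_id, reason = "anchors overlap"))
  }
  structure(list(read_id = read_id, sequence = seq_out,
                 anchor5 = pair$a5, anchor3 = pair$a3,
                 orientation = orientation,
                 expansion_span_bp = pair$a3$start - pair$a5$end),
            class = "oriented_read")
}

#' Inter-flank expansion span of an oriented read
#'
#' @param read an `oriented_read`.
#' @return span in bp (3' anchor start minus 5' anchor end).
#' @export
expansion_span <- function(read) {
  stopifnot(inherits(read, "oriented_read"))
  span <- read$anchor3$start - read$anchor5$end
  if (span < 0) stop("malformed read: anchors overlap", call. = FALSE)
  span
}

#' Extract complete (locus-spanning) reads
#'
#' Applies [orient_read()] to every input read; a read is kept iff both
#' flanks anchor in one consistent orientation. Every input read appears
#' exactly once, either in the kept list or in the rejection log.
#'
#' @param reads named character vector of read sequences (or a
#'   `sim_read_set`, whose reads are used).
#' @param anchors a [flank_anchors()].
#' @return a `complete_reads` object: list with `kept` (list of
#'   `oriented_read`), `table` (data.frame of anchor coordinates and spans),
#'   and `rejected` (data.frame: read_id, reason).
#' @export
extract_complete_reads <- function(reads, anchors) {
  if (inherits(reads, "sim_read_set")) {
    reads <- stats::setNames(reads$reads$sequence, reads$reads$read_id)
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d", seq_along(reads))
  kept <- list()
  rej <- list()
  for (i in seq_along(reads)) {
    r <- orient_read(reads[[i]], anchors, read_id = names(reads)[i])
    if (inherits(r, "oriented_read")) {
      kept[[length(kept) + 1L]] <- r
    } else {
      rej[[length(rej) + 1L]] <- data.frame(read_id = r$read_id,
                                            reason = r$reason,
                                            stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(kept)) {
    do.call(rbind, lapply(kept, function(r) {
      data.frame(read_id = r$read_id, orientation = r$orientation,
                 anchor5_start = r$anchor5$start, anchor5_end = r$anchor5$end,
                 anchor5_edit = r$anchor5$edit,
                 anchor3_start = r$anchor3$start, anchor3_end = r$anchor3$end,
                 anchor3_edit = r$anchor3$edit,
                 expansion_span_bp = r$expansion_span_bp,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(read_id = character(), orientation = character(),
               anchor5_start = integer(), anchor5_end = integer(),
               anchor5_edit = integer(), anchor3_start = integer(),
               anchor3_end = integer(), anchor3_edit = integer(),
               expansion_span_bp = integer(), stringsAsFactors = FALSE)
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(read_id = character(), reason = character(), stringsAsFactors = FALSE)
  structure(list(kept = kept, table = tab, rejected = rejected),
            class = "complete_reads")
}

#' @export
print.complete_reads <- function(x, ...) {
  cat(sprintf("complete_reads: %d kept, %d rejected\n",
              length(x$kept), nrow(x$rejected)))
  invisible(x)
}
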