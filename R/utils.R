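# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar fast path (no S4 dispatch) for per-read inner loops
.revcomp1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", x))))
}

# round half away from zero, matching how percentages are conventionally
# printed (round() in R rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# lower-middle median: for even n the lower of the two central order
# statistics, so the reported value is always an observed data point
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

.assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || any(is.na(x))) {
    stop(what, " must be a character vector without NA", call. = FALSE)
  }
  bad <- grepl("[^ACGTacgt]", x)
  if (any(bad)) {
    stop(what, " contains characters outside the A/C/G/T alphabet", call. = FALSE)
  }
  invisible(toupper(x))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
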