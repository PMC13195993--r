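#' Sequencing error model
#'
#' Uniform per-base substitution/insertion/deletion rates in the style of
#' nanopore reads, whose errors concentrate in homopolymeric and highly
#' repetitive sequence. Substitutions are drawn uniformly from the three
#' alternative bases; inserted bases are uniform over A/C/G/T. Defaults are
#' ONT-like (2% substitution, 1.5% insertion, 2.5% deletion).
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base
#'   probabilities in \[0, 1\].
#' @param seed default seed used by [apply_errors()].
#' @return an `error_model` object.
#' @export
error_model <- function(substitution_rate = 0.02, insertion_rate = 0.015,
                        deletion_rate = 0.025, seed = NULL) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate, seed = seed),
            class = "error_model")
}

#' Mutate a sequence under an error model
#'
#' Each base is deleted with probability `deletion_rate`, otherwise
#' substituted with probability `substitution_rate` (uniform over the three
#' non-identical bases). Independently, an insertion of one uniform random
#' base occurs before each position (and after the last) with probability
#' `insertion_rate`. The coordinate map carries every pre-error position to
#' its 0-based post-error position, with `NA` marking deleted bases.
#'
#' @param sequence character scalar (A/C/G/T).
#' @param model an [error_model()].
#' @param seed RNG seed; defaults to the model's own seed.
#' @return list with `sequence` (mutated) and `map` (integer vector, one
#'   entry per input base).
#' @export
apply_errors <- function(sequence, model, seed = model$seed) {
  stopifnot(inherits(model, "error_model"))
  sequence <- .assert_dna(sequence, "sequence")
  with_seed(seed, .mutate(sequence, model))
}

.mutate <- function(sequence, model) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L == 0L) return(list(sequence = "", map = integer()))

  del <- runif(L) < model$deletion_rate
  sub <- !del & runif(L) < model$substitution_rate
  ins <- runif(L + 1L) < model$insertion_rate

  if (any(sub)) {
    idx <- match(chars[sub], bases)
    # uniform over the 3 alternative bases, cyclic offset
    off <- sample.int(3L, sum(sub), replace = TRUE)
    chars[sub] <- bases[(idx - 1L + off) %% 4L + 1L]
  }
  ins_base <- character(L + 1L)
  if (any(ins)) ins_base[ins] <- sample(bases, sum(ins), replace = TRUE)

  # post-error 0-based position of each kept pre-error base:
  # insertions in slots 1..i plus kept bases before i
  n_ins_before <- cumsum(ins[seq_len(L)])
  n_kept_before <- c(0L, cumsum(!del))[seq_len(L)]
  map <- ifelse(del, NA_integer_, as.integer(n_ins_before + n_kept_before))

  out <- character(2L * L + 1L)
  out[2L * seq_len(L + 1L) - 1L] <- ins_base
  keep <- chars
  keep[del] <- ""
  out[2L * seq_len(L)] <- keep
  list(sequence = paste(out, collapse = ""), map = map)
}
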