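#' Somatic mosaicism model for expansion lengths
#'
#' Describes the distribution of per-read (per-cell) repeat unit counts of
#' the expanded block. Patient data show a wide spread between the minimal,
#' median and maximal per-read expansion, with a heavy right tail, so the
#' default family is a truncated lognormal parameterised by its median;
#' `fixed` (degenerate) and `nbinom` (negative binomial, mean/dispersion)
#' alternatives are provided.
#'
#' @param family one of `"lognormal"`, `"fixed"`, `"nbinom"`.
#' @param location central value in repeat units: the median (lognormal),
#'   the constant value (fixed) or the mean (nbinom).
#' @param dispersion scale parameter: sdlog for lognormal; for nbinom the
#'   variance is `location + dispersion * location^2`.
#' @param min_units,max_units truncation bounds (inclusive); draws outside
#'   are rejected and redrawn.
#' @param seed default seed used by [sample_expansion_lengths()].
#' @return a `mosaic_model` object.
#' @export
mosaic_model <- function(family = c("lognormal", "fixed", "nbinom"),
                         location, dispersion = 0.2,
                         min_units = 1, max_units = Inf, seed = NULL) {
  family <- match.arg(family)
  stopifnot(length(location) == 1L, location > 0, dispersion >= 0,
            min_units >= 0, max_units >= min_units)
  if (family == "fixed" && (location < min_units || location > max_units)) {
    stop("fixed location lies outside the truncation bounds", call. = FALSE)
  }
  structure(list(family = family, location = location, dispersion = dispersion,
                 min_units = min_units, max_units = max_units, seed = seed),
            class = "mosaic_model")
}

#' Draw per-read expansion lengths
#'
#' @param model a [mosaic_model()].
#' @param n_reads number of draws (>= 1).
#' @param seed RNG seed; defaults to the model's own seed. `NULL` uses the
#'   current RNG stream.
#' @return integer vector of length `n_reads`, each within the model's
#'   truncation bounds.
#' @export
sample_expansion_lengths <- function(model, n_reads, seed = model$seed) {
  stopifnot(inherits(model, "mosaic_model"))
  if (length(n_reads) != 1L || is.na(n_reads) || n_reads < 1) {
    stop("n_reads must be >= 1", call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  with_seed(seed, .sample_units(model, n_reads))
}

.sample_units <- function(model, n) {
  draw <- switch(model$family,
    fixed     = function(k) rep(as.integer(round(model$location)), k),
    lognormal = function(k) as.integer(round(rlnorm(k, meanlog = log(model$location),
                                                    sdlog = model$dispersion))),
    nbinom    = function(k) {
      size <- if (model$dispersion == 0) Inf else 1 / model$dispersion
      if (is.infinite(size)) as.integer(stats::rpois(k, model$location))
      else as.integer(rnbinom(k, mu = model$location, size = size))
    })
  out <- draw(n)
  bad <- which(out < model$min_units | out > model$max_units)
  tries <- 0L
  while (length(bad) > 0L) {
    out[bad] <- draw(length(bad))
    bad <- which(out < model$min_units | out > model$max_units)
    tries <- tries + 1L
    if (tries > 1000L) {  # vanishing acceptance region
      out[bad] <- as.integer(pmin(pmax(out[bad], model$min_units), model$max_units))
      break
    }
  }
  out
}
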