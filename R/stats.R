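#' Per-sample mosaicism summary
#'
#' Aggregates read annotations into the per-sample statistics used to
#' describe somatic mosaicism of the expanded allele: expansion-span
#' distribution (bp and quadruplet units), the fraction of expanded-allele
#' reads carrying a 3' TCTG block, per-motif unit summaries, and a 500 bp
#' binned span histogram.
#'
#' Statistics are computed over expanded-class reads only (the denominator
#' used for the published per-patient TCTG fractions) unless
#' `expanded_only = FALSE`. With zero qualifying reads the fraction is an
#' explicit `NA`, never 0. Medians use the lower-middle convention for even
#' counts so every reported value is an observed read.
#'
#' @param annotations a `read_annotations` object from [annotate_reads()].
#' @param sample_id sample identifier.
#' @param expanded_only restrict statistics to expanded-class reads.
#' @param bin_width histogram bin width in bp.
#' @return a `sample_summary` object.
#' @export
summarize_sample <- function(annotations, sample_id = "sample",
                             expanded_only = TRUE, bin_width = 500) {
  stopifnot(inherits(annotations, "read_annotations"))
  pr <- annotations$per_read
  if (nrow(pr) == 0L) stop("at least one annotation is required", call. = FALSE)
  sel <- if (expanded_only) pr$allele_class == "expanded" else rep(TRUE, nrow(pr))
  n_sel <- sum(sel)
  spans <- pr$expansion_span_bp[sel]

  stat3 <- function(x) {
    if (length(x) == 0L) c(min = NA_real_, median = NA_real_, max = NA_real_)
    else c(min = min(x), median = as.numeric(median_low(x)), max = max(x))
  }
  span_bp <- stat3(spans)
  span_units <- if (n_sel) stat3(unit_count(spans)) else span_bp

  motifs <- annotations$params$alphabet
  per_motif <- do.call(rbind, lapply(motifs, function(m) {
    u <- pr[[paste0("units_", tolower(m))]][sel]
    s <- stat3(u[!is.na(u)])
    data.frame(motif = m, min_units = s["min"], median_units = s["median"],
               max_units = s["max"], row.names = NULL, stringsAsFactors = FALSE)
  }))

  frac <- if (n_sel == 0L) NA_real_ else mean(pr$has_3prime_tctg[sel])
  hist <- binned_abundance(spans, bin_width = bin_width)

  structure(list(
    sample_id = sample_id,
    n_complete_reads = nrow(pr),
    n_expanded_reads = sum(pr$allele_class == "expanded"),
    expanded_only = expanded_only,
    span_bp = span_bp,
    span_units = span_units,
    fraction_tctg_reads = frac,
    per_motif_units = per_motif,
    length_distributions = stats::setNames(
      lapply(motifs, function(m) motif_length_distribution(annotations, m, selected = sel)),
      motifs),
    histogram = hist$histogram,
    density = hist$density,
    allele_class_counts = table(factor(pr$allele_class,
                                       levels = c("normal", "grey", "expanded")))
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary '%s': %d complete reads, %d expanded\n",
              x$sample_id, x$n_complete_reads, x$n_expanded_reads))
  cat(sprintf("  span (bp):    min %s / median %s / max %s\n",
              x$span_bp["min"], x$span_bp["median"], x$span_bp["max"]))
  cat(sprintf("  span (units): min %s / median %s / max %s\n",
              x$span_units["min"], x$span_units["median"], x$span_units["max"]))
  cat(sprintf("  3'-TCTG read fraction: %s\n",
              if (is.na(x$fraction_tctg_reads)) "NA"
              else sprintf("%.1f%%", round_half_up(100 * x$fraction_tctg_reads, 1))))
  invisible(x)
}

#' Binned span abundance with kernel density
#'
#' Groups expansion spans into right-open bins of `bin_width` bp starting at
#' 0 and overlays a Gaussian kernel density estimate of the raw spans
#' (bandwidth by the Scott/normal-reference rule, `bw.nrd`). Counts are
#' always reported; the density accompanies, never replaces, them.
#'
#' @param spans numeric vector of spans in bp (>= 0).
#' @param bin_width bin width in bp.
#' @return list with `histogram` (data.frame: bin_start, bin_end, count;
#'   empty for empty input) and `density` (data.frame: x, y; `NULL` when
#'   fewer than 2 distinct spans are available).
#' @export
binned_abundance <- function(spans, bin_width = 500) {
  if (any(is.na(spans)) || any(spans < 0)) stop("spans must be >= 0", call. = FALSE)
  if (length(spans) == 0L) {
    return(list(histogram = data.frame(bin_start = numeric(), bin_end = numeric(),
                                       count = integer()),
                density = NULL))
  }
  bin <- spans %/% bin_width
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  histogram <- data.frame(bin_start = (seq_along(counts) - 1) * bin_width,
                          bin_end = seq_along(counts) * bin_width,
                          count = counts)
  dens <- NULL
  if (length(spans) >= 2L && sd(spans) > 0) {
    bw <- stats::bw.nrd(spans)
    # the normal-reference rule degenerates when the IQR is 0; fall back to
    # the pure sd-based bandwidth
    if (!is.finite(bw) || bw <= 0) bw <- 1.06 * sd(spans) * length(spans)^(-1 / 5)
    d <- density(spans, bw = bw, kernel = "gaussian")
    dens <- data.frame(x = d$x, y = d$y)
  }
  list(histogram = histogram, density = dens)
}

#' Per-read motif length distribution with Tukey box statistics
#'
#' Collects the lengths (bp) of classified segments of one motif across
#' reads, excluding unclassified runs, and computes quartiles (linear
#' interpolation, type 7) with Tukey fences at Q1 - 1.5 IQR and
#' Q3 + 1.5 IQR; whisker ends are the most extreme observations inside the
#' fences and outliers the observations beyond them.
#'
#' @param annotations a `read_annotations` object.
#' @param motif motif label (e.g. `"CCTG"`).
#' @param selected optional logical vector over `annotations$per_read` rows
#'   restricting which reads contribute.
#' @return a `motif_length_distribution` object (fields: motif, lengths, n,
#'   q1, median, q3, iqr, whisker_low, whisker_high, outliers).
#' @export
motif_length_distribution <- function(annotations, motif, selected = NULL) {
  stopifnot(inherits(annotations, "read_annotations"))
  segs <- annotations$segments
  keep <- segs$label == motif
  if (!is.null(selected)) {
    ids <- annotations$per_read$read_id[selected]
    keep <- keep & segs$read_id %in% ids
  }
  lengths <- segs$end[keep] - segs$start[keep]
  if (length(lengths) == 0L) {
    return(structure(list(motif = motif, lengths = numeric(), n = 0L,
                          q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                          iqr = NA_real_, whisker_low = NA_real_,
                          whisker_high = NA_real_, outliers = numeric()),
                     class = "motif_length_distribution"))
  }
  q <- quantile(lengths, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- lengths >= lo_fence & lengths <= hi_fence
  structure(list(motif = motif, lengths = lengths, n = length(lengths),
                 q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 whisker_low = min(lengths[inside]),
                 whisker_high = max(lengths[inside]),
                 outliers = lengths[!inside]),
            class = "motif_length_distribution")
}

#' Minimum detectable read fraction at a given spanning-read coverage
#'
#' With n complete reads over the expanded allele, a single molecule
#' corresponds to a fraction of 1/n: 50 reads give a detection floor of 2%
#' (1 in 50 cells).
#'
#' @param n_complete_reads number of complete reads (>= 1).
#' @return detection floor in percent.
#' @export
detection_floor <- function(n_complete_reads) {
  if (any(is.na(n_complete_reads)) || any(n_complete_reads < 1)) {
    stop("n_complete_reads must be >= 1", call. = FALSE)
  }
  100 / n_complete_reads
}

#' Intergenerational change in expansion statistics
#'
#' Child-minus-parent deltas of the per-motif minimum, median and maximum
#' unit counts and of the expansion span, plus retention/loss flags for the
#' 3' TCTG block (lost = present in the parent's reads, absent from the
#' child's).
#'
#' @param parent,child `sample_summary` objects computed over expanded
#'   reads with the same motif alphabet.
#' @return a `generation_delta` object.
#' @export
compare_generations <- function(parent, child) {
  stopifnot(inherits(parent, "sample_summary"), inherits(child, "sample_summary"))
  if (!identical(parent$per_motif_units$motif, child$per_motif_units$motif)) {
    stop("summaries use different motif alphabets", call. = FALSE)
  }
  delta_units <- data.frame(
    motif = parent$per_motif_units$motif,
    d_min_units = child$per_motif_units$min_units - parent$per_motif_units$min_units,
    d_median_units = child$per_motif_units$median_units - parent$per_motif_units$median_units,
    d_max_units = child$per_motif_units$max_units - parent$per_motif_units$max_units,
    stringsAsFactors = FALSE)
  pf <- parent$fraction_tctg_reads
  cf <- child$fraction_tctg_reads
  lost <- !is.na(pf) && !is.na(cf) && pf > 0 && cf == 0
  retained <- !is.na(pf) && !is.na(cf) && pf > 0 && cf > 0
  structure(list(parent_id = parent$sample_id, child_id = child$sample_id,
                 delta_units = delta_units,
                 delta_span_bp = child$span_bp - parent$span_bp,
                 motif_retained = retained, motif_lost = lost),
            class = "generation_delta")
}

#' @export
print.generation_delta <- function(x, ...) {
  cat(sprintf("generation_delta %s -> %s (TCTG %s)\n", x$parent_id, x$child_id,
              if (x$motif_lost) "lost" else if (x$motif_retained) "retained" else "absent"))
  print(x$delta_units)
  invisible(x)
}
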