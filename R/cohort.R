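#' Read a cohort table from CSV/TSV
#'
#' Expected header: `id`, `sex` ("M"/"F"), `familial` (TRUE for familial
#' cases, FALSE for single cases), `motif_present` (TRUE when the expanded
#' allele carries the 3' TCTG block), optionally `age_at_onset` (years) and
#' any number of logical symptom columns. A synthetic fixture reproducing
#' the published cohort margins ships as
#' `extdata/cohort_table1_synthetic.csv`.
#'
#' @param path CSV (or TSV) file.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("id", "sex", "familial", "motif_present")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$familial <- as.logical(df$familial)
  df$motif_present <- as.logical(df$motif_present)
  if ("age_at_onset" %in% names(df) &&
      any(!is.na(df$age_at_onset) & df$age_at_onset < 0)) {
    stop("age_at_onset must be >= 0", call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Frequency of the 3'-TCTG motif in a cohort
#'
#' Overall carrier percentage with sex and familial/single stratifications.
#' Every stratified table is checked to sum back to the totals.
#'
#' @param cohort a `cohort_table` (or data.frame with columns `sex`,
#'   `familial`, `motif_present`).
#' @return a `motif_frequency` object: list with `n`, `n_carriers`,
#'   `percent` (1 d.p., half-up), `by_sex` and `by_family` data.frames.
#' @export
motif_frequency <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  n <- nrow(cohort)
  carriers <- sum(cohort$motif_present)
  strat <- function(group, labels) {
    tab <- do.call(rbind, lapply(labels, function(g) {
      sub <- cohort$motif_present[group == g]
      data.frame(group = g, n = length(sub), yes = sum(sub),
                 no = sum(!sub),
                 percent = round_half_up(100 * mean(sub), 1),
                 stringsAsFactors = FALSE)
    }))
    if (sum(tab$n) != n || sum(tab$yes) != carriers) {
      stop("stratified counts do not sum to totals", call. = FALSE)
    }
    tab
  }
  structure(list(
    n = n, n_carriers = carriers,
    percent = round_half_up(100 * carriers / n, 1),
    by_sex = strat(cohort$sex, sort(unique(cohort$sex))),
    by_family = strat(ifelse(cohort$familial, "familial", "single"),
                      c("familial", "single"))
  ), class = "motif_frequency")
}

#' @export
print.motif_frequency <- function(x, ...) {
  cat(sprintf("motif carriers: %d/%d (%.1f%%)\n", x$n_carriers, x$n, x$percent))
  print(x$by_sex); print(x$by_family)
  invisible(x)
}

#' Diagnostic assay sensitivity
#'
#' Sensitivity of a test over a cohort of true-positive patients:
#' `(N - FN) / N * 100`. Nine false negatives among 100 patients — the
#' published count for standard 3' repeat-primed PCR — give 91%.
#'
#' @param n_patients cohort size (all true positives, >= 1).
#' @param n_false_negative patients missed by the assay.
#' @return sensitivity in percent.
#' @export
diagnostic_sensitivity <- function(n_patients, n_false_negative) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (n_false_negative < 0 || n_false_negative > n_patients) {
    stop("n_false_negative must lie in [0, n_patients]", call. = FALSE)
  }
  (n_patients - n_false_negative) / n_patients * 100
}

#' Summarise meiotic transmissions
#'
#' Percentages (1 d.p., half-up) of maternal and paternal transmissions and
#' the count of transmissions retaining the 3'-TCTG motif. Records with
#' unknown transmitting-parent sex are excluded and counted.
#'
#' @param records data.frame with columns `family_id`, `parent`
#'   ("maternal", "paternal" or "unknown") and `motif_retained` (logical).
#' @return a `transmission_summary` object.
#' @export
transmission_summary <- function(records) {
  if (nrow(records) == 0L) stop("at least one record is required", call. = FALSE)
  known <- records[records$parent %in% c("maternal", "paternal"), , drop = FALSE]
  n_excluded <- nrow(records) - nrow(known)
  n <- nrow(known)
  if (n == 0L) stop("no records with known parent sex", call. = FALSE)
  n_maternal <- sum(known$parent == "maternal")
  structure(list(
    n_transmissions = n,
    n_maternal = n_maternal,
    n_paternal = n - n_maternal,
    maternal_percent = round_half_up(100 * n_maternal / n, 1),
    paternal_percent = round_half_up(100 * (n - n_maternal) / n, 1),
    n_motif_retained = sum(known$motif_retained, na.rm = TRUE),
    n_excluded = n_excluded
  ), class = "transmission_summary")
}

#' @export
print.transmission_summary <- function(x, ...) {
  cat(sprintf("transmissions: %d (maternal %d, %.1f%%; paternal %d, %.1f%%); motif retained %d\n",
              x$n_transmissions, x$n_maternal, x$maternal_percent,
              x$n_paternal, x$paternal_percent, x$n_motif_retained))
  invisible(x)
}

#' Two-group comparison of age at onset
#'
#' Unpaired two-sample t test (pooled variance by default, Welch on
#' request) for comparing onset ages between carriers of "pure" CCTG and
#' TCTG-containing expanded alleles. When both groups are constant and
#' equal, the test is degenerate and `p = 1` is reported.
#'
#' @param a,b numeric onset ages for the two groups (each n >= 2).
#' @param method `"pooled"` (classic Student) or `"welch"`.
#' @return list with `difference` (mean(a) - mean(b)), `statistic`, `df`,
#'   `p.value` and `method`.
#' @export
onset_comparison <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(difference = 0, statistic = 0,
                  df = length(a) + length(b) - 2L, p.value = 1, method = method))
    }
    return(list(difference = mean(a) - mean(b), statistic = Inf,
                df = length(a) + length(b) - 2L, p.value = 0, method = method))
  }
  tt <- t.test(a, b, var.equal = method == "pooled")
  list(difference = mean(a) - mean(b),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, method = method)
}

#' Spearman correlation of onset age with expansion length
#'
#' @param onset,length paired numeric vectors.
#' @return list with `rho` and `p.value`.
#' @export
onset_length_correlation <- function(onset, length) {
  ct <- cor.test(onset, length, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}
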