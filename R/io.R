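# motif colours for browser display (classified motifs distinct, grey for
# unclassified runs)
.motif_rgb <- c(CCTG = "31,119,180", TCTG = "214,39,40", GCTG = "44,160,44",
                ACTG = "255,127,14", UNCLASSIFIED = "128,128,128")

#' Write read annotations as BED9
#'
#' One feature per segment on a synthetic per-read "chromosome" (the read
#' id), with itemRgb distinct per motif and grey for unclassified runs —
#' suitable for IGV-style display of the repeat structure of each read.
#' Coordinates are 0-based half-open (BED convention), matching all package
#' output.
#'
#' @param annotations a `read_annotations` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotations, path) {
  stopifnot(inherits(annotations, "read_annotations"))
  segs <- annotations$segments
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based half-open (BED)",
               'track name="repeat_motifs" itemRgb="On"'), con)
  if (nrow(segs)) {
    score <- ifelse(is.na(segs$match_ratio), 0L, as.integer(round(1000 * segs$match_ratio)))
    rgb <- .motif_rgb[segs$label]
    rgb[is.na(rgb)] <- "0,0,0"
    writeLines(paste(segs$read_id, segs$start, segs$end, segs$label, score,
                     ".", segs$start, segs$end, rgb, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED9 file written by [write_annotation_bed()]
#'
#' @param path BED file.
#' @return data.frame with read_id, start, end, label, score, rgb.
#' @export
read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^track", lines)]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), start = integer(), end = integer(),
                      label = character(), score = integer(), rgb = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(read_id = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 2L)),
             end = as.integer(vapply(f, `[`, "", 3L)),
             label = vapply(f, `[`, "", 4L),
             score = as.integer(vapply(f, `[`, "", 5L)),
             rgb = vapply(f, `[`, "", 9L),
             stringsAsFactors = FALSE)
}

# flatten a sample_summary into one TSV row
.summary_row <- function(s) {
  fmt1 <- function(x) if (is.na(x)) NA_character_ else sprintf("%.1f", round_half_up(x, 1))
  row <- data.frame(
    sample_id = s$sample_id,
    n_complete_reads = s$n_complete_reads,
    n_expanded_reads = s$n_expanded_reads,
    span_min_bp = s$span_bp["min"], span_median_bp = s$span_bp["median"],
    span_max_bp = s$span_bp["max"],
    units_min = s$span_units["min"], units_median = s$span_units["median"],
    units_max = s$span_units["max"],
    fraction_tctg_percent = fmt1(100 * s$fraction_tctg_reads),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s$per_motif_units))) {
    m <- tolower(s$per_motif_units$motif[i])
    row[[paste0("units_", m, "_min")]] <- s$per_motif_units$min_units[i]
    row[[paste0("units_", m, "_median")]] <- s$per_motif_units$median_units[i]
    row[[paste0("units_", m, "_max")]] <- s$per_motif_units$max_units[i]
  }
  rownames(row) <- NULL
  row
}

#' Write per-sample summaries as TSV
#'
#' Stable column order; undefined statistics are written as explicit `NA`,
#' never as zeros; the TCTG read fraction is printed in percent with one
#' decimal place (half-up).
#'
#' @param summaries a `sample_summary` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summaries, path) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("at least one summary is required", call. = FALSE)
  tab <- do.call(rbind, lapply(summaries, .summary_row))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a summary TSV written by [write_summary_tsv()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_summary_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(fraction_tctg_percent = "character"))
}

#' Write the per-read annotation table as TSV
#'
#' @param annotations a `read_annotations` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_per_read_tsv <- function(annotations, path) {
  stopifnot(inherits(annotations, "read_annotations"))
  write.table(annotations$per_read, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
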