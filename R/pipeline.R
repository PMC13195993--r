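#' Run the simulate/harvest/annotate/summarize pipeline from a config
#'
#' Wires the package stages into one reproducible run. The configuration is
#' a YAML file (or an equivalent named list) with the sections below;
#' unknown keys are rejected before any compute. Every run writes a
#' resolved-config copy (defaults filled in) next to its outputs, a log
#' accounting for every read at each stage, and the standard artifact
#' bundle: simulated FASTQ + truth (when simulating), rejection log TSV,
#' per-read TSV, BED9 segments and the sample summary TSV.
#'
#' Config sections:
#' \describe{
#'   \item{seed}{integer seed; the run is deterministic given it.}
#'   \item{sample_id}{sample label (default "sample").}
#'   \item{simulate}{`n_reads`, `alleles` (list of `label`, `cctg`, `tctg3`,
#'     `tg`, `tctg5`, and `weight` or `count`), optional `mosaic`
#'     (`family`, `location`, `dispersion`, `min_units`, `max_units`),
#'     optional `errors` (`substitution_rate`, `insertion_rate`,
#'     `deletion_rate`), `strand_fraction`, `incomplete_fraction`.}
#'   \item{input}{alternative to `simulate`: `fastq` (or `fasta`) path plus
#'     `flanks` (FASTA with records `flank5`/`flank3`), or `sam`/`bam` path
#'     plus `region` ("chrom:start-end", 1-based closed) and `flanks`.}
#'   \item{harvest}{`max_edit_fraction` (default 0.2).}
#'   \item{annotate}{`minlength` (default 16), `minratio` (default 75,
#'     percent or fraction), `max_bridge` (default 8), `include_nctg`.}
#' }
#'
#' @param config path to a YAML config file, or a named list.
#' @param outdir output directory (created if needed); overrides any
#'   `outdir` key in the config.
#' @return invisibly, a list with the summary object and all output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "sample_id", "outdir", "simulate", "input", "harvest", "annotate")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$simulate) == is.null(config$input)) {
    stop("exactly one of 'simulate' or 'input' must be configured", call. = FALSE)
  }
  if (!is.null(config$input) && is.null(config$input$flanks)) {
    stop("configuration error: 'input' requires 'flanks' (FASTA with flank5/flank3)",
         call. = FALSE)
  }

  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }

  # ---- resolve defaults -------------------------------------------------
  resolved <- config
  resolved$sample_id <- config$sample_id %||% "sample"
  resolved$outdir <- outdir
  h <- config$harvest %||% list()
  resolved$harvest <- list(max_edit_fraction = h$max_edit_fraction %||% 0.2)
  a <- config$annotate %||% list()
  resolved$annotate <- list(minlength = a$minlength %||% 16L,
                            minratio = a$minratio %||% 75,
                            max_bridge = a$max_bridge %||% 8L,
                            include_nctg = isTRUE(a$include_nctg))
  params <- annotator_params(resolved$annotate$minlength,
                             resolved$annotate$minratio,
                             resolved$annotate$max_bridge,
                             motif_alphabet(resolved$annotate$include_nctg))

  paths <- list(config = file.path(outdir, "resolved_config.yaml"),
                log = log_path)

  # ---- stage 1: obtain reads -------------------------------------------
  if (!is.null(config$simulate)) {
    s <- config$simulate
    fl <- default_flanks()
    alleles <- list()
    weights <- counts <- NULL
    for (al in s$alleles) {
      alleles[[al$label]] <- dm2_allele(cctg = al$cctg, tctg3 = al$tctg3 %||% 0,
                                        tg = al$tg %||% 0, tctg5 = al$tctg5 %||% 0,
                                        flank5 = fl$flank5, flank3 = fl$flank3,
                                        label = al$label)
      if (!is.null(al$count)) counts[al$label] <- al$count
      if (!is.null(al$weight)) weights[al$label] <- al$weight
    }
    mosaic <- if (!is.null(s$mosaic)) {
      mosaic_model(s$mosaic$family %||% "lognormal", s$mosaic$location,
                   s$mosaic$dispersion %||% 0.2, s$mosaic$min_units %||% 1,
                   s$mosaic$max_units %||% Inf)
    }
    errors <- if (!is.null(s$errors)) {
      error_model(s$errors$substitution_rate %||% 0.02,
                  s$errors$insertion_rate %||% 0.015,
                  s$errors$deletion_rate %||% 0.025)
    }
    sim <- simulate_read_set(alleles, n_reads = s$n_reads, weights = weights,
                             counts = counts, mosaic = mosaic, errors = errors,
                             strand_fraction = s$strand_fraction %||% 0.5,
                             incomplete_fraction = s$incomplete_fraction %||% 0,
                             seed = config$seed)
    paths$fastq <- file.path(outdir, "simulated.fastq")
    paths$truth <- file.path(outdir, "truth.tsv")
    write_simulated_fastq(sim, paths$fastq)
    write_truth_tsv(sim, paths$truth)
    reads <- stats::setNames(sim$reads$sequence, sim$reads$read_id)
    flank5 <- fl$flank5; flank3 <- fl$flank3
    say("simulate: %d reads from %d allele(s)", length(reads), length(alleles))
  } else {
    inp <- config$input
    fls <- Biostrings::readDNAStringSet(inp$flanks)
    flank5 <- as.character(fls[["flank5"]]); flank3 <- as.character(fls[["flank3"]])
    reads <- if (!is.null(inp$fastq %||% inp$fasta)) {
      read_sequences(inp$fastq %||% inp$fasta)
    } else if (!is.null(inp$sam %||% inp$bam)) {
      read_sam_reads(inp$sam %||% inp$bam, inp$region)
    } else stop("input requires 'fastq'/'fasta' or 'sam'/'bam'", call. = FALSE)
    say("input: %d reads loaded", length(reads))
  }

  # ---- stage 2: harvest -------------------------------------------------
  anchors <- flank_anchors(flank5, flank3,
                           max_edit_fraction = resolved$harvest$max_edit_fraction)
  harvested <- extract_complete_reads(reads, anchors)
  paths$rejected <- file.path(outdir, "rejected_reads.tsv")
  write.table(harvested$rejected, paths$rejected, sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("harvest: %d in -> %d kept + %d rejected", length(reads),
      length(harvested$kept), nrow(harvested$rejected))

  # ---- stage 3: annotate ------------------------------------------------
  ann <- annotate_reads(harvested, params)
  paths$per_read <- file.path(outdir, "per_read.tsv")
  paths$bed <- file.path(outdir, "segments.bed")
  write_per_read_tsv(ann, paths$per_read)
  write_annotation_bed(ann, paths$bed)
  say("annotate: %d reads -> %d segments", nrow(ann$per_read), nrow(ann$segments))

  # ---- stage 4: summarize ----------------------------------------------
  summary <- NULL
  paths$summary <- file.path(outdir, "sample_summary.tsv")
  if (nrow(ann$per_read) > 0L) {
    summary <- summarize_sample(ann, sample_id = resolved$sample_id)
    write_summary_tsv(summary, paths$summary)
    say("summarize: %d expanded reads, 3'-TCTG fraction %s",
        summary$n_expanded_reads,
        if (is.na(summary$fraction_tctg_reads)) "NA"
        else sprintf("%.1f%%", round_half_up(100 * summary$fraction_tctg_reads, 1)))
  } else {
    say("summarize: no complete reads, summary skipped")
  }

  yaml::write_yaml(resolved, paths$config)
  invisible(list(summary = summary, annotations = ann, harvested = harvested,
                 paths = paths))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
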