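# Independent oracles used across the suite. These deliberately avoid the
# package's own primitives: masks come from substring comparison, anchor
# distances from exhaustive substring enumeration with adist(), and the
# reference segmenter enumerates raw intervals and solves the objective by
# memoised search over them.

oracle_mask <- function(seq, motif) {
  L <- nchar(seq)
  mask <- rep(FALSE, L)
  if (L < 4L) return(mask)
  starts <- which(vapply(seq_len(L - 3L),
                         function(i) substring(seq, i, i + 3L) == motif, TRUE))
  for (i in starts) mask[i:(i + 3L)] <- TRUE
  mask
}

# minimum edit distance of `pattern` against any substring of `subject`
# (semi-global), by exhaustive substring enumeration
oracle_min_edit <- function(pattern, subject) {
  m <- nchar(pattern); L <- nchar(subject)
  best <- m
  for (i in seq_len(L)) {
    for (j in i:min(L, i + 2L * m)) {
      d <- utils::adist(pattern, substring(subject, i, j))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

# Reference segmenter: enumerate every legal interval (ends covered by the
# motif, internal uncovered gaps <= bridge, ratio >= minratio, length >=
# minlen), then maximise (classified bp, matched bp, -segments) with the
# same residual tie-breaks as the annotator: a segment starting at the
# current position beats a gap, then longer end, then higher-priority motif.
oracle_segment <- function(seq, minlen = 16, minratio = 0.75, bridge = 8,
                           alphabet = c("CCTG", "TCTG")) {
  L <- nchar(seq)
  cands <- list()
  for (k in seq_along(alphabet)) {
    mask <- oracle_mask(seq, alphabet[k])
    if (!any(mask)) next
    cum <- c(0L, cumsum(mask))
    # positions inside an uncovered run longer than bridge
    r <- rle(mask)
    long <- rep(!r$values & r$lengths > bridge, r$lengths)
    cuml <- c(0L, cumsum(long))
    cov_pos <- which(mask)            # 1-based
    for (a1 in cov_pos) {
      bs <- cov_pos[cov_pos >= a1 + minlen - 1L]   # 1-based end position
      if (length(bs) == 0L) next
      len <- bs - a1 + 1L
      covn <- cum[bs + 1L] - cum[a1]
      no_long <- (cuml[bs + 1L] - cuml[a1]) == 0L  # ends covered => runs inside
      ok <- no_long & (covn + 1e-9 >= minratio * len)
      for (b1 in bs[ok]) {
        cands[[length(cands) + 1L]] <-
          list(start = a1 - 1L, end = b1, k = k,
               matched = cum[b1 + 1L] - cum[a1])
      }
    }
  }
  by_start <- vector("list", L)
  for (ci in seq_along(cands)) {
    s <- cands[[ci]]$start + 1L
    by_start[[s]] <- c(by_start[[s]], ci)
  }
  # right-to-left DP over positions with lexicographic objective
  f_cls <- integer(L + 1L); f_match <- integer(L + 1L); f_nseg <- integer(L + 1L)
  choice <- integer(L + 1L)
  for (pos in L:1) {
    bc <- f_cls[pos + 1L]; bm <- f_match[pos + 1L]; bn <- f_nseg[pos + 1L]
    bch <- 0L; bend <- -1L; bmot <- length(alphabet) + 1L
    for (ci in by_start[[pos]]) {
      cd <- cands[[ci]]
      cc <- (cd$end - cd$start) + f_cls[cd$end + 1L]
      cm <- cd$matched + f_match[cd$end + 1L]
      cn <- 1L + f_nseg[cd$end + 1L]
      take <- (cc > bc) ||
        (cc == bc && (cm > bm ||
          (cm == bm && (cn < bn ||
            (cn == bn && (bch == 0L || cd$end > bend ||
              (cd$end == bend && cd$k < bmot)))))))
      if (take) {
        bc <- cc; bm <- cm; bn <- cn; bch <- ci; bend <- cd$end; bmot <- cd$k
      }
    }
    f_cls[pos] <- bc; f_match[pos] <- bm; f_nseg[pos] <- bn; choice[pos] <- bch
  }
  out <- list(); pos <- 1L
  while (pos <= L) {
    if (choice[pos] == 0L) { pos <- pos + 1L; next }
    cd <- cands[[choice[pos]]]
    out[[length(out) + 1L]] <- data.frame(start = cd$start, end = cd$end,
                                          label = alphabet[cd$k],
                                          matched = cd$matched)
    pos <- cd$end + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      label = character(), matched = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# motif-rich fuzz read: concatenated short motif blocks and random spacers,
# optionally corrupted by substitutions
fuzz_read <- function(max_len = 64L, sub_rate = 0.05) {
  bases <- c("A", "C", "G", "T")
  parts <- character()
  len <- 0L
  target <- sample(8:max_len, 1L)
  while (len < target) {
    p <- if (runif(1) < 0.75) {
      strrep(sample(c("CCTG", "TCTG"), 1L), sample(1:8, 1L))
    } else {
      paste(sample(bases, sample(1:6, 1L), replace = TRUE), collapse = "")
    }
    parts <- c(parts, p)
    len <- len + nchar(p)
  }
  s <- substr(paste(parts, collapse = ""), 1L, max_len)
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < sub_rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
  }
  paste(ch, collapse = "")
}

.flank_cache <- NULL
cached_flanks <- function() {
  if (is.null(.flank_cache)) .flank_cache <<- default_flanks()
  .flank_cache
}

# wrap a bare repeat-region sequence so segment_read() can run on it
wrap_read <- function(region, flanks = cached_flanks(), id = "read") {
  list(read_id = id,
       sequence = paste0(flanks$flank5, region, flanks$flank3),
       anchor5 = list(start = 0L, end = nchar(flanks$flank5), edit = 0L),
       anchor3 = list(start = nchar(flanks$flank5) + nchar(region),
                      end = nchar(flanks$flank5) + nchar(region) + nchar(flanks$flank3),
                      edit = 0L))
}

# segments table of a bare region under given params (classified rows only)
segment_region <- function(region, ...) {
  p <- annotator_params(...)
  ann <- segment_read(wrap_read(region), p)
  segs <- ann$segments
  segs <- segs[segs$label != "UNCLASSIFIED", , drop = FALSE]
  segs$start <- segs$start - 300L   # default flanks are 300 bp
  segs$end <- segs$end - 300L
  rownames(segs) <- NULL
  segs
}
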