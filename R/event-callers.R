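#' High-level amplicons
#'
#' Segments with linear Tumor/Normal ratio at or above `min_ratio` (default 5)
#' are the seeds of putative double-minute amplicons. Seeds on the same
#' chromosome separated by at most `merge_gap` bp are merged into one
#' amplicon. Each amplicon is annotated with the oncogenes it overlaps (by at
#' least 1 bp) and with whether any structural-variant breakend of the sample
#' falls within its boundaries extended by `sv_tolerance` bp.
#'
#' @param segments Segment data frame for ONE sample.
#' @param oncogenes Oncogene data frame (see [read_oncogenes()]).
#' @param sv SV breakend data frame for the same sample (may be empty).
#' @param min_ratio Inclusive Tumor/Normal ratio cutoff. Default 5.
#' @param merge_gap Maximum gap (bp) between merged seeds. Default 1 Mb.
#' @param sv_tolerance Breakend slack (bp) around the amplicon. Default 10 kb.
#' @return Data frame with one row per amplicon: `chrom`, `start`, `end`,
#'   `max_tn_ratio`, `n_segments`, `oncogenes` (comma-separated symbols, ""
#'   when none), `has_sv`.
#' @export
build_amplicons <- function(segments, oncogenes, sv = NULL, min_ratio = 5,
                            merge_gap = 1e6, sv_tolerance = 1e4) {
  seeds <- segments[segments$tn_ratio >= min_ratio, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      max_tn_ratio = numeric(), n_segments = integer(),
                      oncogenes = character(), has_sv = logical())
  if (nrow(seeds) == 0) return(empty)
  out <- list()
  for (ch in unique(seeds$chrom)) {
    s <- seeds[seeds$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, (s$start[-1] - s$end[-nrow(s)] - 1) > merge_gap))
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        max_tn_ratio = max(m$tn_ratio), n_segments = nrow(m))
    }
  }
  amp <- do.call(rbind, out)
  amp$oncogenes <- vapply(seq_len(nrow(amp)), function(i) {
    hit <- oncogenes$chrom == amp$chrom[i] &
      oncogenes$start <= amp$end[i] & oncogenes$end >= amp$start[i]
    paste(sort(oncogenes$gene[hit]), collapse = ",")
  }, character(1))
  amp$has_sv <- vapply(seq_len(nrow(amp)), function(i) {
    if (is.null(sv) || nrow(sv) == 0) return(FALSE)
    lo <- amp$start[i] - sv_tolerance
    hi <- amp$end[i] + sv_tolerance
    any((sv$chrom1 == amp$chrom[i] & sv$pos1 >= lo & sv$pos1 <= hi) |
          (sv$chrom2 == amp$chrom[i] & sv$pos2 >= lo & sv$pos2 <= hi))
  }, logical(1))
  rownames(amp) <- NULL
  amp
}

#' Double-minute call from amplicons
#'
#' Rule (a): the sample carries two or more distinct high-level amplicons
#' genome-wide, at least one of which overlaps an oncogene. Rule (b): the
#' sample carries exactly one amplicon, which overlaps at least one oncogene,
#' is longer than `min_length` (strict, default 1 Mb) and has an associated
#' structural variant.
#'
#' @param amplicons Output of [build_amplicons()].
#' @param min_length Rule (b) length cutoff in bp (exclusive). Default 1 Mb.
#' @return List: `is_dm`, `rule` ("a", "b" or "none"), `oncogenes` (unique
#'   symbols across DM amplicons), `amplicons` (the input).
#' @export
call_dm <- function(amplicons, min_length = 1e6) {
  genes <- unique(unlist(strsplit(amplicons$oncogenes[
    amplicons$oncogenes != ""], ",")))
  n <- nrow(amplicons)
  has_onc <- any(amplicons$oncogenes != "")
  if (n >= 2 && has_onc) {
    rule <- "a"
  } else if (n == 1 && has_onc &&
             (amplicons$end - amplicons$start + 1) > min_length &&
             amplicons$has_sv) {
    rule <- "b"
  } else {
    rule <- "none"
  }
  list(is_dm = rule != "none", rule = rule,
       oncogenes = if (rule == "none") character(0) else sort(genes),
       amplicons = amplicons)
}

# Copy-number state runs of one chromosome: segments ordered by start,
# discretized to loss/neutral/gain, with implicit neutral runs filling gaps
# and flanks. Returns positions where the state changes.
switch_positions <- function(seg, chrom_length, threshold = 0.25) {
  if (nrow(seg) == 0) return(numeric(0))
  seg <- seg[order(seg$start), , drop = FALSE]
  state <- ifelse(seg$log2_ratio > threshold, 1L,
                  ifelse(seg$log2_ratio < -threshold, -1L, 0L))
  starts <- numeric(0); states <- integer(0)
  cursor <- 1
  for (i in seq_len(nrow(seg))) {
    if (seg$start[i] > cursor) {           # uncovered gap is neutral
      starts <- c(starts, cursor); states <- c(states, 0L)
    }
    starts <- c(starts, seg$start[i]); states <- c(states, state[i])
    cursor <- seg$end[i] + 1
  }
  if (cursor <= chrom_length) {
    starts <- c(starts, cursor); states <- c(states, 0L)
  }
  keep <- c(TRUE, states[-1] != states[-length(states)])
  starts <- starts[keep]
  starts[-1]                               # boundaries where the state flips
}

#' Sliding-window chromothripsis caller
#'
#' Discretizes each autosome's segments to copy-number states (loss / neutral
#' / gain via |log2 ratio| > `threshold`), locates the state-switch points,
#' and scans windows of `window_mb` anchored at each switch point. The switch
#' count k in a window is scored against the genome-wide background rate mu
#' (total autosomal switches scaled to one window) with a Poisson log10
#' likelihood ratio, `k * log10(k / mu) - (k - mu) / ln(10)` (0 when k = 0). A
#' window qualifies when k is at least `min_switches` and the score is at
#' least `lr_threshold`; overlapping qualifying windows are merged into one
#' call.
#'
#' @param segments Segment data frame for ONE sample.
#' @param genome A `genome_model`.
#' @param window_mb Window size in Mb. Default 10.
#' @param min_switches Minimum switches per window. Default 10.
#' @param lr_threshold Minimum log10 likelihood ratio. Default 8.
#' @param threshold State discretization cutoff on |log2 ratio|. Default 0.25.
#' @return Data frame of calls: `chrom`, `window_start`, `window_end`,
#'   `n_switches`, `log10_lr`. Zero rows when no region qualifies.
#' @export
call_chromothripsis <- function(segments, genome, window_mb = 10,
                                min_switches = 10, lr_threshold = 8,
                                threshold = 0.25) {
  stopifnot(inherits(genome, "genome_model"))
  if (window_mb <= 0) stop("configuration error: window_mb must be > 0")
  window_bp <- window_mb * 1e6
  seg <- segments[segments$chrom %in% genome$chrom_names, , drop = FALSE]
  sw <- lapply(genome$chrom_names, function(ch)
    switch_positions(seg[seg$chrom == ch, , drop = FALSE],
                     genome$chrom_lengths[[ch]], threshold))
  names(sw) <- genome$chrom_names
  total_switches <- sum(lengths(sw))
  total_mb <- sum(genome$chrom_lengths) / 1e6
  mu <- total_switches * window_mb / total_mb
  empty <- data.frame(chrom = character(), window_start = numeric(),
                      window_end = numeric(), n_switches = integer(),
                      log10_lr = numeric())
  if (total_switches == 0) return(empty)
  lr_of <- function(k) if (k == 0) 0 else k * log10(k / mu) - (k - mu) / log(10)
  calls <- list()
  for (ch in genome$chrom_names) {
    pos <- sw[[ch]]
    if (length(pos) == 0) next
    qual <- list()
    for (p in pos) {
      k <- sum(pos >= p & pos < p + window_bp)
      score <- lr_of(k)
      if (k >= min_switches && score >= lr_threshold)
        qual[[length(qual) + 1]] <- c(p, min(p + window_bp - 1,
                                             genome$chrom_lengths[[ch]]),
                                      score)
    }
    if (length(qual) == 0) next
    q <- do.call(rbind, qual)
    q <- q[order(q[, 1]), , drop = FALSE]
    ends <- q[, 2]
    grp <- cumsum(c(1, q[-1, 1] > cummax(ends[-length(ends)])))
    for (g in unique(grp)) {
      m <- q[grp == g, , drop = FALSE]
      ws <- min(m[, 1]); we <- max(m[, 2])
      calls[[length(calls) + 1]] <- data.frame(
        chrom = ch, window_start = ws, window_end = we,
        n_switches = sum(pos >= ws & pos <= we),
        log10_lr = max(m[, 3]))
    }
  }
  if (length(calls) == 0) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
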