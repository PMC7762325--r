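#' Weighted Genome Instability Index (wGII)
#'
#' For each autosome, the fraction of captured bases lying inside segments
#' with |log2 Tumor/Normal ratio| strictly above the threshold, out of all
#' captured bases of that chromosome. wGII is the unweighted mean of the 22
#' per-chromosome fractions, which removes the bias of unequal chromosome
#' sizes. Captured bases not covered by any segment count as unaltered.
#'
#' @param segments Segment data frame for ONE sample (see [read_segments()]).
#' @param genome A `genome_model`.
#' @param threshold Absolute log2-ratio cutoff (exclusive). Default 0.25.
#' @return List with `wgii` (scalar) and `per_chrom` (named numeric vector of
#'   altered fractions, one per autosome).
#' @export
wgii <- function(segments, genome, threshold = 0.25) {
  stopifnot(inherits(genome, "genome_model"))
  seg <- segments[segments$chrom %in% genome$chrom_names, , drop = FALSE]
  altered <- seg[abs(seg$log2_ratio) > threshold, , drop = FALSE]
  cap <- genome$capture
  per_chrom <- vapply(genome$chrom_names, function(ch) {
    ci <- cap[cap$chrom == ch, , drop = FALSE]
    denom <- if (nrow(ci) == 0) 0 else sum(ci$end - ci$start + 1)
    if (denom == 0)
      stop("configuration error: no captured bases on chromosome ", ch)
    ai <- altered[altered$chrom == ch, , drop = FALSE]
    overlap_bp(ci$start, ci$end, ai$start, ai$end) / denom
  }, numeric(1))
  list(wgii = mean(per_chrom), per_chrom = per_chrom)
}

#' Chromosomal Arm Event Ratio (CAER)
#'
#' For each autosomal arm, the arithmetic mean of the linear Tumor/Normal
#' ratios of the overlapping segments, weighted by their bp of overlap with
#' the arm, is computed first and log2-transformed second. The arm carries an
#' event when the absolute weighted-mean log2 ratio is strictly above the
#' threshold. CAER is the number of arms with an event divided by the size of
#' the arm inventory (44 autosomal arms by default). Arms with no overlapping
#' segment are treated as neutral (ratio 1).
#'
#' @param segments Segment data frame for ONE sample.
#' @param genome A `genome_model`.
#' @param threshold Absolute log2 cutoff on the weighted mean (exclusive).
#'   Default 0.25.
#' @param drop_acrocentric_p Exclude 13p/14p/15p/21p/22p from the inventory.
#' @return List with `caer` (scalar), `n_events`, `n_arms`, and `arm_calls`
#'   (data frame `chrom`, `arm`, `weighted_mean_log2`, `call` in
#'   gain/loss/neutral).
#' @export
caer <- function(segments, genome, threshold = 0.25,
                 drop_acrocentric_p = FALSE) {
  arms <- arm_table(genome, drop_acrocentric_p = drop_acrocentric_p)
  seg <- segments[segments$chrom %in% genome$chrom_names, , drop = FALSE]
  wml <- numeric(nrow(arms))
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    s <- seg[seg$chrom == a$chrom & seg$start <= a$end & seg$end >= a$start, ,
             drop = FALSE]
    if (nrow(s) == 0) { wml[i] <- 0; next }
    w <- pmin(s$end, a$end) - pmax(s$start, a$start) + 1
    wml[i] <- log2(sum(w * s$tn_ratio) / sum(w))
  }
  call <- ifelse(wml > threshold, "gain",
                 ifelse(wml < -threshold, "loss", "neutral"))
  arm_calls <- data.frame(chrom = arms$chrom, arm = arms$arm,
                          weighted_mean_log2 = wml, call = call)
  n_events <- sum(call != "neutral")
  list(caer = n_events / nrow(arms), n_events = n_events, n_arms = nrow(arms),
       arm_calls = arm_calls)
}

#' Copy-number amplitude
#'
#' The highest copy number observed in a sample, taking copy number as twice
#' the linear Tumor/Normal ratio (diploid assumption, no purity correction),
#' rounded half-up. A sample with no segments is diploid (amplitude 2).
#'
#' @param segments Segment data frame for ONE sample.
#' @return Integer amplitude (>= 0).
#' @export
cn_amplitude <- function(segments) {
  if (nrow(segments) == 0) return(2L)
  as.integer(max(floor(2 * segments$tn_ratio + 0.5)))
}
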