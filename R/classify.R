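#' Molecular subset classification
#'
#' An IDH-wild-type glioma specimen is molecularly-defined glioblastoma (mGBM)
#' when it carries at least one of three markers: a TERT promoter mutation
#' (C228 or C250), EGFR amplification, or the combined whole-chromosome-7 gain
#' plus whole-chromosome-10 loss pattern (7+/10-). Specimens with none of the
#' three are "Others". The rule is an evidence union ("and/or").
#'
#' When the sheet carries a `molecular_subset` label that disagrees with the
#' marker rule, a warning is raised and, with `label_precedence = TRUE`
#' (default), the provided label wins — cohorts curated with expert review
#' (e.g. methylation-confirmed entities) can overrule the three-marker rule.
#'
#' @param sheet Sample-sheet data frame (see [read_sample_sheet()]).
#' @param label_precedence Keep a provided `molecular_subset` label when it
#'   conflicts with the marker rule. Default TRUE.
#' @return Data frame: `analysis_id`, `subset` (mGBM / Others), `evidence`
#'   (comma-separated markers among TERT_promoter, EGFR_amplification,
#'   7plus_10minus), `rule_subset` (the pure marker-rule call), `discordant`.
#' @export
classify_subset <- function(sheet, label_precedence = TRUE) {
  needed <- c("tert", "egfr_amp", "seven_plus_ten_minus")
  for (f in needed)
    if (any(is.na(sheet[[f]]) | sheet[[f]] == ""))
      stop("unclassifiable: missing ", f, " for ",
           sheet$analysis_id[which(is.na(sheet[[f]]) | sheet[[f]] == "")[1]])
  ev <- cbind(
    TERT_promoter = sheet$tert %in% c("C228", "C250"),
    EGFR_amplification = sheet$egfr_amp == "amplification",
    `7plus_10minus` = as.logical(sheet$seven_plus_ten_minus)
  )
  rule_subset <- ifelse(rowSums(ev) > 0, "mGBM", "Others")
  evidence <- apply(ev, 1, function(r)
    paste(colnames(ev)[r], collapse = ","))
  subset <- rule_subset
  discordant <- rep(FALSE, nrow(sheet))
  if (!is.null(sheet$molecular_subset)) {
    lab <- sheet$molecular_subset
    has_lab <- !is.na(lab) & lab != ""
    discordant <- has_lab & lab != rule_subset
    if (any(discordant))
      warning("marker rule disagrees with provided label for: ",
              paste(sheet$analysis_id[discordant], collapse = ", "),
              if (label_precedence) " (provided label kept)" else
                " (marker rule kept)")
    if (label_precedence) subset[has_lab] <- lab[has_lab]
  }
  data.frame(analysis_id = sheet$analysis_id, subset = subset,
             evidence = evidence, rule_subset = rule_subset,
             discordant = discordant)
}

#' Derive the 7+/10- flag from segments
#'
#' TRUE iff the length-weighted mean log2 ratio (computed as in [caer()]) is
#' strictly above +0.25 on BOTH arms of chromosome 7 AND strictly below -0.25
#' on BOTH arms of chromosome 10.
#'
#' @param segments Segment data frame for ONE sample.
#' @param genome A `genome_model`.
#' @param threshold Log2 cutoff. Default 0.25.
#' @param chrom_gain,chrom_loss Chromosome names to test. Defaults "7", "10".
#' @return Logical scalar.
#' @export
derive_7plus_10minus <- function(segments, genome, threshold = 0.25,
                                 chrom_gain = "7", chrom_loss = "10") {
  ac <- caer(segments, genome, threshold = threshold)$arm_calls
  g <- ac[ac$chrom == chrom_gain, ]
  l <- ac[ac$chrom == chrom_loss, ]
  nrow(g) == 2 && all(g$call == "gain") &&
    nrow(l) == 2 && all(l$call == "loss")
}
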