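#' Somatic variant filtering
#'
#' Retains calls with VAF strictly above 5%, tumor depth strictly above 20x
#' and normal depth strictly above 10x. All three cuts are strict
#' inequalities: a variant at VAF exactly 0.05 is removed.
#'
#' @param variants Variant data frame (see [read_variants()]).
#' @param min_vaf VAF cutoff (exclusive). Default 0.05.
#' @param min_t_depth Tumor depth cutoff (exclusive). Default 20.
#' @param min_n_depth Normal depth cutoff (exclusive). Default 10.
#' @return The retained subset, same columns.
#' @export
filter_somatic <- function(variants, min_vaf = 0.05, min_t_depth = 20,
                           min_n_depth = 10) {
  keep <- variants$vaf > min_vaf &
    variants$t_depth > min_t_depth &
    variants$n_depth > min_n_depth
  variants[keep, , drop = FALSE]
}

#' SNV and indel burden per captured megabase
#'
#' Counts filtered somatic SNVs and indels that fall inside the capture
#' intervals of autosomes and divides by the captured size in Mb. Variants on
#' sex chromosomes or outside the capture design are excluded from the
#' numerator; the denominator is always the full captured autosomal size.
#'
#' @param variants Filtered variant data frame (apply [filter_somatic()]
#'   first).
#' @param genome A `genome_model`.
#' @return Data frame with one row per sample: `sample`, `n_snv_pass`,
#'   `n_indel_pass`, `exome_mb`, `snv_burden`, `indel_burden`. Samples absent
#'   from `variants` are absent here; pass an empty table to get zero rows.
#' @export
compute_burdens <- function(variants, genome) {
  stopifnot(inherits(genome, "genome_model"))
  mb <- capture_size_mb(genome)
  if (mb <= 0) stop("configuration error: capture size is zero")
  v <- variants[variants$chrom %in% genome$chrom_names, , drop = FALSE]
  v <- v[in_capture(v$chrom, v$pos, genome), , drop = FALSE]
  samples <- unique(variants$sample)
  out <- do.call(rbind, lapply(samples, function(s) {
    vs <- v[v$sample == s, , drop = FALSE]
    n_snv <- sum(vs$variant_type == "SNV")
    n_indel <- sum(vs$variant_type %in% c("INS", "DEL"))
    data.frame(sample = s, n_snv_pass = n_snv, n_indel_pass = n_indel,
               exome_mb = mb, snv_burden = n_snv / mb,
               indel_burden = n_indel / mb)
  }))
  if (is.null(out))
    out <- data.frame(sample = character(), n_snv_pass = integer(),
                      n_indel_pass = integer(), exome_mb = numeric(),
                      snv_burden = numeric(), indel_burden = numeric())
  rownames(out) <- NULL
  out
}

# logical: is position inside a capture interval of its chromosome
in_capture <- function(chrom, pos, genome) {
  if (length(chrom) == 0) return(logical(0))
  out <- logical(length(chrom))
  cap <- genome$capture
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    ci <- cap[cap$chrom == ch, , drop = FALSE]
    if (nrow(ci) == 0) next
    ir <- IRanges::IRanges(ci$start, ci$end)
    out[idx] <- IRanges::countOverlaps(
      IRanges::IRanges(pos[idx], pos[idx]), ir) > 0
  }
  out
}

#' High-impact classification list
#'
#' The nine MAF classes counted as protein-affecting when associating mutated
#' genes with metrics.
#' @export
HIGH_IMPACT_CLASSES <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
  "Translation_Start_Site", "Nonsense_Mutation", "Nonstop_Mutation",
  "In_Frame_Del", "In_Frame_Ins", "Missense_Mutation"
)

#' Genes carrying high-impact variants per sample
#'
#' A variant is high-impact if its VAF is strictly above 5% and its MAF class
#' is one of the nine in [HIGH_IMPACT_CLASSES]. Only the VAF condition applies
#' here (no depth condition). Silent and other classes never qualify.
#'
#' @param variants Variant data frame.
#' @param min_vaf VAF cutoff (exclusive). Default 0.05.
#' @return Named list: sample id to character vector of unique gene symbols.
#' @export
high_impact_genes <- function(variants, min_vaf = 0.05) {
  hi <- variants[variants$vaf > min_vaf &
                   variants$variant_class %in% HIGH_IMPACT_CLASSES &
                   !is.na(variants$gene) & variants$gene != "", , drop = FALSE]
  samples <- unique(variants$sample)
  out <- lapply(samples, function(s)
    sort(unique(hi$gene[hi$sample == s])))
  names(out) <- samples
  out
}
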