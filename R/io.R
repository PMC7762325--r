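#' File formats
#'
#' All tabular inputs are plain TSV with a header line; coordinates are
#' 1-based inclusive everywhere inside the package. BED input (capture design,
#' oncogene intervals) is 0-based half-open and is converted at the boundary.
#' Chromosome names may carry a "chr" prefix; it is stripped on read.
#'
#' Schemas:
#' \itemize{
#'   \item variants: `sample, chrom, pos, ref, alt, variant_class, vaf,
#'     t_depth, n_depth, gene` (a minimal MAF-like table); `variant_type` is
#'     derived from allele lengths (SNV / INS / DEL).
#'   \item segments: `sample, chrom, start, end, tn_ratio` (SEG-like, linear
#'     Tumor/Normal ratio); `log2_ratio` is derived.
#'   \item sv: `sample, chrom1, pos1, chrom2, pos2, sv_type` (BEDPE-like
#'     breakend pairs, types DEL/DUP/INV/TRA).
#'   \item sample sheet: `patient_id, analysis_id, primary_status, gender,
#'     age, sample_type, atrx, tert, h3, egfr_amp, seven_plus_ten_minus,
#'     other_drivers, molecular_subset` (extra columns are carried through).
#'   \item cytoband: `chrom, arm, start, end` with one p and one q row per
#'     chromosome.
#' }
#'
#' @name gliomaburden-io
NULL

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA"), quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a capture BED file
#'
#' Converts 0-based half-open BED records to 1-based inclusive intervals,
#' sorts and merges them.
#'
#' @param path BED file path (3+ columns, no header).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive, merged).
#' @export
read_capture_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 1L)
  if (any(n < 3))
    stop("parse error in ", basename(path), " at line ", which(n < 3)[1],
         ": fewer than 3 fields")
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0
  if (any(bad))
    stop("parse error in ", basename(path), " at line ", which(bad)[1],
         ": invalid coordinates")
  df <- data.frame(chrom = normalize_chrom(vapply(fields, `[[`, "", 1)),
                   start = start0 + 1, end = end0)
  merge_intervals(df)
}

#' Write intervals as BED
#'
#' Inverse of [read_capture_bed()]: 1-based inclusive back to 0-based
#' half-open.
#' @param df Interval data frame (`chrom`, `start`, `end`).
#' @param path Output path.
#' @export
write_capture_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1, end = df$end)
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

variant_required <- c("sample", "chrom", "pos", "ref", "alt", "variant_class",
                      "vaf", "t_depth", "n_depth", "gene")

#' Classify variant type from allele lengths
#'
#' SNV iff both alleles are single bases, INS iff alt longer than ref, DEL iff
#' ref longer than alt.
#' @param ref,alt Allele strings.
#' @return Character vector in `{"SNV","INS","DEL"}`.
#' @export
variant_type_of <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep(NA_character_, length(lr))
  out[lr == 1 & la == 1] <- "SNV"
  out[la > lr] <- "INS"
  out[lr > la] <- "DEL"
  if (anyNA(out))
    stop("cannot type variant with equal-length multi-base alleles ",
         "(split multi-nucleotide substitutions upstream)")
  out
}

#' Read / write somatic variant tables
#'
#' @param path TSV path (see [gliomaburden-io] for the schema).
#' @return Data frame of variant records with derived `variant_type`.
#' @export
read_variants <- function(path) {
  df <- read_tsv_checked(path, variant_required)
  df$chrom <- normalize_chrom(df$chrom)
  df$gene <- ifelse(is.na(df$gene), "", df$gene)
  df$vaf <- as.numeric(df$vaf)
  if (any(df$vaf < 0 | df$vaf > 1))
    stop("vaf outside [0, 1] in ", basename(path))
  df$variant_type <- variant_type_of(df$ref, df$alt)
  df
}

#' @rdname read_variants
#' @param variants Variant data frame.
#' @export
write_variants <- function(variants, path) {
  write_tsv_plain(variants[, variant_required], path)
}

#' Read / write copy-number segment tables
#'
#' @param path SEG-like TSV path.
#' @return Data frame of segments with derived `log2_ratio`.
#' @export
read_segments <- function(path) {
  df <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                 "tn_ratio"))
  df$chrom <- normalize_chrom(df$chrom)
  df$tn_ratio <- as.numeric(df$tn_ratio)
  if (any(df$tn_ratio <= 0)) stop("tn_ratio must be > 0 in ", basename(path))
  if (any(df$start > df$end)) stop("segment start > end in ", basename(path))
  df$log2_ratio <- log2(df$tn_ratio)
  df
}

#' @rdname read_segments
#' @param segments Segment data frame.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("sample", "chrom", "start", "end", "tn_ratio")]
  out$tn_ratio <- format(out$tn_ratio, digits = 15, scientific = FALSE,
                         trim = TRUE)
  write_tsv_plain(out, path)
}

#' Read / write structural-variant breakend tables
#'
#' @param path BEDPE-like TSV path.
#' @return Data frame of SV breakend pairs.
#' @export
read_sv <- function(path) {
  df <- read_tsv_checked(path, c("sample", "chrom1", "pos1", "chrom2", "pos2",
                                 "sv_type"))
  df$chrom1 <- normalize_chrom(df$chrom1)
  df$chrom2 <- normalize_chrom(df$chrom2)
  bad <- !df$sv_type %in% c("DEL", "DUP", "INV", "TRA")
  if (any(bad)) stop("unknown sv_type in ", basename(path))
  df
}

#' @rdname read_sv
#' @param sv SV data frame.
#' @export
write_sv <- function(sv, path) {
  write_tsv_plain(sv[, c("sample", "chrom1", "pos1", "chrom2", "pos2",
                         "sv_type")], path)
}

#' Read oncogene intervals
#'
#' BED with a fourth name column; converted to 1-based inclusive.
#' @param path BED path.
#' @return Data frame `gene`, `chrom`, `start`, `end`.
#' @export
read_oncogenes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 1L)
  if (any(n < 4))
    stop("parse error in ", basename(path), " at line ", which(n < 4)[1],
         ": oncogene BED needs 4 fields")
  df <- data.frame(gene = vapply(fields, `[[`, "", 4),
                   chrom = normalize_chrom(vapply(fields, `[[`, "", 1)),
                   start = as.numeric(vapply(fields, `[[`, "", 2)) + 1,
                   end = as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyDuplicated(df$gene)) stop("duplicate oncogene symbols in ",
                                   basename(path))
  df
}

#' @rdname read_oncogenes
#' @param oncogenes Oncogene data frame.
#' @export
write_oncogenes <- function(oncogenes, path) {
  out <- data.frame(chrom = oncogenes$chrom, start = oncogenes$start - 1,
                    end = oncogenes$end, gene = oncogenes$gene)
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

sheet_required <- c("patient_id", "analysis_id", "primary_status", "gender",
                    "age", "sample_type", "atrx", "tert", "h3", "egfr_amp",
                    "seven_plus_ten_minus")

#' Read a sample sheet
#'
#' Blank `patient_id` cells (multi-sample patients listed once) are filled
#' down. `seven_plus_ten_minus` is parsed as logical.
#'
#' @param path TSV path.
#' @return Data frame of sample-sheet records.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, sheet_required)
  pid <- as.character(df$patient_id)
  for (i in seq_along(pid))
    if (is.na(pid[i]) || pid[i] == "") pid[i] <- pid[i - 1]
  df$patient_id <- pid
  df$age <- as.numeric(df$age)
  if (any(df$age <= 0)) stop("non-positive age in ", basename(path))
  df$seven_plus_ten_minus <- toupper(df$seven_plus_ten_minus) %in%
    c("TRUE", "T", "1", "YES")
  bad <- !df$primary_status %in% c("primary", "recurrent")
  if (any(bad)) stop("invalid primary_status in ", basename(path))
  df
}

#' Packaged Table-1-style cohort sheet
#'
#' The 45-specimen / 39-patient IDH-wild-type glioma cohort sheet bundled with
#' the package.
#' @return Sample-sheet data frame.
#' @export
cohort_sheet <- function() {
  read_sample_sheet(system.file("extdata", "table1.tsv",
                                package = "gliomaburden", mustWork = TRUE))
}

#' Build a genome model from cytoband and capture files
#'
#' The cytoband TSV gives one p and one q row per chromosome; the p-arm end is
#' taken as the centromere and the q-arm end as the chromosome length.
#'
#' @param cytoband_path Cytoband TSV (`chrom`, `arm`, `start`, `end`).
#' @param capture_bed_path Capture BED.
#' @param autosomes_only Keep only chromosomes named 1..22.
#' @return A `genome_model`.
#' @export
genome_from_cytoband <- function(cytoband_path, capture_bed_path,
                                 autosomes_only = TRUE) {
  cb <- read_tsv_checked(cytoband_path, c("chrom", "arm", "start", "end"))
  cb$chrom <- normalize_chrom(cb$chrom)
  if (autosomes_only) cb <- cb[cb$chrom %in% as.character(1:22), ]
  p <- cb[cb$arm == "p", ]
  q <- cb[cb$arm == "q", ]
  chroms <- intersect(unique(cb$chrom), p$chrom)
  chroms <- intersect(chroms, q$chrom)
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)))]
  cen <- p$end[match(chroms, p$chrom)]
  len <- q$end[match(chroms, q$chrom)]
  capture <- read_capture_bed(capture_bed_path)
  capture <- capture[capture$chrom %in% chroms, ]
  genome_model(chroms, len, cen, capture)
}

#' Read / write a signature matrix
#'
#' TSV with a `channel` column (96 trinucleotide substitution classes) and one
#' column per signature; each signature column is a probability vector.
#'
#' @param path TSV path.
#' @return Numeric matrix, 96 rows (channels) by k signatures.
#' @export
read_signature_matrix <- function(path) {
  df <- read_tsv_checked(path, "channel")
  m <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  rownames(m) <- df$channel
  validate_signature_matrix(m)
  m
}

#' @rdname read_signature_matrix
#' @param mat Signature matrix.
#' @export
write_signature_matrix <- function(mat, path) {
  df <- data.frame(channel = rownames(mat), mat, check.names = FALSE)
  write_tsv_plain(df, path)
}

#' Read / write mutation catalogs
#'
#' TSV with a `channel` column and one integer count column per sample.
#' @param path TSV path.
#' @return Integer matrix, 96 rows by n samples.
#' @export
read_catalogs <- function(path) {
  df <- read_tsv_checked(path, "channel")
  m <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  rownames(m) <- df$channel
  if (nrow(m) != 96) stop("catalog must have 96 channels")
  m
}

#' @rdname read_catalogs
#' @param catalogs Catalog matrix.
#' @export
write_catalogs <- function(catalogs, path) {
  df <- data.frame(channel = rownames(catalogs), catalogs, check.names = FALSE)
  write_tsv_plain(df, path)
}
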