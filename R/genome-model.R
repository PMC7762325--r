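#' Genome model: autosome inventory, arm boundaries and capture intervals
#'
#' A `genome_model` bundles everything the burden and instability metrics need
#' to know about the reference genome and the exome assay: the ordered autosome
#' names, chromosome lengths, centromere positions splitting each chromosome
#' into a p arm `[1, centromere]` and a q arm `(centromere, length]`, and the
#' capture intervals of the exome kit (1-based, inclusive, sorted, merged).
#'
#' Only autosomes enter any metric; sex-chromosome records in input files are
#' parsed but dropped at the metric stage.
#'
#' @param chrom_names Character vector of autosome identifiers (unprefixed).
#' @param chrom_lengths Numeric vector of chromosome lengths in bp, one per
#'   chromosome.
#' @param centromere_pos Numeric vector of centromere positions in bp
#'   (strictly inside each chromosome).
#' @param capture Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) giving the capture intervals. Overlapping or abutting intervals
#'   are merged; intervals must lie within chromosome bounds.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_names, chrom_lengths, centromere_pos, capture) {
  chrom_names <- as.character(chrom_names)
  stopifnot(length(chrom_lengths) == length(chrom_names),
            length(centromere_pos) == length(chrom_names))
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), chrom_names)
  centromere_pos <- stats::setNames(as.numeric(centromere_pos), chrom_names)
  if (any(centromere_pos <= 0) || any(centromere_pos >= chrom_lengths))
    stop("centromere positions must lie strictly inside their chromosomes")
  capture <- as.data.frame(capture)
  stopifnot(all(c("chrom", "start", "end") %in% names(capture)))
  capture$chrom <- normalize_chrom(capture$chrom)
  unknown <- setdiff(unique(capture$chrom), chrom_names)
  if (length(unknown) > 0)
    stop("capture intervals on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  bad <- capture$start < 1 | capture$end > chrom_lengths[capture$chrom]
  if (any(bad))
    stop("capture interval beyond chromosome bounds at row ", which(bad)[1])
  capture <- merge_intervals(capture)
  if (interval_total_bp(capture) <= 0) stop("total capture size must be > 0")
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         centromere_pos = centromere_pos, capture = capture),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "autosomes,",
      sprintf("%.1f", sum(x$chrom_lengths) / 1e6), "Mb genome,",
      sprintf("%.3f", capture_size_mb(x)), "Mb captured\n")
  invisible(x)
}

#' Toy desk-scale genome
#'
#' Default test genome: `n_chrom` autosomes of `chrom_length` bp each,
#' centromere at `centromere` bp, and a capture design of `tile_width`-bp tiles
#' every `tile_spacing` bp (a caricature of an exome kit: small islands of
#' captured sequence spread along each chromosome). With the defaults each
#' chromosome carries 1000 tiles of 1 kb, i.e. 1 Mb captured per chromosome and
#' 22 Mb in total.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Chromosome length in bp.
#' @param centromere Centromere position in bp.
#' @param tile_width,tile_spacing Capture tile width and period in bp.
#' @return A `genome_model`.
#' @export
toy_genome <- function(n_chrom = 22, chrom_length = 1e7, centromere = 4e6,
                       tile_width = 1000, tile_spacing = 10000) {
  chroms <- as.character(seq_len(n_chrom))
  starts <- seq(1, chrom_length - tile_width + 1, by = tile_spacing)
  capture <- data.frame(
    chrom = rep(chroms, each = length(starts)),
    start = rep(starts, times = n_chrom),
    end = rep(starts + tile_width - 1, times = n_chrom)
  )
  genome_model(chroms, rep(chrom_length, n_chrom), rep(centromere, n_chrom),
               capture)
}

#' Autosomal arm inventory
#'
#' One row per chromosome arm with its boundaries. The CAER denominator is the
#' number of rows of this table (44 for a 22-autosome genome); the five
#' acrocentric p arms (13p, 14p, 15p, 21p, 22p) can be excluded for
#' real-genome runs where they carry no captured sequence.
#'
#' @param genome A `genome_model`.
#' @param drop_acrocentric_p Drop 13p/14p/15p/21p/22p from the inventory.
#' @return Data frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
arm_table <- function(genome, drop_acrocentric_p = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  cen <- genome$centromere_pos
  len <- genome$chrom_lengths
  arms <- rbind(
    data.frame(chrom = genome$chrom_names, arm = "p",
               start = 1, end = unname(cen)),
    data.frame(chrom = genome$chrom_names, arm = "q",
               start = unname(cen) + 1, end = unname(len))
  )
  arms <- arms[order(match(arms$chrom, genome$chrom_names), arms$arm), ]
  if (drop_acrocentric_p) {
    acro <- paste0(c("13", "14", "15", "21", "22"), "p")
    arms <- arms[!(paste0(arms$chrom, arms$arm) %in% acro), ]
  }
  rownames(arms) <- NULL
  if (nrow(arms) == 0) stop("empty arm inventory")
  arms
}

#' Total captured size in Mb
#' @param genome A `genome_model`.
#' @return Captured megabases (numeric scalar).
#' @export
capture_size_mb <- function(genome) {
  interval_total_bp(genome$capture) / 1e6
}

# --- interval helpers (1-based inclusive throughout) ------------------------

#' Normalize chromosome names
#'
#' Accepts "chr7" or "7"; returns the unprefixed form used internally.
#' @param x Character vector of chromosome names.
#' @return Character vector without the "chr" prefix.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Sort and merge intervals
#'
#' Merges overlapping and abutting intervals per chromosome. Idempotent.
#' @param df Data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return Merged data frame, sorted by chromosome then start.
#' @export
merge_intervals <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  stopifnot(all(df$start <= df$end))
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r),
               end = IRanges::end(r))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Total interval length in bp
#' @param df Interval data frame (`chrom`, `start`, `end`, 1-based inclusive).
#' @return Total bp after merging.
#' @export
interval_total_bp <- function(df) {
  m <- merge_intervals(df)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start + 1)
}

# bp of overlap between two interval sets restricted to one chromosome
overlap_bp <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0 || length(b_start) == 0) return(0)
  ia <- IRanges::reduce(IRanges::IRanges(a_start, a_end))
  ib <- IRanges::reduce(IRanges::IRanges(b_start, b_end))
  ov <- IRanges::intersect(ia, ib)
  sum(IRanges::width(ov))
}
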