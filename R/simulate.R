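#' Toy oncogene annotation
#'
#' A small oncogene inventory placed on the toy genome, using loci that mirror
#' the genes recurrently found on glioma double minutes (EGFR/SEC61G/MET on
#' chromosome 7, MDM2/CDK4/AGAP2 on chromosome 12, plus a few others).
#' Coordinates are toy-genome coordinates, not hg19.
#'
#' @return Oncogene data frame (`gene`, `chrom`, `start`, `end`).
#' @export
toy_oncogenes <- function() {
  data.frame(
    gene = c("EGFR", "SEC61G", "MET", "MDM2", "CDK4", "AGAP2", "MYCN",
             "CCND1"),
    chrom = c("7", "7", "7", "12", "12", "12", "2", "11"),
    start = c(2000001, 1900001, 8000001, 6000001, 5800001, 5700001, 1000001,
              6900001),
    end = c(2200000, 1950000, 8100000, 6100000, 5850000, 5750000, 1100000,
            7000000)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the statistical character of an IDH-wild-type glioma
#' exome cohort: median-scale SNV rate 3.4/Mb and indel rate 0.4/Mb, VAF ~
#' Beta(8, 12) (mean 0.4), tumor/normal depths Poisson with means 200/120,
#' 20% sub-threshold filter fodder, arm events with log2 shift +/-0.585
#' (Tumor/Normal 1.5 or 0.5), chromothripsis as a 5-Mb cluster of 30
#' copy-number switches oscillating between ratios 1.0 and 0.5, double-minute
#' amplicons at ratio 8 and width 2 Mb over an oncogene, and an 80% mGBM
#' labeling fraction. Per-sample lognormal intensity multipliers (one for
#' mutational rates, one for copy-number event rates) couple the metrics
#' within each of the two mechanism families; chromothripsis and double
#' minutes are assigned to the samples with the highest copy-number intensity.
#'
#' @param seed Integer seed fixing the full cohort byte-for-byte.
#' @param n_samples Number of tumor samples.
#' @param snv_rate,indel_rate Expected passing events per captured Mb.
#' @param mutation_dispersion,cna_dispersion Lognormal sigma of the
#'   per-sample intensity multipliers (0 = homogeneous cohort).
#' @param vaf_shape Beta(a, b) parameters of the VAF distribution.
#' @param depth_means Poisson means, `c(tumor, normal)`.
#' @param subthreshold_fraction Fraction of all planted variants failing at
#'   least one filter.
#' @param arm_event_prob Per-arm event probability (before the intensity
#'   multiplier).
#' @param arm_log2_shift Absolute log2 shift of an arm event.
#' @param segment_noise_sd Log2 noise sd of neutral segments (truncated at
#'   +/-0.2 so neutral segments never cross the 0.25 alteration threshold).
#' @param n_ct_samples,n_dm_samples Number of samples carrying a planted
#'   chromothripsis cluster / double minute. NULL = 40% of the cohort.
#' @param ct_span,ct_switches,ct_levels Chromothripsis cluster span (bp),
#'   number of state switches, and the two alternating Tumor/Normal levels.
#' @param dm_ratio,dm_width,dm_oncogene,dm_rule,dm_with_sv Double-minute
#'   amplicon ratio (>= 5), width (bp), target oncogene, planted rule ("a" =
#'   two amplicons, "b" = single amplicon with SV), and whether breakends are
#'   planted at the amplicon.
#' @param signature_matrix 96 x k probability matrix (default 4 synthetic
#'   signatures).
#' @param exposures Per-sample exposure fractions: vector (recycled) or
#'   n_samples x k matrix; rows must sum to 1.
#' @param n_catalog_mutations Mutations per simulated catalog.
#' @param mgbm_fraction Fraction of samples labelled mGBM.
#' @param recurrent_fraction Fraction of samples labelled recurrent.
#' @param n_background_sv Background translocation breakend pairs per sample.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 17, n_samples = 20, snv_rate = 3.4,
                          indel_rate = 0.4, mutation_dispersion = 0.8,
                          cna_dispersion = 0.8, vaf_shape = c(8, 12),
                          depth_means = c(tumor = 200, normal = 120),
                          subthreshold_fraction = 0.2, arm_event_prob = 0.08,
                          arm_log2_shift = 0.585, segment_noise_sd = 0.05,
                          n_ct_samples = NULL, n_dm_samples = NULL,
                          ct_span = 5e6, ct_switches = 30,
                          ct_levels = c(1.0, 0.5), dm_ratio = 8,
                          dm_width = 2e6, dm_oncogene = "EGFR",
                          dm_rule = "a", dm_with_sv = TRUE,
                          signature_matrix = NULL, exposures = NULL,
                          n_catalog_mutations = 2000, mgbm_fraction = 0.8,
                          recurrent_fraction = 0.18, n_background_sv = 2) {
  if (is.null(n_ct_samples)) n_ct_samples <- round(0.4 * n_samples)
  if (is.null(n_dm_samples)) n_dm_samples <- round(0.4 * n_samples)
  if (is.null(signature_matrix))
    signature_matrix <- synthetic_signature_matrix(4, seed = 99)
  if (is.null(exposures)) {
    k <- ncol(signature_matrix)
    exposures <- stats::setNames(c(0.45, 0.30, 0.15, 0.10)[seq_len(min(k, 4))],
                                 colnames(signature_matrix)[seq_len(min(k, 4))])
    exposures <- exposures / sum(exposures)
  }
  stopifnot(snv_rate >= 0, indel_rate >= 0,
            subthreshold_fraction >= 0, subthreshold_fraction < 1,
            arm_event_prob >= 0, arm_event_prob <= 1,
            dm_ratio >= 5, n_ct_samples <= n_samples,
            n_dm_samples <= n_samples)
  structure(mget(names(formals()), envir = environment()),
            class = "cohort_config")
}

trunc_norm <- function(n, sd, limit = 0.2) {
  if (sd == 0) return(rep(0, n))
  pmax(-limit, pmin(limit, stats::rnorm(n, 0, sd)))
}

# fill [1, len] minus `occupied` intervals with neutral noise segments
fill_neutral <- function(occupied, len, noise_sd) {
  full <- IRanges::IRanges(1, len)
  occ <- if (nrow(occupied) == 0) IRanges::IRanges() else
    IRanges::reduce(IRanges::IRanges(occupied$start, occupied$end))
  gaps <- IRanges::setdiff(full, occ)
  out <- list()
  for (i in seq_along(gaps)) {
    s <- IRanges::start(gaps)[i]; e <- IRanges::end(gaps)[i]
    n_break <- stats::rpois(1, 1)
    cuts <- sort(unique(c(s - 1, e,
                          if (n_break > 0) floor(stats::runif(n_break, s, e)))))
    for (j in seq_len(length(cuts) - 1)) {
      a <- cuts[j] + 1; b <- cuts[j + 1]
      if (a > b) next
      out[[length(out) + 1]] <- data.frame(
        start = a, end = b, tn_ratio = 2^trunc_norm(1, noise_sd))
    }
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      tn_ratio = numeric()))
  do.call(rbind, out)
}

# clip [start, end] around already-occupied intervals; returns kept pieces
clip_interval <- function(start, end, occupied) {
  new <- IRanges::IRanges(start, end)
  if (nrow(occupied) > 0) {
    occ <- IRanges::reduce(IRanges::IRanges(occupied$start, occupied$end))
    new <- IRanges::setdiff(new, occ)
  }
  data.frame(start = IRanges::start(new), end = IRanges::end(new))
}

#' Simulate a cohort with planted ground truth
#'
#' Generates, for each sample, the somatic variant table, the copy-number
#' segment table (full genome coverage, non-overlapping), the
#' structural-variant breakends, a 96-channel mutation catalog and a
#' sample-sheet row, together with a ground-truth manifest recording the
#' planted burdens, arm events, altered fraction per chromosome,
#' chromothripsis and double-minute loci and signature exposures. When `dir`
#' is given all tables are written as the package's TSV formats plus a JSON
#' manifest; an identical seed reproduces the files byte-for-byte.
#'
#' @param config A `cohort_config`.
#' @param genome A `genome_model` (default [toy_genome()]).
#' @param oncogenes Oncogene annotation (default [toy_oncogenes()]).
#' @param dir Optional output directory (created if missing).
#' @return Invisibly, a list with `variants`, `segments`, `sv`, `sheet`,
#'   `catalogs`, `signature_matrix`, `manifest`.
#' @export
simulate_cohort <- function(config, genome = toy_genome(),
                            oncogenes = toy_oncogenes(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(genome, "genome_model"))
  cfg <- config
  if (!cfg$dm_oncogene %in% oncogenes$gene)
    stop("configuration error: oncogene ", cfg$dm_oncogene,
         " not in the annotation")
  onc_row <- oncogenes[oncogenes$gene == cfg$dm_oncogene, ]
  if (!onc_row$chrom %in% genome$chrom_names)
    stop("configuration error: oncogene chromosome not in genome")
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("SIM-%03d", seq_len(n))
  mb <- capture_size_mb(genome)
  cap <- genome$capture
  arms <- arm_table(genome)

  # per-sample latent intensities
  m_mult <- exp(stats::rnorm(n, 0, cfg$mutation_dispersion) -
                  cfg$mutation_dispersion^2 / 2)
  g_mult <- exp(stats::rnorm(n, 0, cfg$cna_dispersion) -
                  cfg$cna_dispersion^2 / 2)
  ct_samples <- ids[order(-g_mult)][seq_len(cfg$n_ct_samples)]
  dm_samples <- ids[order(-g_mult)][seq_len(cfg$n_dm_samples)]

  # subset labels and sheet fields
  n_mgbm <- round(cfg$mgbm_fraction * n)
  subset <- c(rep("mGBM", n_mgbm), rep("Others", n - n_mgbm))
  tert <- rep("WT", n); egfr <- rep("copy neutral", n); s710 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (subset[i] != "mGBM") next
    ev <- c(tert = stats::runif(1) < 0.6, egfr = stats::runif(1) < 0.6,
            s710 = stats::runif(1) < 0.5)
    if (!any(ev)) ev[sample.int(3, 1)] <- TRUE
    if (ev["tert"]) tert[i] <- sample(c("C228", "C250"), 1)
    if (ev["egfr"]) egfr[i] <- "amplification"
    if (ev["s710"]) s710[i] <- TRUE
  }
  n_rec <- round(cfg$recurrent_fraction * n)
  status <- sample(c(rep("recurrent", n_rec), rep("primary", n - n_rec)))
  sheet <- data.frame(
    patient_id = ids, analysis_id = ids, primary_status = status,
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
    age = pmin(85, pmax(18, round(stats::rnorm(n, 51, 12)))),
    sample_type = sample(c("LiN2", "FFPE"), n, replace = TRUE,
                         prob = c(0.6, 0.4)),
    atrx = sample(c("WT", "MUT"), n, replace = TRUE, prob = c(0.8, 0.2)),
    tert = tert, h3 = "WT", egfr_amp = egfr, seven_plus_ten_minus = s710,
    other_drivers = "", molecular_subset = subset
  )

  variants <- list(); segments <- list(); svs <- list()
  catalogs <- matrix(0L, nrow = 96, ncol = n,
                     dimnames = list(rownames(cfg$signature_matrix), ids))
  expo <- cfg$exposures
  if (is.null(dim(expo)))
    expo <- matrix(expo, nrow = n, ncol = length(expo), byrow = TRUE,
                   dimnames = list(ids, names(expo)))
  if (is.null(rownames(expo))) rownames(expo) <- ids
  if (any(abs(rowSums(expo) - 1) > 1e-6))
    stop("configuration error: exposures must sum to 1")
  manifest <- list(seed = cfg$seed, n_samples = n, capture_mb = mb,
                   samples = list())

  cap_by_chrom <- split(cap, cap$chrom)
  cap_bp <- vapply(genome$chrom_names, function(ch) {
    ci <- cap_by_chrom[[ch]]
    if (is.null(ci)) 0 else sum(ci$end - ci$start + 1)
  }, numeric(1))

  for (i in seq_len(n)) {
    id <- ids[i]
    # ---- copy-number specials (priority: DM > CT > 7+/10- > arm events) ----
    spec <- stats::setNames(
      rep(list(data.frame(start = numeric(), end = numeric(),
                          tn_ratio = numeric())), length(genome$chrom_names)),
      genome$chrom_names)
    truth <- list(sample = id)
    busy_chroms <- character(0)

    if (id %in% dm_samples) {
      ch <- onc_row$chrom
      mid <- floor((onc_row$start + onc_row$end) / 2)
      a_start <- max(1, mid - floor(cfg$dm_width / 2))
      a_end <- min(genome$chrom_lengths[[ch]], a_start + cfg$dm_width - 1)
      spec[[ch]] <- rbind(spec[[ch]],
                          data.frame(start = a_start, end = a_end,
                                     tn_ratio = cfg$dm_ratio))
      dm_loci <- data.frame(chrom = ch, start = a_start, end = a_end)
      if (cfg$dm_rule == "a") {
        ch2 <- genome$chrom_names[length(genome$chrom_names)]
        if (ch2 == ch) ch2 <- genome$chrom_names[1]
        b_start <- floor(genome$chrom_lengths[[ch2]] / 2)
        b_end <- b_start + 5e5 - 1
        spec[[ch2]] <- rbind(spec[[ch2]],
                             data.frame(start = b_start, end = b_end,
                                        tn_ratio = cfg$dm_ratio * 0.75))
        dm_loci <- rbind(dm_loci,
                         data.frame(chrom = ch2, start = b_start, end = b_end))
      }
      if (cfg$dm_with_sv)
        svs[[length(svs) + 1]] <- data.frame(
          sample = id, chrom1 = ch, pos1 = a_start + 50,
          chrom2 = ch, pos2 = a_end - 50, sv_type = "DUP")
      busy_chroms <- union(busy_chroms, dm_loci$chrom)
      truth$dm <- list(present = TRUE, rule = cfg$dm_rule,
                       oncogene = cfg$dm_oncogene, loci = dm_loci)
    } else truth$dm <- list(present = FALSE)

    if (id %in% ct_samples) {
      allowed <- setdiff(genome$chrom_names, c("7", "10", busy_chroms))
      ch <- sample(allowed, 1)
      len <- genome$chrom_lengths[[ch]]
      span_start <- floor(stats::runif(1, 1, len - cfg$ct_span))
      n_seg <- cfg$ct_switches + 1
      bounds <- round(seq(span_start, span_start + cfg$ct_span, length.out =
                            n_seg + 1))
      lev <- rep(cfg$ct_levels, length.out = n_seg)
      spec[[ch]] <- rbind(spec[[ch]], data.frame(
        start = bounds[-length(bounds)] + c(0, rep(1, n_seg - 1)),
        end = bounds[-1], tn_ratio = lev))
      busy_chroms <- union(busy_chroms, ch)
      truth$ct <- list(present = TRUE, chrom = ch, span_start = span_start,
                       span_end = span_start + cfg$ct_span,
                       n_switches = cfg$ct_switches)
    } else truth$ct <- list(present = FALSE)

    planted_arms <- data.frame(chrom = character(), arm = character(),
                               direction = character())
    if (s710[i]) {
      for (ch in c("7", "10")) {
        ratio <- if (ch == "7") 2^cfg$arm_log2_shift else 2^-cfg$arm_log2_shift
        keep <- clip_interval(1, genome$chrom_lengths[[ch]], spec[[ch]])
        if (nrow(keep) > 0)
          spec[[ch]] <- rbind(spec[[ch]],
                              cbind(keep, data.frame(tn_ratio = ratio)))
        dirn <- if (ch == "7") "gain" else "loss"
        planted_arms <- rbind(planted_arms,
                              data.frame(chrom = ch, arm = c("p", "q"),
                                         direction = dirn))
      }
      busy_chroms <- union(busy_chroms, c("7", "10"))
    }
    p_arm <- min(0.5, cfg$arm_event_prob * g_mult[i])
    for (j in seq_len(nrow(arms))) {
      a <- arms[j, ]
      if (a$chrom %in% busy_chroms) next
      if (stats::runif(1) >= p_arm) next
      dirn <- sample(c("gain", "loss"), 1)
      ratio <- 2^(if (dirn == "gain") cfg$arm_log2_shift else
        -cfg$arm_log2_shift)
      spec[[a$chrom]] <- rbind(spec[[a$chrom]],
                               data.frame(start = a$start, end = a$end,
                                          tn_ratio = ratio))
      planted_arms <- rbind(planted_arms,
                            data.frame(chrom = a$chrom, arm = a$arm,
                                       direction = dirn))
    }
    truth$arm_events <- planted_arms

    seg_sample <- list()
    altered_frac <- stats::setNames(numeric(length(genome$chrom_names)),
                                    genome$chrom_names)
    for (ch in genome$chrom_names) {
      sp <- spec[[ch]]
      neutral <- fill_neutral(sp, genome$chrom_lengths[[ch]],
                              cfg$segment_noise_sd)
      all_seg <- rbind(sp, neutral)
      all_seg <- all_seg[order(all_seg$start), , drop = FALSE]
      seg_sample[[ch]] <- data.frame(sample = id, chrom = ch,
                                     start = all_seg$start, end = all_seg$end,
                                     tn_ratio = all_seg$tn_ratio)
      alt <- sp[abs(log2(sp$tn_ratio)) > 0.25, , drop = FALSE]
      ci <- cap_by_chrom[[ch]]
      altered_frac[[ch]] <- if (is.null(ci) || cap_bp[[ch]] == 0) 0 else
        overlap_bp(ci$start, ci$end, alt$start, alt$end) / cap_bp[[ch]]
    }
    segments[[i]] <- do.call(rbind, seg_sample)
    truth$altered_fraction <- as.list(altered_frac)
    truth$true_wgii <- mean(altered_frac)

    # ---- variants ----
    n_snv <- stats::rpois(1, cfg$snv_rate * m_mult[i] * mb)
    n_indel <- stats::rpois(1, cfg$indel_rate * m_mult[i] * mb)
    n_pass <- n_snv + n_indel
    f <- cfg$subthreshold_fraction
    n_sub <- if (f > 0) round(n_pass * f / (1 - f)) else 0
    n_tot <- n_pass + n_sub
    v <- if (n_tot > 0) {
      tile <- cap[sample.int(nrow(cap), n_tot, replace = TRUE), ]
      pos <- tile$start + floor(stats::runif(n_tot) *
                                  (tile$end - tile$start + 1))
      is_snv <- c(rep(TRUE, n_snv), rep(FALSE, n_indel),
                  stats::runif(n_sub) < 0.85)
      ref <- ifelse(is_snv, sample(c("A", "C", "G", "T"), n_tot,
                                   replace = TRUE), "A")
      alt <- character(n_tot)
      for (k in which(is_snv))
        alt[k] <- sample(setdiff(c("A", "C", "G", "T"), ref[k]), 1)
      ins <- !is_snv & stats::runif(n_tot) < 0.5
      alt[!is_snv & ins] <- "AT"
      ref[!is_snv & !ins] <- "AT"; alt[!is_snv & !ins] <- "A"
      vclass <- ifelse(is_snv,
                       sample(c("Missense_Mutation", "Silent",
                                "Nonsense_Mutation", "Splice_Site", "3'UTR"),
                              n_tot, replace = TRUE,
                              prob = c(0.55, 0.25, 0.07, 0.06, 0.07)),
                       ifelse(ins, "Frame_Shift_Ins", "Frame_Shift_Del"))
      vaf <- stats::rbeta(n_tot, cfg$vaf_shape[1], cfg$vaf_shape[2])
      vaf <- pmax(vaf, 0.051)                 # passing variants clear the cut
      t_depth <- pmax(21, stats::rpois(n_tot, cfg$depth_means[["tumor"]]))
      n_depth <- pmax(11, stats::rpois(n_tot, cfg$depth_means[["normal"]]))
      if (n_sub > 0) {                        # fodder fails >= 1 filter
        idx <- n_pass + seq_len(n_sub)
        mode <- sample(3, n_sub, replace = TRUE)
        vaf[idx][mode == 1] <- stats::runif(sum(mode == 1), 0.005, 0.05)
        t_depth[idx][mode == 2] <- sample(20, sum(mode == 2), replace = TRUE)
        n_depth[idx][mode == 3] <- sample(10, sum(mode == 3), replace = TRUE)
      }
      data.frame(sample = id, chrom = tile$chrom, pos = pos, ref = ref,
                 alt = alt, variant_class = vclass, vaf = round(vaf, 4),
                 t_depth = t_depth, n_depth = n_depth,
                 gene = paste0("G", tile$chrom, "_",
                               1 + (pos - 1) %/% 1e5))
    } else {
      data.frame(sample = character(), chrom = character(), pos = numeric(),
                 ref = character(), alt = character(),
                 variant_class = character(), vaf = numeric(),
                 t_depth = integer(), n_depth = integer(), gene = character())
    }
    variants[[i]] <- v
    truth$n_snv_pass <- n_snv
    truth$n_indel_pass <- n_indel
    truth$snv_burden <- n_snv / mb
    truth$indel_burden <- n_indel / mb
    truth$snv_rate_config <- cfg$snv_rate * m_mult[i]

    # background SVs
    if (cfg$n_background_sv > 0) {
      ch1 <- sample(genome$chrom_names, cfg$n_background_sv, replace = TRUE)
      ch2 <- sample(genome$chrom_names, cfg$n_background_sv, replace = TRUE)
      svs[[length(svs) + 1]] <- data.frame(
        sample = id, chrom1 = ch1,
        pos1 = floor(stats::runif(cfg$n_background_sv, 1,
                                  genome$chrom_lengths[ch1])),
        chrom2 = ch2,
        pos2 = floor(stats::runif(cfg$n_background_sv, 1,
                                  genome$chrom_lengths[ch2])),
        sv_type = "TRA")
    }

    catalogs[, id] <- simulate_catalog(expo[id, ], cfg$signature_matrix,
                                       cfg$n_catalog_mutations)
    truth$exposures <- as.list(expo[id, ])
    truth$subset <- subset[i]
    manifest$samples[[id]] <- truth
  }

  variants <- do.call(rbind, variants)
  segments <- do.call(rbind, segments)
  sv <- if (length(svs) > 0) do.call(rbind, svs) else
    data.frame(sample = character(), chrom1 = character(), pos1 = numeric(),
               chrom2 = character(), pos2 = numeric(), sv_type = character())
  rownames(variants) <- rownames(segments) <- rownames(sv) <- NULL
  variants$variant_type <- if (nrow(variants) > 0)
    variant_type_of(variants$ref, variants$alt) else character(0)
  segments$log2_ratio <- log2(segments$tn_ratio)

  out <- list(variants = variants, segments = segments, sv = sv,
              sheet = sheet, catalogs = catalogs,
              signature_matrix = cfg$signature_matrix, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_variants(variants, file.path(dir, "variants.tsv"))
    write_segments(segments, file.path(dir, "segments.tsv"))
    write_sv(sv, file.path(dir, "sv.tsv"))
    write_tsv_plain(sheet, file.path(dir, "sample_sheet.tsv"))
    write_catalogs(catalogs, file.path(dir, "catalogs.tsv"))
    write_signature_matrix(cfg$signature_matrix,
                           file.path(dir, "signatures.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
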