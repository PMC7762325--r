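test_that("zero mutation rates give empty variant tables and zero burdens", {
  sim <- simulate_cohort(cohort_config(seed = 1, n_samples = 3, snv_rate = 0,
                                       indel_rate = 0,
                                       subthreshold_fraction = 0))
  expect_equal(nrow(sim$variants), 0)
  for (s in sim$manifest$samples) expect_equal(s$snv_burden, 0)
})

test_that("a 7+/10- sample has manifest altered fraction 1 on chromosome 7", {
  sim <- simulate_cohort(cohort_config(seed = 2, n_samples = 8,
                                       mgbm_fraction = 1,
                                       arm_event_prob = 0,
                                       n_ct_samples = 0, n_dm_samples = 0))
  with_710 <- sim$sheet$analysis_id[sim$sheet$seven_plus_ten_minus]
  expect_gt(length(with_710), 0)
  for (id in with_710) {
    tr <- sim$manifest$samples[[id]]
    expect_equal(tr$altered_fraction[["7"]], 1.0)
    expect_equal(tr$altered_fraction[["10"]], 1.0)
  }
})

test_that("identical seeds reproduce the cohort byte-for-byte", {
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  cfg <- cohort_config(seed = 17, n_samples = 6)
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 0)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  # and a different seed changes the output
  d3 <- tempfile("run3")
  simulate_cohort(cohort_config(seed = 18, n_samples = 6), dir = d3)
  expect_false(identical(readBin(file.path(d1, "variants.tsv"), "raw", 1e7),
                         readBin(file.path(d3, "variants.tsv"), "raw", 1e7)))
})

test_that("written files re-parse to the in-memory tables (manifest consistency)", {
  d <- tempfile("coh")
  sim <- simulate_cohort(cohort_config(seed = 3, n_samples = 5), dir = d)
  v <- read_variants(file.path(d, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants))
  seg <- read_segments(file.path(d, "segments.tsv"))
  expect_equal(seg$tn_ratio, sim$segments$tn_ratio)
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.tsv"))
  expect_equal(sheet$analysis_id, sim$sheet$analysis_id)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(length(man$samples), 5)
  # manifest burden equals the filtered recount from the written file
  g <- toy_genome()
  b <- compute_burdens(filter_somatic(v), g)
  for (id in names(man$samples))
    expect_equal(b$snv_burden[b$sample == id],
                 man$samples[[id]]$snv_burden)
})

test_that("segments tile each chromosome without overlap", {
  sim <- simulate_cohort(cohort_config(seed = 4, n_samples = 4))
  g <- toy_genome()
  seg <- sim$segments
  for (id in unique(seg$sample)) {
    for (ch in unique(seg$chrom[seg$sample == id])) {
      s <- seg[seg$sample == id & seg$chrom == ch, ]
      s <- s[order(s$start), ]
      expect_true(all(s$start[-1] > s$end[-nrow(s)]), info = paste(id, ch))
      expect_lte(max(s$end), g$chrom_lengths[[ch]])
    }
  }
})

test_that("planted burden rates are recovered within Poisson error", {
  mb <- capture_size_mb(toy_genome())
  lambda <- 3
  sim <- simulate_cohort(cohort_config(seed = 6, n_samples = 30,
                                       snv_rate = lambda,
                                       mutation_dispersion = 0))
  m <- compute_burdens(filter_somatic(sim$variants), toy_genome())
  se <- sqrt(lambda / mb) / sqrt(nrow(m))
  expect_lt(abs(mean(m$snv_burden) - lambda), 3 * se)
  # per-sample: measured burden equals the manifest count exactly
  for (id in m$sample)
    expect_equal(m$snv_burden[m$sample == id],
                 sim$manifest$samples[[id]]$snv_burden)
})

test_that("sub-threshold fodder is planted and removed by the filter", {
  sim <- simulate_cohort(cohort_config(seed = 7, n_samples = 6,
                                       subthreshold_fraction = 0.2))
  v <- sim$variants
  kept <- filter_somatic(v)
  frac_removed <- 1 - nrow(kept) / nrow(v)
  expect_gt(frac_removed, 0.1)
  expect_lt(frac_removed, 0.3)
  truth <- sum(sapply(sim$manifest$samples, function(s)
    s$n_snv_pass + s$n_indel_pass))
  expect_equal(nrow(kept), truth)
})

test_that("an unknown double-minute oncogene is a configuration error", {
  expect_error(simulate_cohort(cohort_config(seed = 8, n_samples = 2,
                                             dm_oncogene = "NOSUCH")),
               "config")
})

test_that("a pure-signature simulated catalog matches its multinomial mean", {
  S <- synthetic_signature_matrix(2, seed = 20)
  cat1 <- simulate_catalog(c(1, 0), S, 50000, seed = 21)
  expect_equal(sum(cat1), 50000)
  expect_lt(max(abs(cat1 / 50000 - S[, 1])), 0.01)
})
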