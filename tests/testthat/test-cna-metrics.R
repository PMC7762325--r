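test_that("one fully altered chromosome gives wGII 1/22", {
  g <- toy_genome()
  seg <- rbind(make_segments("S1", "3", 1, 1e7, 1.5),
               flat_segments(g)[flat_segments(g)$chrom != "3", ])
  w <- wgii(seg, g)
  expect_equal(unname(w$per_chrom["3"]), 1.0)
  expect_equal(w$wgii, 1 / 22)
})

test_that("log2 ratio exactly at the threshold does not count as altered", {
  g <- mini_genome()
  seg <- make_segments("S1", "1", 1, 1e6, 2^0.25)
  expect_equal(wgii(seg, g)$wgii, 0)
  expect_gt(wgii(make_segments("S1", "1", 1, 1e6, 2^0.2501), g)$wgii, 0)
})

test_that("wGII equals base-level classification on random segmentations", {
  g <- mini_genome()
  set.seed(21)
  for (rep in 1:3) {
    seg <- do.call(rbind, lapply(g$chrom_names, function(ch) {
      cuts <- sort(sample.int(1e6 - 1, 8))
      bounds <- c(0, cuts, 1e6)
      make_segments("S1", ch, bounds[-length(bounds)] + 1, bounds[-1],
                    round(runif(length(bounds) - 1, 0.3, 2.5), 3))
    }))
    w <- wgii(seg, g)
    # oracle: classify every captured base
    per_chrom_oracle <- sapply(g$chrom_names, function(ch) {
      cap <- logical(1e6); alt <- logical(1e6)
      ci <- g$capture[g$capture$chrom == ch, ]
      for (i in seq_len(nrow(ci))) cap[ci$start[i]:ci$end[i]] <- TRUE
      si <- seg[seg$chrom == ch & abs(seg$log2_ratio) > 0.25, ]
      for (i in seq_len(nrow(si))) alt[si$start[i]:si$end[i]] <- TRUE
      sum(cap & alt) / sum(cap)
    })
    expect_equal(unname(w$per_chrom), unname(per_chrom_oracle))
    expect_equal(w$wgii, mean(per_chrom_oracle))
  }
})

test_that("a single whole-arm gain gives CAER 1/44", {
  g <- toy_genome()
  seg <- make_segments("S1", "5", 1, 4e6, 1.5)    # p arm only
  ca <- caer(seg, g)
  expect_equal(ca$n_events, 1)
  expect_equal(ca$caer, 1 / 44)
  expect_equal(ca$arm_calls$call[ca$arm_calls$chrom == "5" &
                                   ca$arm_calls$arm == "p"], "gain")
})

test_that("arm means are weighted in linear space then log-transformed", {
  g <- mini_genome()                      # p arm is [1, 4e5]
  seg <- rbind(make_segments("S1", "1", 1, 2e5, 2.0),
               make_segments("S1", "1", 2e5 + 1, 4e5, 0.5))
  ca <- caer(seg, g)
  wm <- ca$arm_calls$weighted_mean_log2[ca$arm_calls$chrom == "1" &
                                          ca$arm_calls$arm == "p"]
  expect_equal(wm, log2(1.25))            # mean of ratios, not of log2s
  expect_equal(ca$arm_calls$call[ca$arm_calls$chrom == "1" &
                                   ca$arm_calls$arm == "p"], "gain")
})

test_that("a neutral genome has CAER 0 and uncovered arms count as neutral", {
  g <- toy_genome()
  expect_equal(caer(flat_segments(g), g)$caer, 0)
  # segments on one chromosome only: the other 42 arms neutral-fill
  seg <- make_segments("S1", "1", 1, 1e7, 1.5)
  expect_equal(caer(seg, g)$n_events, 2)
})

test_that("acrocentric p arms can be dropped from the inventory", {
  g <- toy_genome()
  ca <- caer(make_segments("S1", "1", 1, 4e6, 1.5), g,
             drop_acrocentric_p = TRUE)
  expect_equal(ca$n_arms, 39)
  expect_equal(ca$caer, 1 / 39)
})

test_that("metrics are invariant under segment splitting", {
  g <- mini_genome()
  seg <- rbind(make_segments("S1", "1", 1, 6e5, 1.8),
               make_segments("S1", "2", 1, 3e5, 0.4))
  split_seg <- rbind(
    make_segments("S1", "1", 1, 2.5e5, 1.8),
    make_segments("S1", "1", 2.5e5 + 1, 6e5, 1.8),
    make_segments("S1", "2", 1, 1e5, 0.4),
    make_segments("S1", "2", 1e5 + 1, 3e5, 0.4))
  expect_equal(wgii(split_seg, g)$wgii, wgii(seg, g)$wgii)
  expect_equal(caer(split_seg, g)$caer, caer(seg, g)$caer)
  expect_equal(cn_amplitude(split_seg), cn_amplitude(seg))
})

test_that("wGII is monotone as non-overlapping altered segments accumulate", {
  g <- mini_genome()
  set.seed(9)
  starts <- seq(1, 9e5, by = 1e5)
  prev <- 0
  for (k in 1:6) {
    seg <- make_segments("S1", "1", starts[1:k], starts[1:k] + 5e4, 2.0)
    cur <- wgii(seg, g)$wgii
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("copy-number amplitude rounds 2 x ratio half-up with diploid floor", {
  expect_equal(cn_amplitude(make_segments("S1", "1", 1, 100, 7.5)), 15L)
  expect_equal(cn_amplitude(make_segments("S1", "1", 1, 100, 1.0)), 2L)
  expect_equal(cn_amplitude(make_segments("S1", "1", 1, 100, 1.0)[0, ]), 2L)
  set.seed(13)
  r <- runif(200, 0.2, 20)
  seg <- make_segments("S1", "1", seq_along(r) * 10,
                       seq_along(r) * 10 + 5, r)
  expect_equal(cn_amplitude(seg), as.integer(max(floor(2 * r + 0.5))))
})
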