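onc <- toy_oncogenes()

test_that("high-level seeds merge within the gap and sub-cutoff ratios never seed", {
  seg <- rbind(make_segments("S1", "7", 1e6, 1.5e6, 6),
               make_segments("S1", "7", 2.0e6, 2.4e6, 6))   # 0.5 Mb apart
  amp <- build_amplicons(seg, onc)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 1e6)
  expect_equal(amp$end, 2.4e6)
  expect_equal(amp$n_segments, 2L)
  expect_match(amp$oncogenes, "EGFR")
  expect_equal(nrow(build_amplicons(make_segments("S1", "7", 1e6, 2e6, 4.9),
                                    onc)), 0)
})

test_that("amplicon construction equals a brute-force interval merge", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30
    seg <- make_segments("S1", sample(c("7", "12"), n, replace = TRUE),
                         start = sample.int(9e6, n), end = 0,
                         tn_ratio = runif(n, 1, 10))
    seg$end <- seg$start + sample.int(5e5, n)
    seg$log2_ratio <- log2(seg$tn_ratio)
    amp <- build_amplicons(seg, onc, merge_gap = 3e5)
    # oracle: greedy merge of sorted high-level seeds
    seeds <- seg[seg$tn_ratio >= 5, ]
    expected <- list()
    for (ch in sort(unique(seeds$chrom))) {
      s <- seeds[seeds$chrom == ch, ]
      s <- s[order(s$start), ]
      cur <- s[1, c("start", "end")]
      for (i in seq_len(nrow(s))[-1]) {
        if (s$start[i] - cur$end - 1 <= 3e5) {
          cur$end <- max(cur$end, s$end[i])
        } else {
          expected[[length(expected) + 1]] <- cbind(chrom = ch, cur)
          cur <- s[i, c("start", "end")]
        }
      }
      expected[[length(expected) + 1]] <- cbind(chrom = ch, cur)
    }
    expected <- do.call(rbind, expected)
    expected <- expected[order(expected$chrom, expected$start), ]
    got <- amp[order(amp$chrom, amp$start), c("chrom", "start", "end")]
    expect_equal(got, expected, ignore_attr = TRUE)
  }
})

test_that("double-minute rule (a) fires on two amplicons with an oncogene", {
  seg <- rbind(make_segments("S1", "7", 2.0e6, 2.3e6, 8),    # over EGFR
               make_segments("S1", "3", 5e6, 5.4e6, 6))
  dm <- call_dm(build_amplicons(seg, onc))
  expect_true(dm$is_dm)
  expect_equal(dm$rule, "a")
  expect_true("EGFR" %in% dm$oncogenes)
})

test_that("double-minute rule (b) needs oncogene, >1 Mb and an SV", {
  seg <- make_segments("S1", "12", 5.5e6, 7.6e6, 9)          # 2.1 Mb, MDM2
  sv <- data.frame(sample = "S1", chrom1 = "12", pos1 = 6e6,
                   chrom2 = "12", pos2 = 7e6, sv_type = "DUP")
  dm <- call_dm(build_amplicons(seg, onc, sv))
  expect_true(dm$is_dm)
  expect_equal(dm$rule, "b")
  # same single amplicon but short: 0.8 Mb fails the length condition
  seg2 <- make_segments("S1", "12", 5.9e6, 6.7e6 - 1, 9)
  sv2 <- data.frame(sample = "S1", chrom1 = "12", pos1 = 6e6,
                    chrom2 = "12", pos2 = 6.5e6, sv_type = "DUP")
  expect_false(call_dm(build_amplicons(seg2, onc, sv2))$is_dm)
  # and without the SV the 2.1 Mb amplicon fails too
  expect_false(call_dm(build_amplicons(seg, onc))$is_dm)
})

test_that("DM calls are invariant to segment order and splitting", {
  seg <- rbind(make_segments("S1", "7", 2.0e6, 2.3e6, 8),
               make_segments("S1", "3", 5e6, 5.4e6, 6))
  base <- call_dm(build_amplicons(seg, onc))
  shuffled <- call_dm(build_amplicons(seg[2:1, ], onc))
  expect_equal(shuffled$rule, base$rule)
  split_seg <- rbind(make_segments("S1", "7", 2.0e6, 2.15e6, 8),
                     make_segments("S1", "7", 2.15e6 + 1, 2.3e6, 8),
                     make_segments("S1", "3", 5e6, 5.4e6, 6))
  resplit <- call_dm(build_amplicons(split_seg, onc))
  expect_equal(resplit$rule, base$rule)
  expect_equal(nrow(resplit$amplicons), nrow(base$amplicons))
})

ct_cluster <- function(genome, chrom = "5", span_start = 2e6, span = 5e6,
                       n_switches = 30, levels = c(1.0, 0.5),
                       sample = "S1") {
  n_seg <- n_switches + 1
  bounds <- round(seq(span_start, span_start + span, length.out = n_seg + 1))
  osc <- make_segments(sample, chrom,
                       bounds[-length(bounds)] + c(0, rep(1, n_seg - 1)),
                       bounds[-1], rep(levels, length.out = n_seg))
  rest <- flat_segments(genome, sample)
  rest <- rest[rest$chrom != chrom, ]
  flank <- rbind(
    if (span_start > 1)
      make_segments(sample, chrom, 1, span_start - 1, 1.0),
    if (span_start + span < genome$chrom_lengths[[chrom]])
      make_segments(sample, chrom, span_start + span + 1,
                    genome$chrom_lengths[[chrom]], 1.0))
  rbind(osc, flank, rest)
}

test_that("an oscillating cluster yields exactly one call on its chromosome", {
  g <- toy_genome()
  seg <- ct_cluster(g)
  calls <- call_chromothripsis(seg, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "5")
  expect_gte(calls$n_switches, 30)
  expect_gte(calls$log10_lr, 8)
  # the call window brackets the planted cluster
  expect_lte(calls$window_start, 2e6 + 2e5)
  expect_gte(calls$window_end, 7e6 - 2e5)
})

test_that("flat genomes and isolated gains produce no chromothripsis call", {
  g <- toy_genome()
  expect_equal(nrow(call_chromothripsis(flat_segments(g), g)), 0)
  seg <- rbind(make_segments("S1", "4", 3e6, 4e6, 2.0),
               flat_segments(g))
  expect_equal(nrow(call_chromothripsis(seg, g)), 0)   # 2 switches < 10
})

test_that("chromothripsis calls shift with the planted cluster", {
  g <- toy_genome()
  c1 <- call_chromothripsis(ct_cluster(g, span_start = 2e6), g)
  c2 <- call_chromothripsis(ct_cluster(g, span_start = 3e6), g)
  expect_equal(c2$window_start - c1$window_start, 1e6)
  expect_equal(c2$n_switches, c1$n_switches)
})

test_that("window counts match an oracle scan over switch points", {
  g <- toy_genome()
  seg <- ct_cluster(g, n_switches = 12, span = 3e6)
  calls <- call_chromothripsis(seg, g, window_mb = 5, min_switches = 10,
                               lr_threshold = 5)
  # oracle: recompute switch count inside the merged call window
  s5 <- seg[seg$chrom == "5", ]
  s5 <- s5[order(s5$start), ]
  state <- ifelse(s5$log2_ratio > 0.25, 1, ifelse(s5$log2_ratio < -0.25,
                                                  -1, 0))
  switch_pos <- s5$start[-1][state[-1] != state[-length(state)]]
  expect_equal(calls$n_switches,
               sum(switch_pos >= calls$window_start &
                     switch_pos <= calls$window_end))
})
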