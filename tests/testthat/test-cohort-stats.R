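test_that("group summaries report median and range", {
  m <- data.frame(sample = c("a", "b", "c", "d"),
                  snv_burden = c(1, 2, 3, 7), grp = c("x", "x", "x", "y"))
  s <- summarize_metrics(m, metric_names = "snv_burden", group_by = "grp")
  sx <- s[s$group == "x", ]
  expect_equal(c(sx$median, sx$min, sx$max), c(2, 1, 3))
  sy <- s[s$group == "y", ]
  expect_equal(c(sy$median, sy$min, sy$max), c(7, 7, 7))
  set.seed(51)
  v <- rlnorm(37)
  s2 <- summarize_metrics(data.frame(sample = seq_along(v), snv_burden = v),
                          metric_names = "snv_burden")
  expect_equal(s2$median, sort(v)[19])   # brute-force sort-based median
})

test_that("rank-sum: identical groups give p = 1 and a known shift its exact p", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  t <- rank_sum_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(t$method, "exact")
  expect_equal(t$p_value, 2 / 70)        # 2 extreme assignments of C(8,4)
})

test_that("exact enumeration agrees with wilcox.test on tie-free small groups", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- sample(seq_len(50), n); y <- sample(seq_len(50) + 100, m)
    y <- sample(c(y, x + 0.5))[seq_len(m)]   # interleave, still tie-free
    p_mine <- rank_sum_test(x, y)$p_value
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_mine, p_ref, tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are invariant to sample order and lie in (0, 1]", {
  set.seed(62)
  x <- rnorm(15); y <- rnorm(18)
  p1 <- rank_sum_test(x, y)$p_value
  p2 <- rank_sum_test(sample(x), sample(y))$p_value
  expect_equal(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("compare_groups labels the two groups and their medians", {
  m <- data.frame(sample = letters[1:6], wgii = c(0.1, 0.2, 0.3, 0.6, 0.7,
                                                  0.8),
                  subset = rep(c("Others", "mGBM"), each = 3))
  cg <- compare_groups(m, "wgii", "subset")
  expect_equal(cg$medians[["mGBM"]], 0.7)
  expect_equal(cg$medians[["Others"]], 0.2)
  expect_equal(cg$p_value, 2 / choose(6, 3))
})

test_that("prevalence chi-squared matches the textbook formula", {
  expect_equal(compare_prevalence(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  expect_lt(compare_prevalence(matrix(c(20, 0, 0, 20), 2))$p_value, 1e-8)
  set.seed(71)
  for (rep in 1:20) {
    tab <- matrix(sample(5:40, 4, replace = TRUE), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    # plain statistic
    p_plain <- stats::pchisq(sum((tab - e)^2 / e), df = 1,
                             lower.tail = FALSE)
    expect_equal(compare_prevalence(tab, correct = FALSE)$p_value, p_plain,
                 tolerance = 1e-12)
    # Yates-corrected statistic
    adj <- pmin(0.5, abs(tab - e))
    p_yates <- stats::pchisq(sum((abs(tab - e) - adj)^2 / e), df = 1,
                             lower.tail = FALSE)
    expect_equal(compare_prevalence(tab, correct = TRUE)$p_value, p_yates,
                 tolerance = 1e-12)
  }
  expect_error(compare_prevalence(matrix(c(0, 0, 5, 5), 2)), "zero-margin")
})

test_that("correlogram: duplicated metrics correlate perfectly and cluster together", {
  set.seed(81)
  x <- rnorm(30)
  m <- data.frame(a = x, b = x, c = rnorm(30))
  cg <- metric_correlogram(m, metric_names = c("a", "b", "c"))
  expect_equal(cg$cor["a", "b"], 1)
  expect_equal(cg$clusters[["a"]], cg$clusters[["b"]])
})

test_that("constant metrics yield a warning and zeroed correlations", {
  m <- data.frame(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_warning(cg <- metric_correlogram(m, metric_names = c("a", "b", "c")),
                 "constant")
  expect_equal(cg$cor["a", "b"], 0)
})

test_that("age correlation recovers exact and planted relationships", {
  m <- data.frame(sample = 1:10, age = 1:10, up = 1:10, down = 10:1)
  expect_equal(age_correlation(m, "up")$r, 1)
  expect_equal(age_correlation(m, "down")$r, -1)
  set.seed(91)
  n <- 500; rho <- 0.3
  age <- rnorm(n)
  y <- rho * age + sqrt(1 - rho^2) * rnorm(n)
  est <- age_correlation(data.frame(sample = 1:n, age = age, m = y), "m")
  expect_lt(abs(est$r - rho), 0.1)
  expect_error(age_correlation(data.frame(sample = 1:5, age = rep(1, 5),
                                          m = rnorm(5)), "m"), "variance")
})

test_that("gene association skips degenerate genes and ranks a planted effect first", {
  set.seed(101)
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  metric <- rnorm(n)
  hi <- lapply(ids, function(i) character(0))
  names(hi) <- ids
  # DRIVER mutated in 12 samples whose metric is shifted by +5 SD
  mut <- sample(ids, 12)
  for (s in mut) hi[[s]] <- "DRIVER"
  metric[ids %in% mut] <- metric[ids %in% mut] + 5
  # EVERYWHERE mutated in all samples: must be skipped
  for (s in ids) hi[[s]] <- c(hi[[s]], "EVERYWHERE")
  # background genes
  for (g in sprintf("BG%02d", 1:10)) {
    for (s in sample(ids, 6)) hi[[s]] <- c(hi[[s]], g)
  }
  tab <- gene_metric_association(hi, data.frame(sample = ids,
                                                m = metric), "m")
  expect_false("EVERYWHERE" %in% tab$gene)
  expect_equal(tab$gene[1], "DRIVER")
  expect_equal(tab$direction[1], 1)
  expect_true(tab$significant[1])
  expect_equal(tab$n_mut[tab$gene == "DRIVER"], 12)
})
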