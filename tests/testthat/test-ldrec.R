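test_that("Watterson's theta matches harmonic-number arithmetic", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(5, 2, 100), 0.05)   # H_1 = 1
  expect_equal(watterson_theta(100, 10, 10000), 3.5349e-3, tolerance = 1e-4)
  expect_equal(watterson_theta(100, 10, 10000), 100 / (sum(1 / (1:9)) * 1e4))
})

test_that("rho to r conversion and its round trip use the stated constants", {
  expect_equal(rho_to_r(0, 1e-8, 1e-4)$r, 0)
  # r = 1e-8 per bp per generation is 1 cM/Mb by definition
  ne <- 11695
  theta <- 4 * ne * 0.4e-8
  expect_equal(rho_to_r(4 * ne * 1e-8, 0.4e-8, theta)$cM_Mb, 1)
  # N_e = 11,695 and r = 0.85e-8: rho = 3.9763e-4, inverting gives 0.85 cM/Mb
  rho <- 4 * ne * 0.85e-8
  expect_equal(rho, 3.9763e-4, tolerance = 1e-5)
  out <- rho_to_r(rho, 0.4e-8, theta)
  expect_equal(out$cM_Mb, 0.85, tolerance = 1e-12)
  expect_equal(out$N_e, ne)
  expect_error(rho_to_r(1e-4, 0, 1e-4), "positive")
})

test_that("outlier windows beyond the fold threshold are removed", {
  m <- recomb_map("s1", seq(0, 1000e3, by = 1e3)[1:1001],
                  seq(1e3, 1001e3, by = 1e3)[1:1001],
                  c(rep(1, 1000), 200))
  res <- filter_outlier_windows(m, fold = 100)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$rate, 200)
  expect_equal(res$genome_mean, (1000 + 200) / 1001)
  # uniform map: nothing removed; infinite fold: identity
  u <- recomb_map("s1", c(0, 1e3), c(1e3, 2e3), c(1, 1))
  expect_equal(nrow(filter_outlier_windows(u, 100)$removed), 0)
  expect_equal(nrow(filter_outlier_windows(m, Inf)$removed), 0)
})

test_that("rescaling conserves the target length and relative rates", {
  set.seed(31)
  n <- 200
  m <- recomb_map("s1", seq(0, by = 1e4, length.out = n),
                  seq(1e4, by = 1e4, length.out = n),
                  stats::runif(n, 0.1, 3))
  res <- rescale_map(m, 1525)
  expect_equal(total_map_cM(res$map), 1525, tolerance = 1e-6)
  ratio_before <- m$rate[-1] / m$rate[1]
  ratio_after <- res$map$rate[-1] / res$map$rate[1]
  expect_equal(ratio_after, ratio_before, tolerance = 1e-12)
  # the published factor 14.444 with target 1525 implies a 105.58 cM input
  implied <- 1525 / 14.444
  expect_equal(implied, 105.58, tolerance = 1e-2)
  m2 <- rescale_map(m, implied)$map
  expect_equal(rescale_map(m2, 1525)$factor, 14.444, tolerance = 1e-3)
  # trivial factor
  m3 <- recomb_map("s1", 0, 1e6, 152.5)
  expect_equal(rescale_map(m3, 1525)$factor, 10)
  expect_error(rescale_map(recomb_map("s1", 0, 1e6, 0), 10), "zero total")
})

test_that("cumulative map length is non-decreasing and ends at the total", {
  set.seed(32)
  m <- recomb_map(rep(c("s1", "s2"), each = 50),
                  rep(seq(0, by = 2e4, length.out = 50), 2),
                  rep(seq(2e4, by = 2e4, length.out = 50), 2),
                  stats::runif(100, 0, 2))
  for (s in c("s1", "s2")) {
    cc <- m$cum_cM[m$scaffold == s]
    expect_true(all(diff(cc) >= 0))
    sub <- m[m$scaffold == s, ]
    expect_equal(cc[length(cc)], sum(sub$rate * (sub$end - sub$start) / 1e6))
  }
})

test_that("window aggregation equals a brute-force weighted mean", {
  # uniform fine map stays unchanged; window counting matches arithmetic
  u <- recomb_map("s1", seq(0, by = 1e5, length.out = 100),
                  seq(1e5, by = 1e5, length.out = 100), rep(0.7, 100))
  agg <- aggregate_windows(u, 1e6, 5e5)
  expect_equal(nrow(agg), 19)
  expect_equal(agg$rate, rep(0.7, 19))
  # random fine map vs per-bp oracle
  set.seed(33)
  fine <- recomb_map("s1", seq(0, by = 2.5e4, length.out = 80),
                     seq(2.5e4, by = 2.5e4, length.out = 80),
                     stats::runif(80, 0, 3))
  agg2 <- aggregate_windows(fine, 5e5, 2.5e5)
  bp_rate <- rep(fine$rate, each = 2.5e4)
  for (k in seq_len(nrow(agg2))) {
    expect_equal(agg2$rate[k],
                 mean(bp_rate[(agg2$start[k] + 1):agg2$end[k]]))
  }
})

test_that("Welch t-test matches the textbook formula and detects enrichment", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  m <- recomb_map("s1", seq(0, by = 1e3, length.out = 6),
                  seq(1e3, by = 1e3, length.out = 6), c(x, y))
  motifs <- data.frame(scaffold = "s1", pos = c(500, 1500, 2500))
  res <- compare_motif_rates(m, motifs)
  se2 <- stats::var(x) / 3 + stats::var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((stats::var(x) / 3)^2 / 2 + (stats::var(y) / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df_hand))
  # identical groups: t = 0
  m2 <- recomb_map("s1", seq(0, by = 1e3, length.out = 6),
                   seq(1e3, by = 1e3, length.out = 6), rep(c(1, 2, 3), 2))
  expect_equal(compare_motif_rates(m2, motifs)$t, 0)
  expect_error(compare_motif_rates(m2, data.frame(scaffold = "s1", pos = 1)),
               "at least 2")
})

test_that("strongly enriched synthetic motifs raise the motif-group mean", {
  spec <- toy_spec(2e6, "chr1")
  w <- sliding_windows(spec, 1e5)
  set.seed(34)
  truth <- rate_track(w$scaffold, w$start, w$end,
                      stats::runif(nrow(w), 0.1, 3), units = "cM/Mb")
  mot <- place_motifs(spec, truth, enrichment = 50, n_motifs = 40, seed = 35)
  fine <- recomb_map(truth$scaffold, truth$start, truth$end, truth$rate)
  res <- compare_motif_rates(fine, mot)
  expect_gt(res$mean_motif, res$mean_other)
})

test_that("benchmark report covers the full design grid reproducibly", {
  b <- benchmark_estimator(
    demographies = list(equilibrium = equilibrium_model(3000)),
    mu_values = c(1e-7), replicates = 3, region_length = 2e4,
    table_reps = 800, seed = 36)
  expect_equal(nrow(b$estimates), 3)
  expect_equal(nrow(b$summary), 1)
  expect_true(all(c("mean_cM_Mb", "median_cM_Mb", "bias_cM_Mb",
                    "ratio_to_truth") %in% names(b$summary)))
  b2 <- benchmark_estimator(
    demographies = list(equilibrium = equilibrium_model(3000)),
    mu_values = c(1e-7), replicates = 3, region_length = 2e4,
    table_reps = 800, seed = 36)
  expect_identical(b, b2)
})
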