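test_that("accessibility mask does interval arithmetic correctly", {
  callable <- data.frame(scaffold = "s1", start = 0, end = 1e5)
  ann <- data.frame(scaffold = "s1", start = 20000, end = 21000)
  m <- build_accessibility_mask(ann, callable, flank = 10000)
  expect_equal(m$start, c(0, 31000))
  expect_equal(m$end, c(10000, 100000))
  # no annotations: accessible = callable
  m0 <- build_accessibility_mask(NULL, callable, flank = 10000)
  expect_equal(m0[, c("start", "end")], callable[, c("start", "end")],
               ignore_attr = TRUE)
  # feature beyond bounds is clipped with a warning
  expect_warning(
    build_accessibility_mask(data.frame(scaffold = "s1", start = 95000,
                                        end = 120000),
                             callable, flank = 0, spec = toy_spec(1e5)),
    "clipped")
})

test_that("random masks match a per-site boolean sweep", {
  set.seed(10)
  len <- 20000
  callable <- data.frame(scaffold = "s1",
                         start = c(0, 9000), end = c(8000, 20000))
  st <- sort(sample(0:(len - 200), 50))
  ann <- data.frame(scaffold = "s1", start = st,
                    end = st + sample(20:150, 50, replace = TRUE))
  extra <- data.frame(scaffold = "s1", start = c(500, 15000),
                      end = c(700, 15500))
  flank <- 300
  m <- build_accessibility_mask(ann, callable, flank = flank,
                                extra_masks = list(extra))
  sites <- 0:(len - 1)
  flanked <- data.frame(start = pmax(ann$start - flank, 0), end = ann$end + flank)
  truth <- site_in_intervals(sites, callable) &
    !site_in_intervals(sites, flanked) &
    !site_in_intervals(sites, extra)
  expect_identical(site_in_intervals(sites, m), truth)
})

test_that("windowed divergence counts match a brute-force recount", {
  set.seed(11)
  spec <- toy_spec(10000)
  subs <- data.frame(scaffold = "s1", pos = sort(sample(0:9999, 400)))
  class(subs) <- c("substitution_set", "data.frame")
  snps <- data.frame(scaffold = "s1", pos = sort(sample(0:9999, 300)))
  mask_st <- sort(sample(seq(0, 9000, by = 500), 12))
  mask <- data.frame(scaffold = "s1", start = mask_st, end = mask_st + 400)
  dm <- windowed_divergence(subs, snps, mask, spec, window = 2000, step = 1000,
                            min_access = 0)
  sites <- 0:9999
  acc <- site_in_intervals(sites, mask)
  is_sub <- sites %in% setdiff(subs$pos, snps$pos)
  for (k in seq_len(nrow(dm))) {
    inw <- sites >= dm$start[k] & sites < dm$end[k]
    expect_equal(dm$accessible[k], sum(acc & inw))
    expect_equal(dm$divergent[k], sum(acc & inw & is_sub))
  }
  # forced ratio and exclusion rules
  expect_equal(dm$d[!is.na(dm$d)],
               (dm$divergent / dm$accessible)[!is.na(dm$d)])
})

test_that("substitutions at segregating positions leave the numerator only", {
  spec <- toy_spec(1000)
  mask <- data.frame(scaffold = "s1", start = 0, end = 1000)
  subs <- data.frame(scaffold = "s1", pos = c(10L, 20L, 30L))
  snps <- data.frame(scaffold = "s1", pos = 20L)
  dm <- windowed_divergence(subs, snps, mask, spec, window = 1000)
  expect_equal(dm$divergent, 2)
  expect_equal(dm$accessible, 1000)   # site stays in the denominator
  dm2 <- windowed_divergence(subs, snps, mask, spec, window = 1000,
                             drop_segregating_from_denominator = TRUE)
  expect_equal(dm2$accessible, 999)
  # zero accessible sites: undefined, not zero
  far_mask <- data.frame(scaffold = "s1", start = 0, end = 10)
  dm3 <- windowed_divergence(subs, NULL, far_mask, spec, window = 500,
                             min_access = 0.5)
  expect_true(is.na(dm3$d[1]))
})

test_that("windowed diversity equals mean pairwise difference", {
  # 2 haplotypes differing at 1 of 100 accessible sites: pi = 0.01
  p2 <- toy_panel(rbind(c(1), c(0)), positions = 50, length = 100)
  mask <- data.frame(scaffold = "s1", start = 0, end = 100)
  d <- windowed_diversity(p2, mask, toy_spec(100), window = 100)
  expect_equal(d$pi, 0.01)
  # monomorphic window is 0
  pmono <- toy_panel(matrix(0L, 2, 0), positions = integer(0), length = 100)
  expect_equal(windowed_diversity(pmono, mask, toy_spec(100), 100)$pi, 0)
  # 10 haplotypes vs brute-force mean pairwise difference
  set.seed(12)
  S <- 40
  hap <- matrix(rbinom(10 * S, 1, 0.4), nrow = 10)
  keep <- colSums(hap) > 0 & colSums(hap) < 10
  hap <- hap[, keep, drop = FALSE]
  pos <- sort(sample(0:999, ncol(hap)))
  pan <- toy_panel(hap, pos, length = 1000)
  mask2 <- data.frame(scaffold = "s1", start = 0, end = 1000)
  d10 <- windowed_diversity(pan, mask2, toy_spec(1000), window = 1000)
  pairs <- utils::combn(10, 2)
  mpd <- mean(vapply(seq_len(ncol(pairs)), function(k) {
    sum(hap[pairs[1, k], ] != hap[pairs[2, k], ])
  }, numeric(1))) / 1000
  expect_equal(d10$pi, mpd)
})

test_that("divergence/time conversions reproduce the published cells", {
  # divergence-based rates from d = 0.043
  expect_equal(mutation_rate_from_divergence(0.043, 3, 74.7e6), 1.73e-9,
               tolerance = 0.005)
  expect_equal(mutation_rate_from_divergence(0.043, 5, 54.9e6), 3.93e-9,
               tolerance = 0.005)
  expect_equal(mutation_rate_from_divergence(0, 5, 1e6), 0)
  # pedigree-anchored times
  expect_equal(divergence_time_from_rate(0.043, 5, 4.0e-9) / 1e6, 53.8,
               tolerance = 0.001)
  expect_equal(divergence_time_from_rate(0.043, 3, 2.0e-8) / 1e6, 6.45,
               tolerance = 0.001)
  expect_equal(divergence_time_from_rate(0, 3, 1e-8), 0)
  expect_error(mutation_rate_from_divergence(0.04, 3, 0), "positive")
  expect_error(divergence_time_from_rate(0.04, 3, 0), "positive")
})

test_that("conversion table is complete, rounded and self-inverse", {
  tb <- rate_conversion_table(0.043, c(3, 5), c(54.9, 74.7),
                              c(4e-9, 1.1e-8, 2e-8))
  expect_equal(dim(tb$mu), c(2, 2))
  expect_equal(dim(tb$T_mya), c(2, 3))
  # single-entry lists give 1x1 tables
  tb1 <- rate_conversion_table(0.043, 5, 54.9, 4e-9)
  expect_equal(dim(tb1$mu), c(1, 1))
  # invertibility: T(G, mu(G, T)) = T up to rounding
  for (gi in 1:2) for (ti in 1:2) {
    G <- c(3, 5)[gi]; T0 <- c(54.9, 74.7)[ti]
    back <- divergence_time_from_rate(0.043, G, tb$mu_raw[gi, ti]) / 1e6
    expect_equal(back, T0, tolerance = 1e-9)
  }
})

test_that("genome-wide d is conserved as the weighted mean of window d", {
  spec <- toy_spec(2e5)
  subs <- simulate_substitutions(spec, 3e-9, 1.5e7, seed = 13)
  set.seed(13)
  mask_st <- seq(0, 1.9e5, by = 10000)
  mask <- data.frame(scaffold = "s1", start = mask_st,
                     end = mask_st + sample(4000:9000, length(mask_st), TRUE))
  global <- windowed_divergence(subs, NULL, mask, spec, window = 2e5,
                                min_access = 0)
  for (w in c(1e4, 5e4)) {
    dm <- windowed_divergence(subs, NULL, mask, spec, window = w,
                              min_access = 0)
    pooled <- sum(dm$d * dm$accessible, na.rm = TRUE) /
      sum(dm$accessible[!is.na(dm$d)])
    expect_equal(pooled, global$d, tolerance = 1e-12)
  }
})

test_that("known mutation-rate structure is recovered at the 1 Mb scale", {
  spec <- toy_spec(4e6, "chr1")
  w <- sliding_windows(spec, 1e6)
  truth <- rate_track(w$scaffold, w$start, w$end,
                      c(1.5e-9, 2.5e-9, 3.5e-9, 4.5e-9), units = "mut/bp/gen")
  gens <- 54.9e6 / 5
  subs <- simulate_substitutions(spec, truth, gens, seed = 14)
  mask <- data.frame(scaffold = "chr1", start = 0, end = 4e6)
  dm <- windowed_divergence(subs, NULL, mask, spec, window = 1e6)
  mm <- mutation_rate_map(dm, G = 5, T_years = 54.9e6)
  rel_err <- (mm$mu - truth$rate) / truth$rate
  expect_lt(sqrt(mean(rel_err^2)), 0.05)
  # monotone directions of the conversions
  expect_true(all(diff(mutation_rate_from_divergence(0.043, c(2, 3, 5), 5e7)) > 0))
  expect_true(all(diff(mutation_rate_from_divergence(0.043, 3, c(5e7, 6e7, 7e7))) < 0))
  expect_true(all(diff(divergence_time_from_rate(0.043, 3, c(1e-9, 1e-8, 1e-7))) < 0))
})
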