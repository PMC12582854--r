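test_that("Haar pyramid reproduces the hand-computed example", {
  w <- haar_dwt(c(1, 3, 2, 2))
  expect_equal(w$details[[1]], c(-2, 0) / sqrt(2), tolerance = 1e-9)
  expect_equal(round(w$details[[1]], 5), c(-1.41421, 0))
  expect_equal(w$details[[2]], 0)
  expect_equal(w$smooth, 4)   # mean * sqrt(n)
  # constant input: all details zero
  wc <- haar_dwt(rep(3.7, 16))
  expect_true(all(abs(unlist(wc$details)) < 1e-12))
  expect_error(haar_dwt(rnorm(10)), "power of two")
})

test_that("Haar transform conserves energy and reconstructs exactly", {
  set.seed(41)
  for (k in 1:5) {
    x <- rnorm(4096)
    w <- haar_dwt(x)
    energy <- sum(unlist(w$details)^2) + sum(w$smooth^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-9)
    expect_equal(haar_idwt(w), x, tolerance = 1e-9)
    expect_equal(vapply(w$details, length, numeric(1)), 4096 / 2^(1:12))
  }
  # partial-depth decomposition also reconstructs
  x <- rnorm(64)
  w3 <- haar_dwt(x, J = 3)
  expect_equal(haar_idwt(w3), x, tolerance = 1e-11)
})

test_that("halves are dyadic, inner-anchored and within the original", {
  h <- split_halves(seq_len(8192))
  expect_equal(length(h$left), 4096)
  expect_equal(length(h$right), 4096)
  h2 <- split_halves(seq_len(10000))
  expect_equal(length(h2$left), 4096)   # 2^12 cap
  expect_equal(h2$left, 905:5000)       # anchored at the midpoint
  expect_equal(h2$right, 5001:9096)
  expect_true(all(c(h2$left, h2$right) %in% 1:10000))
  h3 <- split_halves(seq_len(100), max_level = 12)
  expect_equal(length(h3$left), 32)     # floor-power-of-two rule
  expect_error(split_halves(1:3), "too short")
})

test_that("log transform uses the half-minimum offset and keeps order", {
  x <- c(0, 0.5, 1, 2)
  y <- log_transform_rates(x)
  expect_equal(attr(y, "eps"), 0.25)
  expect_equal(as.numeric(y), log(x + 0.25))
  expect_true(all(diff(as.numeric(y)) > 0))
  # strictly positive track with negligible offset: plain log
  z <- log_transform_rates(c(1, exp(1)))
  expect_equal(as.numeric(z), log(c(1, exp(1)) + 0.5), tolerance = 1e-12)
  expect_error(log_transform_rates(c(0, 0)), "all-zero")
  expect_error(log_transform_rates(c(-1, 2)), "non-negative")
})

test_that("Kendall tau and exact p match full pair/permutation enumeration", {
  # perfect association (single-coefficient coarse levels report NA)
  d1 <- haar_dwt(rnorm(32)); d2 <- d1
  d3 <- d1; d3$details <- lapply(d1$details, function(v) -v)
  rep_same <- kendall_detail_correlations(list(a = d1, b = d2))
  expect_equal(rep_same$tau[rep_same$level <= 4], rep(1, 4), tolerance = 1e-12)
  expect_true(is.na(rep_same$tau[rep_same$level == 5]))
  rep_neg <- kendall_detail_correlations(list(a = d1, b = d3))
  expect_equal(rep_neg$tau[rep_neg$level <= 4], rep(-1, 4), tolerance = 1e-12)
  # n = 6 oracle: tau by pair counting, p by permutation enumeration
  set.seed(42)
  x <- rnorm(6); y <- rnorm(6)
  conc <- 0; disc <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  tau_hand <- (conc - disc) / choose(6, 2)
  taus <- vapply(all_perms(1:6), function(p) {
    stats::cor(x, y[p], method = "kendall")
  }, numeric(1))
  p_hand <- mean(abs(taus) >= abs(tau_hand) - 1e-12)
  ct <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
  expect_equal(unname(ct$estimate), tau_hand)
  expect_equal(ct$p.value, p_hand)
  # the report path produces the same numbers at a given level
  dx <- haar_dwt(rnorm(16)); dy <- haar_dwt(rnorm(16))
  dx$details[[1]] <- x; dy$details[[1]] <- y
  rep6 <- kendall_detail_correlations(list(a = dx, b = dy))
  expect_equal(rep6$tau[rep6$level == 1], tau_hand)
  expect_equal(rep6$p[rep6$level == 1], p_hand)
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(43)
  d1 <- haar_dwt(rnorm(128))
  d2 <- haar_dwt(rnorm(128))
  base <- kendall_detail_correlations(list(a = d1, b = d2))
  d2m <- d2
  d2m$details <- lapply(d2$details, function(v) exp(3 * v) - 1)
  mono <- kendall_detail_correlations(list(a = d1, b = d2m))
  expect_equal(mono$tau, base$tau)
})

test_that("through-origin models recover planted coefficients", {
  set.seed(44)
  n <- 256
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
  make_dec <- function(v) { d <- haar_dwt(rnorm(n)); d$details[[1]] <- v; d }
  y <- 2 * x1
  dec <- list(recombination = make_dec(y), diversity = make_dec(x1),
              divergence = make_dec(x2), gc = make_dec(x3),
              exon = make_dec(x4))
  rep1 <- suppressWarnings(scale_linear_models(dec))  # perfect fit by design
  lvl1 <- rep1[rep1$level == 1, ]
  expect_equal(lvl1$coef[lvl1$predictor == "diversity"], 2, tolerance = 1e-10)
  expect_equal(lvl1$coef[lvl1$predictor != "diversity"],
               rep(0, 3), tolerance = 1e-10)
  expect_equal(lvl1$adj_r2[1], 1, tolerance = 1e-12)
  # brute-force normal equations on a 10-point example
  X <- cbind(rnorm(10), rnorm(10))
  yy <- rnorm(10)
  beta_hand <- solve(t(X) %*% X, t(X) %*% yy)
  dec10 <- list(recombination = make_dec(c(yy, numeric(n - 10))),
                a = make_dec(c(X[, 1], numeric(n - 10))),
                b = make_dec(c(X[, 2], numeric(n - 10))))
  # restrict to the 10-point design by direct lm comparison instead
  fit <- stats::lm(yy ~ 0 + X)
  expect_equal(unname(stats::coef(fit)), as.numeric(beta_hand), tolerance = 1e-10)
  # rank deficiency is reported with the offending predictor
  dec_bad <- list(recombination = make_dec(y), diversity = make_dec(x1),
                  dup = make_dec(x1))
  expect_error(scale_linear_models(dec_bad), "collinear")
})

test_that("null regressions keep the nominal type-I error rate", {
  set.seed(45)
  n <- 128
  rej <- replicate(200, {
    dec <- list(recombination = haar_dwt(rnorm(n)),
                diversity = haar_dwt(rnorm(n)),
                gc = haar_dwt(rnorm(n)))
    r <- scale_linear_models(dec)
    r$p[r$level == 1] < 0.05
  })
  expect_lt(mean(rej), 0.10)   # nominal 5%, Monte-Carlo slack
})

test_that("a correlation planted at one scale is detected there only", {
  set.seed(46)
  n <- 4096; J <- 12; planted <- 5
  build <- function(shared) {
    d <- haar_dwt(rnorm(n))
    for (j in seq_len(J)) {
      m <- length(d$details[[j]])
      d$details[[j]] <- if (j == planted) {
        shared + 0.25 * rnorm(m)
      } else rnorm(m)
    }
    d
  }
  shared <- rnorm(n / 2^planted)
  decs <- list(a = build(shared), b = build(shared))
  rep <- kendall_detail_correlations(decs, alpha = 0.01)
  expect_true(rep$significant[rep$level == planted])
  expect_false(any(rep$significant[rep$level != planted & rep$level <= 9]))
})

test_that("feature binning matches a per-base recount", {
  set.seed(47)
  len <- 8000
  spec <- toy_spec(len, "chr1", gc = 0.5)
  seqs <- simulate_sequence(spec, seed = 48)
  ann <- data.frame(scaffold = "chr1", start = c(500, 3250, 6000),
                    end = c(1500, 3750, 6100), type = "exon")
  mask <- data.frame(scaffold = "chr1", start = c(0, 4000), end = c(3000, 8000))
  pan <- simulate_haplotypes(equilibrium_model(2000), 5e-7, 0, 4, len, seed = 49,
                             scaffold = "chr1")
  pi1k <- windowed_diversity(pan, mask, spec, 1000, min_access = 0)
  subs <- simulate_substitutions(spec, 1e-5, 1e3, seed = 50)
  d1k <- windowed_divergence(subs, NULL, mask, spec, 1000, 1000, min_access = 0)
  rmap <- recomb_map("chr1", seq(0, 7000, by = 1000), seq(1000, 8000, by = 1000),
                     runif(8, 0, 2))
  tr <- bin_tracks(seqs, ann, pi1k, d1k, rmap, mask, bin = 1000)
  expect_equal(nrow(tr), 8)
  # GC per bin against a direct string count
  s <- strsplit(as.character(seqs[[1]]), "")[[1]]
  for (k in 1:8) {
    bin_chars <- s[((k - 1) * 1000 + 1):(k * 1000)]
    expect_equal(tr$gc[k], mean(bin_chars %in% c("G", "C")))
  }
  # exon fraction: exon covering half a bin gives 0.5
  expect_equal(tr$exon[4], 0.5)
  expect_equal(tr$exon[1], 0.5)  # 500-1000 of bin 1
  expect_equal(tr$exon[7], 0.1)
  # accessibility fraction from the mask
  expect_equal(tr$access_frac, c(1, 1, 1, 0, 1, 1, 1, 1))
  expect_true(tr$masked[4])
  # grid mismatch errors
  expect_error(bin_tracks(seqs, ann, pi1k[-1, ], d1k, rmap, mask, bin = 1000),
               "common")
})

test_that("all-GC sequence yields a unit GC track", {
  seqs <- Biostrings::DNAStringSet(c(chrG = paste(rep("G", 4000), collapse = "")))
  spec <- genome_spec("chrG", 4000)
  mask <- data.frame(scaffold = "chrG", start = 0, end = 4000)
  pan <- toy_panel(rbind(c(1), c(0)), positions = 10, length = 4000,
                   scaffold = "chrG")
  pi1k <- windowed_diversity(pan, mask, spec, 1000, min_access = 0)
  subs <- data.frame(scaffold = "chrG", pos = 100L)
  d1k <- windowed_divergence(subs, NULL, mask, spec, 1000, 1000, min_access = 0)
  rmap <- recomb_map("chrG", seq(0, 3000, by = 1000), seq(1000, 4000, by = 1000),
                     rep(1, 4))
  tr <- bin_tracks(seqs, NULL, pi1k, d1k, rmap, mask)
  expect_equal(tr$gc, rep(1, 4))
  expect_equal(tr$exon, rep(0, 4))
})
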