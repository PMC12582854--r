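# Demography-aware two-locus likelihood lookup tables and the pairwise
# composite-likelihood estimator of the population recombination rate.

# Encode a (n00, n01, n10, n11) configuration as a single integer key.
config_key <- function(cfg, n) {
  ((cfg[, 1] * (n + 1) + cfg[, 2]) * (n + 1) + cfg[, 3]) * (n + 1) + cfg[, 4]
}

# Fold a configuration matrix to its canonical representative: minimum key
# over allele relabelling at either locus and locus exchange (8 symmetries).
# Matches unpolarized SNP data.
fold_config_key <- function(cfg, n) {
  a <- cfg[, 1]; b <- cfg[, 2]; c <- cfg[, 3]; d <- cfg[, 4]
  variants <- list(
    cbind(a, b, c, d), cbind(c, d, a, b), cbind(b, a, d, c), cbind(d, c, b, a),
    cbind(a, c, b, d), cbind(b, d, a, c), cbind(c, a, d, b), cbind(d, b, c, a)
  )
  keys <- vapply(variants, config_key, numeric(nrow(cfg)), n = n)
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = 1)
  apply(keys, 1, min)
}

# All folded biallelic two-locus configurations for sample size n.
enumerate_folded_configs <- function(n) {
  grid <- expand.grid(n00 = 0:n, n01 = 0:n, n10 = 0:n)
  grid$n11 <- n - grid$n00 - grid$n01 - grid$n10
  grid <- grid[grid$n11 >= 0, ]
  # both loci segregating
  segA <- (grid$n10 + grid$n11) > 0 & (grid$n10 + grid$n11) < n
  segB <- (grid$n01 + grid$n11) > 0 & (grid$n01 + grid$n11) < n
  cfg <- as.matrix(grid[segA & segB, c("n00", "n01", "n10", "n11")])
  keys <- fold_config_key(cfg, n)
  keep <- !duplicated(keys)
  list(configs = cfg[keep, , drop = FALSE], keys = keys[keep])
}

#' Build a Monte-Carlo two-locus likelihood lookup table
#'
#' For each value of the population recombination rate `rho` between two loci,
#' simulates two-locus genealogies for `n_hap` haplotypes under the given
#' demographic history, conditions on both loci being biallelic by dropping a
#' single mutation per locus uniformly over the marginal tree (the low-theta
#' limit), and tallies folded haplotype-count configurations into normalized
#' probabilities. Unobserved configurations receive a 0.5 pseudocount before
#' normalization so the composite log-likelihood stays finite.
#'
#' `rho` is scaled as `4 * N_ref * r_gen` with `N_ref` the first-epoch
#' (present-day) diploid size of `model`.
#'
#' @param n_hap Haplotype sample size (2-30).
#' @param grid Ascending numeric rho grid starting at 0, at least 2 points.
#' @param model A [demographic_model()].
#' @param reps Monte-Carlo replicates per grid point (>= 1e4 for production
#'   tables; smaller values are fine for toy examples).
#' @param seed Integer seed.
#' @return A `two_locus_table`: list with `n_hap`, `grid`, `configs`, `keys`,
#'   `prob` (configurations x grid matrix; columns sum to 1), `model`, `reps`.
#' @export
build_two_locus_table <- function(n_hap, grid, model, reps, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), reps >= 1,
            length(grid) >= 2, grid[1] == 0, all(diff(grid) > 0))
  enum <- enumerate_folded_configs(n_hap)
  raw <- with_seed(seed, {
    cpp_two_locus_configs(n_hap, grid, as.integer(reps),
                          model$sizes, model$times, model$sizes[1])
  })
  keys <- fold_config_key(raw[, 2:5, drop = FALSE], n_hap)
  idx <- match(keys, enum$keys)
  if (anyNA(idx)) stop("internal error: sampled configuration outside enumeration")
  counts <- matrix(0, nrow = nrow(enum$configs), ncol = length(grid))
  tab <- table(factor(idx, levels = seq_len(nrow(enum$configs))), raw[, 1])
  counts[, as.integer(colnames(tab))] <- as.matrix(tab)
  if (any(colSums(counts) / reps < 1e-4)) {
    stop("conditioning acceptance below 1e-4; increase `reps`")
  }
  counts <- counts + 0.5
  prob <- sweep(counts, 2, colSums(counts), "/")
  structure(list(n_hap = n_hap, grid = as.numeric(grid),
                 configs = enum$configs, keys = enum$keys, prob = prob,
                 model = model, reps = as.integer(reps)),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat("Two-locus lookup table: n =", x$n_hap, "haplotypes,",
      length(x$grid), "rho grid points,", nrow(x$configs),
      "folded configurations,", x$reps, "Monte-Carlo reps/point\n")
  invisible(x)
}

# Interpolated log-probability of table rows `row` at pairwise rho values
# `rho_pair` (linear in rho, clamped at the grid ends).
table_log_prob <- function(table, row, rho_pair) {
  g <- table$grid
  rho_pair <- pmin(pmax(rho_pair, g[1]), g[length(g)])
  lo <- findInterval(rho_pair, g, rightmost.closed = TRUE)
  hi <- pmin(lo + 1, length(g))
  w <- ifelse(hi == lo, 0, (rho_pair - g[lo]) / (g[hi] - g[lo]))
  p <- table$prob[cbind(row, lo)] * (1 - w) + table$prob[cbind(row, hi)] * w
  log(p)
}

# SNP-pair table for a panel: indices, bp distance and folded config row.
panel_pairs <- function(panel, table, in_window, pair_span) {
  S <- length(panel$positions)
  n <- panel$n_hap
  pairs <- do.call(rbind, lapply(in_window, function(i) {
    if (i >= S) return(NULL)
    cbind(i = i, j = seq(i + 1, min(i + pair_span, S)))
  }))
  if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
  H <- panel$haplotypes
  n1 <- colSums(H)
  n11 <- vapply(seq_len(nrow(pairs)), function(r) {
    sum(H[, pairs[r, "i"]] & H[, pairs[r, "j"]])
  }, numeric(1))
  n10 <- n1[pairs[, "i"]] - n11
  n01 <- n1[pairs[, "j"]] - n11
  n00 <- n - n10 - n01 - n11
  keys <- fold_config_key(cbind(n00, n01, n10, n11), n)
  row <- match(keys, table$keys)
  if (anyNA(row)) stop("panel configuration missing from lookup table ",
                       "(sample sizes differ?)")
  data.frame(i = pairs[, "i"], j = pairs[, "j"],
             dist = panel$positions[pairs[, "j"]] - panel$positions[pairs[, "i"]],
             row = row)
}

#' Composite-likelihood estimate of the per-bp population recombination rate
#'
#' Maximizes the pairwise composite log-likelihood
#' `sum over SNP pairs (i, j), j - i <= pair_span, of log P(config_ij | rho * dist_ij)`
#' over a per-bp candidate grid, with the lookup table interpolated linearly
#' in rho and clamped at its grid ends. Pairs are anchored at the left SNP:
#' every pair whose left member lies in `window` contributes.
#'
#' @param panel A `haplotype_panel` (see [simulate_haplotypes()]).
#' @param table A [build_two_locus_table()] result with matching `n_hap`.
#' @param window Optional `c(start, end)` (0-based half-open bp) restricting
#'   the left SNP; default spans the whole panel.
#' @param pair_span Maximum SNP-index separation of a pair (default 30).
#' @param rho_grid Per-bp candidate values; default 0 plus 25 log-spaced
#'   points from 1e-7 to 1e-2.
#' @return A `rho_estimate`: list with `rho_hat` (per bp; `NA` when fewer
#'   than 2 usable SNPs), `objective` (data frame `rho`, `loglik`),
#'   `n_pairs`, `n_snps`.
#' @export
estimate_rho_window <- function(panel, table, window = NULL, pair_span = 30,
                                rho_grid = default_rho_grid()) {
  stopifnot(inherits(table, "two_locus_table"),
            panel$n_hap == table$n_hap, pair_span >= 1)
  pos <- panel$positions
  in_window <- if (is.null(window)) seq_along(pos) else
    which(pos >= window[1] & pos < window[2])
  if (length(in_window) < 2) {
    return(structure(list(rho_hat = NA_real_, objective = NULL,
                          n_pairs = 0L, n_snps = length(in_window)),
                     class = "rho_estimate"))
  }
  pr <- panel_pairs(panel, table, in_window, pair_span)
  if (is.null(pr)) {
    return(structure(list(rho_hat = NA_real_, objective = NULL,
                          n_pairs = 0L, n_snps = length(in_window)),
                     class = "rho_estimate"))
  }
  ll <- vapply(rho_grid, function(r) {
    sum(table_log_prob(table, pr$row, r * pr$dist))
  }, numeric(1))
  structure(list(rho_hat = rho_grid[which.max(ll)],
                 objective = data.frame(rho = rho_grid, loglik = ll),
                 n_pairs = nrow(pr), n_snps = length(in_window)),
            class = "rho_estimate")
}

#' Default per-bp candidate grid for rho
#' @export
default_rho_grid <- function() c(0, 10^seq(-7, -2, length.out = 25))

#' Default pairwise rho grid for lookup tables
#' @export
default_table_grid <- function() c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100)

#' Expected r-squared per grid point of a lookup table
#'
#' Monte-Carlo expectation of the squared allele-frequency correlation between
#' the two loci, per rho grid value; a decreasing profile in rho is the
#' classic LD decay signature used to sanity-check tables.
#'
#' @param table A `two_locus_table`.
#' @return Numeric vector, one value per grid point.
#' @export
table_expected_r2 <- function(table) {
  cfg <- table$configs
  n <- table$n_hap
  pA <- (cfg[, 3] + cfg[, 4]) / n
  pB <- (cfg[, 2] + cfg[, 4]) / n
  D <- cfg[, 4] / n - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  as.numeric(colSums(table$prob * r2))
}
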