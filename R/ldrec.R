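# LD-based recombination maps: Watterson's theta, rho -> r conversion,
# window estimation over a lookup table, outlier filtering, rescaling to the
# pedigree map length, aggregation to display windows, motif comparison and
# the simulation benchmark.

#' Watterson's theta per site
#'
#' `theta_W = S / (H_{n-1} * L)` with `H_k` the k-th harmonic number.
#'
#' @param S Number of segregating sites.
#' @param n_hap Number of haplotypes (>= 2).
#' @param L Number of sites surveyed.
#' @return Theta per site.
#' @export
#' @examples
#' watterson_theta(100, 10, 1e4)
watterson_theta <- function(S, n_hap, L) {
  stopifnot(n_hap >= 2, L > 0, S >= 0)
  S / (sum(1 / seq_len(n_hap - 1)) * L)
}

#' Convert a population recombination rate to a per-generation rate
#'
#' Uses the mutation-rate route to the effective size: `N_e =
#' theta_hat / (4 mu)`, then per-generation rate `rho / (4 N_e)` and
#' `cM/Mb = 1e8 * rho / (4 N_e)`.
#'
#' @param rho Population recombination rate per bp (`4 N_e r`).
#' @param mu Mutation rate per bp per generation (> 0).
#' @param theta_hat Estimated theta per site (> 0).
#' @return List with `r` (per bp per generation), `cM_Mb`, and the implied
#'   `N_e`.
#' @export
#' @examples
#' rho_to_r(3.9763e-4, mu = 0.4e-8, theta_hat = 4 * 11695 * 0.4e-8)
rho_to_r <- function(rho, mu, theta_hat) {
  if (mu <= 0 || theta_hat <= 0) stop("mu and theta_hat must be positive")
  if (any(rho < 0, na.rm = TRUE)) stop("rho must be non-negative")
  n_e <- theta_hat / (4 * mu)
  r <- rho / (4 * n_e)
  list(r = r, cM_Mb = r * 1e8, N_e = n_e)
}

#' Recombination map container
#'
#' @param scaffold,start,end Window coordinates (0-based half-open).
#' @param rate Rate in cM/Mb (may contain `NA` for undefined windows).
#' @param rho Optional per-bp population rate.
#' @return A `recomb_map` data frame with a `cum_cM` column (per-scaffold
#'   cumulative map length; `NA` rates contribute zero).
#' @export
recomb_map <- function(scaffold, start, end, rate, rho = NA_real_) {
  df <- data.frame(scaffold = as.character(scaffold), start = start, end = end,
                   rate = rate, rho = rho, stringsAsFactors = FALSE)
  if (any(df$rate < 0, na.rm = TRUE)) stop("rates must be non-negative")
  df <- df[order(df$scaffold, df$start), ]
  rownames(df) <- NULL
  df <- add_cumulative_cM(df)
  class(df) <- c("recomb_map", "data.frame")
  df
}

add_cumulative_cM <- function(df) {
  cm <- ifelse(is.na(df$rate), 0, df$rate * (df$end - df$start) / 1e6)
  df$cum_cM <- stats::ave(cm, df$scaffold, FUN = cumsum)
  df
}

#' Total genetic map length in cM
#'
#' @param map A `recomb_map`.
#' @export
total_map_cM <- function(map) {
  sum(map$rate * (map$end - map$start) / 1e6, na.rm = TRUE)
}

#' Estimate a windowed recombination map from a haplotype panel
#'
#' Runs [estimate_rho_window()] on consecutive windows of the panel's region
#' and converts rho to cM/Mb with [rho_to_r()] using Watterson's theta
#' estimated from the panel.
#'
#' @param panel A `haplotype_panel`.
#' @param table A `two_locus_table` with matching sample size.
#' @param window Estimation window size in bp (constant rate per window).
#' @param mu Mutation rate used for the conversion.
#' @param pair_span Maximum SNP-index pair separation.
#' @param rho_grid Per-bp candidate grid.
#' @return A `recomb_map` with one row per window (`NA` where < 2 SNPs).
#' @export
estimate_recombination_map <- function(panel, table, window, mu,
                                       pair_span = 30,
                                       rho_grid = default_rho_grid()) {
  theta <- watterson_theta(length(panel$positions), panel$n_hap, panel$length)
  starts <- seq(0, panel$length - 1, by = window)
  ends <- pmin(starts + window, panel$length)
  rho <- vapply(seq_along(starts), function(i) {
    estimate_rho_window(panel, table, window = c(starts[i], ends[i]),
                        pair_span = pair_span, rho_grid = rho_grid)$rho_hat
  }, numeric(1))
  rate <- rho_to_r(pmax(rho, 0), mu, theta)$cM_Mb
  rate[is.na(rho)] <- NA_real_
  recomb_map(panel$scaffold, starts, ends, rate, rho)
}

#' Remove extreme-rate outlier windows
#'
#' Windows whose rate exceeds `fold` times the length-weighted genome-wide
#' mean (undefined windows excluded from the mean) are removed, mirroring the
#' removal of assembly-artifact regions with rates ~100-300x the average.
#'
#' @param map A `recomb_map`.
#' @param fold Fold-change threshold (> 1; `Inf` disables filtering).
#' @return List with `map` (filtered, cumulative lengths recomputed) and
#'   `removed` (the dropped rows).
#' @export
filter_outlier_windows <- function(map, fold = 100) {
  stopifnot(fold > 1)
  w <- map$end - map$start
  ok <- !is.na(map$rate)
  gmean <- sum(map$rate[ok] * w[ok]) / sum(w[ok])
  out <- !is.na(map$rate) & map$rate > fold * gmean
  kept <- map[!out, , drop = FALSE]
  rownames(kept) <- NULL
  kept <- add_cumulative_cM(kept)
  class(kept) <- class(map)
  list(map = kept, removed = map[out, , drop = FALSE], genome_mean = gmean)
}

#' Rescale a map to a target total genetic length
#'
#' Multiplies every rate by `target_cM / total_map_cM(map)` so the total map
#' length matches an externally known (pedigree-based) length while relative
#' rates are untouched.
#'
#' @param map A `recomb_map`.
#' @param target_cM Target total length in cM (default the aye-aye
#'   sex-averaged autosomal pedigree map, 1525 cM).
#' @return List with `map` (rescaled) and `factor`.
#' @export
rescale_map <- function(map, target_cM = AYE_PEDIGREE_MAP_CM) {
  stopifnot(target_cM > 0)
  tot <- total_map_cM(map)
  if (tot <= 0) stop("map has zero total length; cannot rescale")
  f <- target_cM / tot
  map$rate <- map$rate * f
  if (!is.null(map$rho)) map$rho <- map$rho * f
  map <- add_cumulative_cM(map)
  list(map = map, factor = f)
}

#' Aggregate a fine map into sliding display windows
#'
#' bp-length-weighted mean of the constituent fine-window rates per sliding
#' window (undefined fine windows carry no weight).
#'
#' @param map A `recomb_map`.
#' @param window,step Aggregation window and step in bp (defaults 1 Mb /
#'   500 kb).
#' @return A `recomb_map` on the sliding grid.
#' @export
aggregate_windows <- function(map, window = 1e6, step = 5e5) {
  stopifnot(step <= window)
  scafs <- unique(map$scaffold)
  lens <- vapply(scafs, function(s) max(map$end[map$scaffold == s]), numeric(1))
  spec <- genome_spec(scafs, lens)
  win <- sliding_windows(spec, window, step, keep_partial = FALSE)
  fine <- df_to_gr(map)
  agg <- df_to_gr(win)
  hits <- GenomicRanges::findOverlaps(agg, fine)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(agg[qh], fine[sh])
  wgt <- GenomicRanges::width(ov)
  rate <- map$rate[sh]
  ok <- !is.na(rate)
  num <- tapply(wgt[ok] * rate[ok], qh[ok], sum)
  den <- tapply(wgt[ok], qh[ok], sum)
  agg_rate <- rep(NA_real_, nrow(win))
  agg_rate[as.integer(names(num))] <- num / den
  recomb_map(win$scaffold, win$start, win$end, agg_rate)
}

#' Welch t-test of rates in motif vs non-motif windows
#'
#' Partitions the fine map windows by whether they contain a motif midpoint
#' and compares mean rates with a Welch two-sample t-test (two-sided).
#'
#' @param fine_map A `recomb_map`.
#' @param motifs A `motif_set` (data frame `scaffold`, `pos`).
#' @return List with `mean_motif`, `mean_other` (cM/Mb), `t`, `df`, `p`,
#'   and group sizes.
#' @export
compare_motif_rates <- function(fine_map, motifs) {
  mw <- df_to_gr(fine_map)
  mp <- df_to_gr(data.frame(scaffold = motifs$scaffold, start = motifs$pos,
                            end = motifs$pos + 1))
  has <- GenomicRanges::countOverlaps(mw, mp) > 0
  ok <- !is.na(fine_map$rate)
  x <- fine_map$rate[ok & has]
  y <- fine_map$rate[ok & !has]
  if (length(x) < 2 || length(y) < 2) {
    stop("both motif and non-motif groups need at least 2 defined windows")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(mean_motif = mean(x), mean_other = mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_motif = length(x), n_other = length(y))
}

#' Benchmark the LD-based estimator on simulated data
#'
#' Simulates replicate regions with a fixed true crossover rate under each
#' demography/mutation-rate combination, estimates the rate with the
#' composite-likelihood estimator over a demography-matched lookup table, and
#' reports per-combination mean/median estimates, bias and ratio to truth
#' (before any rescaling).
#'
#' @param demographies Named list of [demographic_model()]s; defaults to the
#'   bottleneck-decline and equilibrium aye-aye models.
#' @param mu_values Mutation rates (per bp per gen) to cross with the
#'   demographies (defaults 0.4e-8 and 1.1e-8).
#' @param true_cM_Mb True simulated crossover rate (default 0.85 cM/Mb).
#' @param n_dip Number of sampled diploids (default 5, i.e. 10 haplotypes).
#' @param replicates Replicates per combination (default 10).
#' @param region_length Region length in bp (default 1.6 Mb; reducible).
#' @param table_reps Monte-Carlo replicates per lookup-table grid point.
#' @param table_grid Pairwise rho grid for the tables.
#' @param pair_span,rho_grid Estimator settings.
#' @param seed Integer seed.
#' @return A `benchmark_report`: list with `estimates` (one row per
#'   replicate) and `summary` (one row per combination).
#' @export
benchmark_estimator <- function(demographies = list(
                                  bottleneck_decline = bottleneck_decline_model(),
                                  equilibrium = equilibrium_model()),
                                mu_values = c(AYE_MU_YOUNG, AYE_MU_AVERAGE),
                                true_cM_Mb = AYE_PEDIGREE_REC_CM_MB,
                                n_dip = 5, replicates = 10,
                                region_length = 1.6e6,
                                table_reps = 10000,
                                table_grid = default_table_grid(),
                                pair_span = 30,
                                rho_grid = default_rho_grid(),
                                seed = 1) {
  n_hap <- 2L * n_dip
  r_true <- true_cM_Mb * 1e-8
  rows <- list()
  for (di in seq_along(demographies)) {
    model <- demographies[[di]]
    dname <- names(demographies)[di]
    tab <- build_two_locus_table(n_hap, table_grid, model, table_reps,
                                 seed = seed + 1000L * di)
    for (mu in mu_values) {
      for (rep_i in seq_len(replicates)) {
        s <- seed + 1000L * di + round(mu * 1e10) + rep_i
        panel <- simulate_haplotypes(model, mu, r_true, n_hap, region_length,
                                     seed = s)
        est <- estimate_rho_window(panel, tab, pair_span = pair_span,
                                   rho_grid = rho_grid)
        theta <- watterson_theta(length(panel$positions), n_hap, region_length)
        cm <- if (is.na(est$rho_hat) || theta <= 0) NA_real_ else
          rho_to_r(est$rho_hat, mu, theta)$cM_Mb
        rows[[length(rows) + 1L]] <- data.frame(
          demography = dname, mu = mu, replicate = rep_i,
          S = length(panel$positions), theta = theta,
          rho_hat = est$rho_hat, est_cM_Mb = cm, stringsAsFactors = FALSE)
      }
    }
  }
  est <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(est, list(est$demography, est$mu)), function(g) {
    data.frame(demography = g$demography[1], mu = g$mu[1],
               n = nrow(g),
               mean_cM_Mb = mean(g$est_cM_Mb, na.rm = TRUE),
               median_cM_Mb = stats::median(g$est_cM_Mb, na.rm = TRUE),
               bias_cM_Mb = mean(g$est_cM_Mb, na.rm = TRUE) - true_cM_Mb,
               ratio_to_truth = stats::median(g$est_cM_Mb, na.rm = TRUE) / true_cM_Mb,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(estimates = est, summary = agg, true_cM_Mb = true_cM_Mb,
                 region_length = region_length, n_dip = n_dip),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("LD-estimator benchmark: true rate", x$true_cM_Mb, "cM/Mb,",
      x$n_dip, "diploids,", x$region_length / 1e6, "Mb regions\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
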