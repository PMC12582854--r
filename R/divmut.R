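# Accessibility masking, windowed neutral divergence and diversity, and the
# algebra linking divergence d, mutation rate mu, generation time G and
# divergence time T: d = mu * (T / G) for a single lineage measured against
# the reconstructed ancestor.

#' Build an accessibility mask
#'
#' Accessible sites are the callable intervals minus the union of all
#' annotated features expanded by `flank` on both sides, minus any extra
#' masks. Features extending beyond scaffold bounds are clipped with a
#' warning.
#'
#' @param annotations An `annotation_set` (or any data frame with `scaffold`,
#'   `start`, `end`), possibly empty.
#' @param callable Data frame of callable intervals (`scaffold`, `start`,
#'   `end`, 0-based half-open).
#' @param flank Flank in bp added to each feature before subtraction
#'   (default 10 kb, masking sites within 10 kb of functional regions).
#' @param extra_masks Optional list of interval data frames to subtract
#'   (e.g. blacklists).
#' @param spec Optional [genome_spec()] supplying scaffold bounds for
#'   clipping.
#' @return An `accessibility_mask`: data frame `scaffold`, `start`, `end`
#'   with sorted, disjoint intervals.
#' @export
#' @examples
#' callable <- data.frame(scaffold = "s", start = 0, end = 1e5)
#' ann <- data.frame(scaffold = "s", start = 20000, end = 21000)
#' build_accessibility_mask(ann, callable, flank = 10000)
build_accessibility_mask <- function(annotations, callable, flank = 10000,
                                     extra_masks = list(), spec = NULL) {
  stopifnot(flank >= 0)
  sl <- if (!is.null(spec)) spec_seqlengths(spec) else NULL
  acc <- GenomicRanges::reduce(df_to_gr(callable))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    if (!is.null(sl)) {
      beyond <- annotations$end > sl[annotations$scaffold] | annotations$start < 0
      if (any(beyond, na.rm = TRUE)) {
        warning("features beyond scaffold bounds clipped")
        annotations$start <- pmax(annotations$start, 0)
        annotations$end <- pmin(annotations$end, sl[annotations$scaffold])
        annotations <- annotations[annotations$end > annotations$start, ]
      }
    }
    feat <- df_to_gr(annotations)
    feat <- GenomicRanges::reduce(feat + flank)
    acc <- GenomicRanges::setdiff(acc, feat)
  }
  for (m in extra_masks) {
    if (!is.null(m) && nrow(m) > 0) acc <- GenomicRanges::setdiff(acc, df_to_gr(m))
  }
  out <- gr_to_df(GenomicRanges::reduce(acc))
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accessibility_mask", "data.frame")
  out
}

# Windowed sums of a per-position weight vector restricted to a mask, via
# run-length coverage views. `positions` are 0-based; windows 0-based
# half-open on a single scaffold.
windowed_masked_sum <- function(positions, weights, mask_df, windows, len) {
  cov_mask <- IRanges::coverage(
    IRanges::IRanges(mask_df$start + 1, mask_df$end), width = len)
  acc <- as.logical(cov_mask >= 1)
  wvec <- numeric(len)
  if (length(positions) > 0) wvec[positions + 1] <- weights
  wvec[!acc] <- 0
  rcov <- S4Vectors::Rle(wvec)
  v <- IRanges::Views(rcov, IRanges::IRanges(windows$start + 1, windows$end))
  num <- IRanges::viewSums(v)
  va <- IRanges::Views(cov_mask, IRanges::IRanges(windows$start + 1, windows$end))
  acc_n <- IRanges::viewSums(va)
  list(sum = as.numeric(num), accessible = as.numeric(acc_n))
}

#' Windowed neutral divergence
#'
#' Per sliding window: numerator = accessible substitution positions that are
#' not segregating in the sample; denominator = accessible sites. Windows
#' advance by `step`; the last partial window of each scaffold is kept and
#' flagged. Windows with fewer than `min_access` (fraction) accessible sites
#' are reported as missing; windows with zero accessible sites are undefined,
#' not zero.
#'
#' @param subs A `substitution_set` (data frame `scaffold`, `pos`).
#' @param snps Optional polymorphism positions (data frame `scaffold`,
#'   `pos`); substitutions coinciding with a segregating site are excluded
#'   from the numerator (they remain in the accessible denominator).
#' @param mask An `accessibility_mask`.
#' @param spec A [genome_spec()] giving scaffold lengths.
#' @param window,step Window and step size in bp (`step <= window`).
#' @param min_access Minimum accessible fraction for a defined window
#'   (default 0.1).
#' @param drop_segregating_from_denominator If `TRUE`, segregating positions
#'   are removed from the accessible denominator as well (default `FALSE`:
#'   the site is alignable and callable).
#' @return A `divergence_map`: data frame `scaffold`, `start`, `end`,
#'   `divergent`, `accessible`, `d`, `partial`, `low_access`.
#' @export
windowed_divergence <- function(subs, snps = NULL, mask, spec, window,
                                step = window, min_access = 0.1,
                                drop_segregating_from_denominator = FALSE) {
  stopifnot(window > 0, step <= window)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    scaf <- spec$scaffold[i]; len <- spec$length[i]
    win <- sliding_windows(spec[i, ], window, step)
    m <- mask[mask$scaffold == scaf, , drop = FALSE]
    sp <- subs$pos[subs$scaffold == scaf]
    seg <- if (is.null(snps)) integer(0) else snps$pos[snps$scaffold == scaf]
    keep <- !(sp %in% seg)
    if (drop_segregating_from_denominator && length(seg) > 0 && nrow(m) > 0) {
      mgr <- GenomicRanges::setdiff(
        df_to_gr(m), df_to_gr(data.frame(scaffold = scaf, start = seg, end = seg + 1)))
      m <- gr_to_df(mgr)
    }
    res <- windowed_masked_sum(sp[keep], rep(1, sum(keep)), m, win, len)
    win$divergent <- res$sum
    win$accessible <- res$accessible
    win$low_access <- win$accessible < min_access * (win$end - win$start)
    win$d <- ifelse(win$accessible > 0 & !win$low_access,
                    win$divergent / win$accessible, NA_real_)
    win
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("divergence_map", "data.frame")
  out
}

#' Windowed nucleotide diversity
#'
#' Per window, pi equals the sum over accessible segregating sites of
#' `2 p (1 - p) n / (n - 1)` divided by the number of accessible sites
#' (monomorphic accessible sites contribute zero to the numerator).
#'
#' @param panel A `haplotype_panel`, or a list with `positions` (0-based) and
#'   `freq` (derived-allele counts) plus `n_hap`.
#' @param mask An `accessibility_mask`.
#' @param spec A [genome_spec()] (used for scaffold length).
#' @param window Window size in bp.
#' @param step Step size (defaults to `window`: non-overlapping 1 kb-style
#'   grid).
#' @param min_access Minimum accessible fraction for a defined window.
#' @return Data frame `scaffold`, `start`, `end`, `pi`, `accessible`,
#'   `partial`, `low_access`.
#' @export
windowed_diversity <- function(panel, mask, spec, window, step = window,
                               min_access = 0.1) {
  stopifnot(panel$n_hap >= 2)
  n <- panel$n_hap
  scaf <- panel$scaffold
  i <- match(scaf, spec$scaffold)
  if (is.na(i)) stop("panel scaffold absent from genome spec")
  len <- spec$length[i]
  win <- sliding_windows(spec[i, ], window, step)
  m <- mask[mask$scaffold == scaf, , drop = FALSE]
  p <- colSums(panel$haplotypes) / n
  wgt <- 2 * p * (1 - p) * n / (n - 1)
  res <- windowed_masked_sum(panel$positions, wgt, m, win, len)
  win$accessible <- res$accessible
  win$low_access <- win$accessible < min_access * (win$end - win$start)
  win$pi <- ifelse(win$accessible > 0 & !win$low_access,
                   res$sum / win$accessible, NA_real_)
  win[, c("scaffold", "start", "end", "pi", "accessible", "partial", "low_access")]
}

#' Mutation rate from neutral divergence
#'
#' Under neutrality a lineage accumulates `d = mu * (T / G)` substitutions
#' per site, so `mu = d * G / T`.
#'
#' @param d Per-site neutral divergence (>= 0).
#' @param G Generation time in years (> 0).
#' @param T_years Divergence time in years (> 0).
#' @return Mutation rate in mutations/bp/generation.
#' @export
#' @examples
#' mutation_rate_from_divergence(0.043, G = 5, T_years = 54.9e6)
mutation_rate_from_divergence <- function(d, G, T_years) {
  if (any(T_years <= 0, na.rm = TRUE)) stop("divergence time must be positive")
  if (any(G <= 0, na.rm = TRUE)) stop("generation time must be positive")
  if (any(d < 0, na.rm = TRUE)) stop("divergence must be non-negative")
  d * G / T_years
}

#' Divergence time from a known mutation rate
#'
#' Inverts `d = mu * (T / G)`: `T = d * G / mu` (years).
#'
#' @param d Per-site neutral divergence.
#' @param G Generation time in years.
#' @param mu Mutation rate in mutations/bp/generation (> 0).
#' @return Divergence time in years.
#' @export
#' @examples
#' divergence_time_from_rate(0.043, G = 5, mu = 4.0e-9) / 1e6  # mya
divergence_time_from_rate <- function(d, G, mu) {
  if (any(mu <= 0, na.rm = TRUE)) stop("mutation rate must be positive")
  if (any(G <= 0, na.rm = TRUE)) stop("generation time must be positive")
  d * G / mu
}

#' Convert a divergence map to a mutation-rate map
#'
#' @param div_map A `divergence_map` from [windowed_divergence()].
#' @param G,T_years Generation time and divergence time (years).
#' @return The map with an added `mu` column (mutations/bp/generation).
#' @export
mutation_rate_map <- function(div_map, G, T_years) {
  div_map$mu <- mutation_rate_from_divergence(pmax(div_map$d, 0), G, T_years)
  div_map$mu[is.na(div_map$d)] <- NA_real_
  div_map
}

# Round-half-up at `digits` significant figures (printed-table convention;
# base signif() rounds half to even).
signif_half_up <- function(x, digits = 3) {
  s <- ifelse(x == 0, 0, sign(x))
  x <- abs(x)
  mag <- ifelse(x == 0, 0, floor(log10(x)) + 1)
  f <- 10^(digits - mag)
  # small absolute nudge so values sitting on .5 after floating-point error
  # (e.g. 537.4999999...) round up as intended
  s * floor(x * f + 0.5 + 1e-8) / f
}

#' Cross table of divergence-based rates and pedigree-based times
#'
#' Builds both halves of the conversion table: divergence-based mutation
#' rates `mu(G, T)` for each generation-time/divergence-time pair, and
#' pedigree-anchored divergence times `T(G, mu)` for each generation-time/
#' pedigree-mutation-rate pair. Values are rounded half-up to 3 significant
#' figures (times reported in mya).
#'
#' @param d Mean per-site neutral divergence.
#' @param G_years Generation times in years.
#' @param T_mya Divergence times in millions of years.
#' @param mu_pedigree Pedigree-based mutation rates (mutations/bp/gen).
#' @return List with matrices `mu` (`G x T`, mutations/bp/gen) and `T_mya`
#'   (`G x mu`), plus the unrounded `mu_raw`, `T_mya_raw`.
#' @export
#' @examples
#' rate_conversion_table(0.043, c(3, 5), c(54.9, 74.7), c(4e-9, 1.1e-8, 2e-8))
rate_conversion_table <- function(d, G_years, T_mya, mu_pedigree) {
  stopifnot(length(G_years) > 0, length(T_mya) > 0, length(mu_pedigree) > 0)
  mu_raw <- outer(G_years, T_mya, function(g, t) {
    mutation_rate_from_divergence(d, g, t * 1e6)
  })
  t_raw <- outer(G_years, mu_pedigree, function(g, m) {
    divergence_time_from_rate(d, g, m) / 1e6
  })
  dimnames(mu_raw) <- list(paste0("G", G_years), paste0("T", T_mya, "mya"))
  dimnames(t_raw) <- list(paste0("G", G_years), paste0("mu", mu_pedigree))
  list(mu = signif_half_up(mu_raw, 3), T_mya = signif_half_up(t_raw, 3),
       mu_raw = mu_raw, T_mya_raw = t_raw, d = d)
}
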