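# Multi-scale structure of 1 kb genomic feature tracks: orthonormal Haar
# pyramid, dyadic half-scaffold extraction, Kendall correlations of detail
# coefficients per scale, and through-origin linear models.

#' Bin genomic features on a common 1 kb grid
#'
#' Builds the five feature tracks (nucleotide diversity, neutral divergence,
#' recombination rate, GC fraction, exon fraction) on one grid, with the
#' per-bin accessible fraction; bins below the accessibility threshold or
#' with undefined inputs are flagged `masked`.
#'
#' @param genome A `Biostrings::DNAStringSet` (or path to a FASTA file) for
#'   GC content.
#' @param annotations An `annotation_set` (exon intervals).
#' @param pi_track Output of [windowed_diversity()] on the `bin` grid.
#' @param div_track Output of [windowed_divergence()] on the `bin` grid.
#' @param rec_map A `recomb_map` on the `bin` grid.
#' @param mask An `accessibility_mask`.
#' @param bin Bin width in bp (default 1000).
#' @param min_access Minimum accessible fraction for an unmasked bin.
#' @return A `feature_tracks` data frame: `scaffold`, `start`, `end`,
#'   `diversity`, `divergence`, `recombination`, `gc`, `exon`,
#'   `access_frac`, `masked`.
#' @export
bin_tracks <- function(genome, annotations, pi_track, div_track, rec_map,
                       mask, bin = 1000, min_access = 0.1) {
  stopifnot(bin > 0)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  spec <- genome_spec(names(genome), as.numeric(lens))
  grid <- sliding_windows(spec, bin, bin)
  same_grid <- function(tr) {
    nrow(tr) == nrow(grid) && all(tr$scaffold == grid$scaffold) &&
      all(tr$start == grid$start) && all(tr$end == grid$end)
  }
  if (!same_grid(pi_track) || !same_grid(div_track) || !same_grid(rec_map)) {
    stop("input tracks are not on the common ", bin, " bp grid")
  }
  gc <- unlist(lapply(seq_along(genome), function(i) {
    g <- grid[grid$scaffold == names(genome)[i], ]
    v <- Biostrings::Views(genome[[i]], start = g$start + 1, end = g$end)
    f <- Biostrings::letterFrequency(v, letters = c("GC", "AT"))
    known <- f[, 1] + f[, 2]
    ifelse(known > 0, f[, 1] / known, NA_real_)
  }))
  exon_cov <- rep(0, nrow(grid))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    gr_ann <- GenomicRanges::reduce(df_to_gr(annotations))
    gr_grid <- df_to_gr(grid)
    hits <- GenomicRanges::findOverlaps(gr_grid, gr_ann)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      gr_grid[S4Vectors::queryHits(hits)], gr_ann[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    exon_cov[as.integer(names(agg))] <- agg
  }
  acc <- rep(0, nrow(grid))
  gr_mask <- df_to_gr(mask)
  gr_grid <- df_to_gr(grid)
  hits <- GenomicRanges::findOverlaps(gr_grid, gr_mask)
  if (length(hits) > 0) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      gr_grid[S4Vectors::queryHits(hits)], gr_mask[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    acc[as.integer(names(agg))] <- agg
  }
  width <- grid$end - grid$start
  out <- data.frame(
    scaffold = grid$scaffold, start = grid$start, end = grid$end,
    diversity = pi_track$pi, divergence = div_track$d,
    recombination = rec_map$rate, gc = gc, exon = exon_cov / width,
    access_frac = acc / width, stringsAsFactors = FALSE)
  out$masked <- out$access_frac < min_access | is.na(out$diversity) |
    is.na(out$divergence) | is.na(out$recombination) | is.na(out$gc)
  class(out) <- c("feature_tracks", "data.frame")
  out
}

#' Log-transform a non-negative rate track
#'
#' `ln(x + eps)` with `eps` equal to half the smallest positive value in the
#' track; intended for the three rate tracks (recombination, diversity,
#' divergence), never for GC or exon fractions.
#'
#' @param x Non-negative numeric vector (`NA` allowed).
#' @return Transformed vector with attribute `eps`.
#' @export
log_transform_rates <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("rates must be non-negative")
  pos <- x[!is.na(x) & x > 0]
  if (length(pos) == 0) stop("all-zero track cannot be log-transformed")
  eps <- min(pos) / 2
  structure(log(x + eps), eps = eps)
}

#' Split a track into dyadic left/right halves
#'
#' Each half is truncated to the largest `2^J` bins (`J <= max_level`) taken
#' from the scaffold midpoint outward, so both halves are dyadic and adjacent
#' to the inner edge.
#'
#' @param x Numeric vector of bin values.
#' @param max_level Maximum dyadic level J (default 12, i.e. 4096 bins).
#' @return List with `left`, `right` (length `2^J` each) and `J`.
#' @export
#' @examples
#' split_halves(rnorm(10000))$J
split_halves <- function(x, max_level = 12) {
  n <- length(x)
  if (n < 4) stop("track too short to split into dyadic halves")
  mid <- n %/% 2
  J <- min(max_level, floor(log2(mid)))
  size <- 2^J
  list(left = x[(mid - size + 1):mid], right = x[(mid + 1):(mid + size)], J = J)
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Pyramid recursion `s_{j,k} = (s_{j-1,2k-1} + s_{j-1,2k}) / sqrt(2)`,
#' `d_{j,k} = (s_{j-1,2k-1} - s_{j-1,2k}) / sqrt(2)` for levels `1..J`.
#' Orthonormality conserves energy: `sum(x^2) = sum(details^2) +
#' smooth^2`.
#'
#' @param x Numeric vector of length `2^J` (error on non-dyadic input; the
#'   caller truncates via [split_halves()]).
#' @param J Number of levels (default: full decomposition).
#' @return A `wavelet_decomposition`: list with `details` (list of numeric
#'   vectors, level j holding `2^(J-j)`... `length(x)/2^j` coefficients),
#'   `smooth` (final smooth coefficients), `J`, `n`.
#' @export
#' @examples
#' haar_dwt(c(1, 3, 2, 2))$details[[1]]
haar_dwt <- function(x, J = NULL) {
  n <- length(x)
  full <- log2(n)
  if (full != round(full)) stop("input length must be a power of two")
  if (is.null(J)) J <- full
  stopifnot(J >= 1, J <= full)
  details <- vector("list", J)
  s <- x
  for (j in seq_len(J)) {
    odd <- s[seq(1, length(s), by = 2)]
    even <- s[seq(2, length(s), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    s <- (odd + even) / sqrt(2)
  }
  structure(list(details = details, smooth = s, J = J, n = n),
            class = "wavelet_decomposition")
}

#' Inverse of [haar_dwt()]
#'
#' @param w A `wavelet_decomposition`.
#' @return The reconstructed numeric vector.
#' @export
haar_idwt <- function(w) {
  s <- w$smooth
  for (j in rev(seq_len(w$J))) {
    d <- w$details[[j]]
    out <- numeric(2 * length(s))
    out[seq(1, length(out), by = 2)] <- (s + d) / sqrt(2)
    out[seq(2, length(out), by = 2)] <- (s - d) / sqrt(2)
    s <- out
  }
  s
}

#' Kendall correlations of detail coefficients per scale
#'
#' For every pair of tracks and every level, computes Kendall's tau-b with
#' tie correction and a two-sided p-value (exact enumeration when the number
#' of coefficients is <= 10 and there are no ties; normal approximation
#' otherwise). Constant coefficient vectors yield `NA` (reported missing).
#'
#' @param decomps Named list of `wavelet_decomposition`s over the same input
#'   length.
#' @param alpha Significance level for the flag (default 0.01, two-tailed).
#' @return A `data.frame`: `level`, `scale_kb`, `pair`, `tau`, `p`,
#'   `significant`.
#' @export
kendall_detail_correlations <- function(decomps, alpha = 0.01) {
  stopifnot(length(decomps) >= 2, !is.null(names(decomps)))
  J <- decomps[[1]]$J
  if (!all(vapply(decomps, function(d) d$J == J, logical(1)))) {
    stop("decompositions have differing depths")
  }
  nm <- names(decomps)
  rows <- list()
  for (j in seq_len(J)) {
    for (a in seq_len(length(nm) - 1)) {
      for (b in seq((a + 1), length(nm))) {
        x <- decomps[[a]]$details[[j]]
        y <- decomps[[b]]$details[[j]]
        if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) {
          tau <- NA_real_; p <- NA_real_
        } else {
          ct <- suppressWarnings(
            stats::cor.test(x, y, method = "kendall",
                            exact = length(x) <= 10, alternative = "two.sided"))
          tau <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          level = j, scale_kb = 2^j, pair = paste(nm[a], nm[b], sep = ":"),
          tau = tau, p = p,
          significant = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Through-origin linear models of detail coefficients per scale
#'
#' At each level, regresses the response track's detail coefficients on the
#' predictors' detail coefficients with the intercept forced through the
#' origin; reports coefficients, two-sided t-test p-values, signs and the
#' adjusted r-squared under the no-intercept convention (total sum of squares
#' about zero).
#'
#' @param decomps Named list of `wavelet_decomposition`s.
#' @param response Name of the response track (default `"recombination"`).
#' @return A `data.frame`: `level`, `scale_kb`, `predictor`, `coef`, `p`,
#'   `sign`, `adj_r2`, `n`.
#' @export
scale_linear_models <- function(decomps, response = "recombination") {
  stopifnot(response %in% names(decomps))
  preds <- setdiff(names(decomps), response)
  J <- decomps[[1]]$J
  rows <- list()
  for (j in seq_len(J)) {
    y <- decomps[[response]]$details[[j]]
    X <- vapply(preds, function(p) decomps[[p]]$details[[j]],
                numeric(length(y)))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, preds))
    if (length(y) <= ncol(X)) next  # underdetermined at the coarsest scales
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
      stop("rank-deficient design at level ", j, "; collinear predictors: ",
           paste(drop, collapse = ", "))
    }
    fit <- stats::lm(y ~ 0 + X)
    sm <- summary(fit)
    co <- sm$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      level = j, scale_kb = 2^j, predictor = preds,
      coef = unname(co[, 1]), p = unname(co[, 4]),
      sign = sign(unname(co[, 1])), adj_r2 = sm$adj.r.squared,
      n = length(y), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Decompose feature-track halves for the multi-scale analysis
#'
#' Splits each selected column of a `feature_tracks` scaffold into dyadic
#' halves, imputes masked bins with the half's mean (fraction reported;
#' halves above `max_impute` flagged), and returns Haar decompositions per
#' half.
#'
#' @param tracks A `feature_tracks` data frame (single scaffold).
#' @param columns Track columns to decompose.
#' @param max_level Maximum dyadic depth (default 12).
#' @param max_impute Imputed-bin fraction above which a half is flagged
#'   (default 0.2).
#' @param log_rates Log-transform the rate columns (diversity, divergence,
#'   recombination) before decomposition?
#' @return List of halves (`left`, `right`), each with `decomps` (named list
#'   of decompositions), `imputed_frac`, `flagged`.
#' @export
decompose_halves <- function(tracks,
                             columns = c("recombination", "diversity",
                                         "divergence", "gc", "exon"),
                             max_level = 12, max_impute = 0.2,
                             log_rates = FALSE) {
  stopifnot(length(unique(tracks$scaffold)) == 1)
  rate_cols <- intersect(columns, c("recombination", "diversity", "divergence"))
  vals <- tracks[, columns, drop = FALSE]
  if (log_rates) for (cc in rate_cols) vals[[cc]] <- log_transform_rates(vals[[cc]])
  masked <- tracks$masked
  halves <- split_halves(seq_len(nrow(tracks)), max_level)
  out <- list()
  for (h in c("left", "right")) {
    idx <- halves[[h]]
    miss <- masked[idx]
    dec <- lapply(columns, function(cc) {
      v <- vals[[cc]][idx]
      # rate tracks are undefined in inaccessible bins; GC/exon come from the
      # assembly and only need their own missing values imputed
      bad <- if (cc %in% rate_cols) miss | is.na(v) else is.na(v)
      v[bad] <- mean(v[!bad])
      haar_dwt(v)
    })
    names(dec) <- columns
    out[[h]] <- list(decomps = dec, imputed_frac = mean(miss),
                     flagged = mean(miss) > max_impute)
  }
  out
}
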