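# Bespoke SNP post-filters applied after standard genotype-quality control:
# SNP-cluster removal and the heterozygote-excess Hardy-Weinberg exact test.

#' Polymorphism set
#'
#' Biallelic SNPs with per-individual diploid genotypes.
#'
#' @param scaffold,pos,ref,alt Per-site vectors (`pos` 0-based).
#' @param gt Integer matrix (sites x individuals) of alternate-allele dosages
#'   (0, 1, 2; `NA` = missing).
#' @param phased Logical: are genotypes phased?
#' @param hap Optional 0/1 haplotype matrix (2*individuals x sites) when
#'   phased.
#' @return A `polymorphism_set`.
#' @export
polymorphism_set <- function(scaffold, pos, ref, alt, gt, phased = FALSE,
                             hap = NULL) {
  gt <- as.matrix(gt)
  stopifnot(length(scaffold) == length(pos), nrow(gt) == length(pos))
  ord <- order(scaffold, pos)
  structure(list(scaffold = as.character(scaffold)[ord],
                 pos = as.integer(pos)[ord],
                 ref = as.character(ref)[ord], alt = as.character(alt)[ord],
                 gt = gt[ord, , drop = FALSE], phased = isTRUE(phased),
                 hap = if (!is.null(hap)) hap[, ord, drop = FALSE]),
            class = "polymorphism_set")
}

#' @export
print.polymorphism_set <- function(x, ...) {
  cat("Polymorphism set:", length(x$pos), "biallelic SNPs,",
      ncol(x$gt), "diploid individuals,",
      if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

n_sites <- function(snps) length(snps$pos)

subset_sites <- function(snps, keep) {
  polymorphism_set(snps$scaffold[keep], snps$pos[keep], snps$ref[keep],
                   snps$alt[keep], snps$gt[keep, , drop = FALSE],
                   snps$phased, if (!is.null(snps$hap)) snps$hap[, keep, drop = FALSE])
}

#' Convert a haplotype panel to a polymorphism set
#'
#' Pairs consecutive haplotypes into diploid individuals; alleles are
#' arbitrary fixed ref/alt symbols.
#'
#' @param panel A `haplotype_panel` with an even number of haplotypes.
#' @return A phased `polymorphism_set`.
#' @export
panel_to_polymorphisms <- function(panel) {
  stopifnot(panel$n_hap %% 2 == 0)
  h <- panel$haplotypes
  idx1 <- seq(1, panel$n_hap, by = 2)
  gt <- h[idx1, , drop = FALSE] + h[idx1 + 1, , drop = FALSE]
  polymorphism_set(rep(panel$scaffold, length(panel$positions)),
                   panel$positions,
                   rep("A", length(panel$positions)),
                   rep("C", length(panel$positions)),
                   t(gt), phased = TRUE, hap = h)
}

#' Rebuild a haplotype panel from a phased polymorphism set
#'
#' Inverse of [panel_to_polymorphisms()] for a single scaffold; requires
#' phased haplotypes.
#'
#' @param snps A phased `polymorphism_set` carrying haplotypes.
#' @param length Region/scaffold length in bp.
#' @param scaffold Scaffold to extract (default: the first present).
#' @return A `haplotype_panel`.
#' @export
polymorphisms_to_panel <- function(snps, length, scaffold = NULL) {
  if (!snps$phased || is.null(snps$hap)) stop("polymorphism set is not phased")
  if (is.null(scaffold)) scaffold <- snps$scaffold[1]
  keep <- snps$scaffold == scaffold
  structure(list(haplotypes = snps$hap[, keep, drop = FALSE],
                 positions = snps$pos[keep], n_hap = nrow(snps$hap),
                 length = length, scaffold = scaffold),
            class = "haplotype_panel")
}

#' Remove SNP clusters
#'
#' Removes every SNP lying in any `w`-bp span that contains at least `k`
#' SNPs (default: three or more SNPs within a 10 bp window).
#'
#' @param snps A `polymorphism_set`.
#' @param k Minimum cluster size (>= 2).
#' @param w Window span in bp (>= 1).
#' @return List with `snps` (filtered) and `removed` (count).
#' @export
#' @examples
#' # positions 100, 105, 109 span 10 bp: all three removed
filter_snp_clusters <- function(snps, k = 3, w = 10) {
  stopifnot(k >= 2, w >= 1)
  drop <- logical(n_sites(snps))
  for (s in unique(snps$scaffold)) {
    idx <- which(snps$scaffold == s)
    pos <- snps$pos[idx]
    m <- length(pos)
    if (m < k) next
    starts <- seq_len(m - k + 1)
    clustered <- starts[pos[starts + k - 1] - pos[starts] <= w - 1]
    for (st in clustered) drop[idx[st:(st + k - 1)]] <- TRUE
  }
  list(snps = subset_sites(snps, !drop), removed = sum(drop))
}

#' Heterozygote-excess exact Hardy-Weinberg p-value
#'
#' Levene-Haldane exact distribution of the heterozygote count conditional on
#' the allele counts; the one-sided excess p-value is the probability of
#' observing at least as many heterozygotes.
#'
#' @param n_het,n_hom_ref,n_hom_alt Genotype counts at one site.
#' @param side `"excess"` (one-sided heterozygote excess, default) or
#'   `"two.sided"` (sum of outcomes no more probable than observed).
#' @return Exact p-value.
#' @export
#' @examples
#' hwe_exact_test(5, 0, 0)  # five diploids all heterozygous: 32/252
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt,
                           side = c("excess", "two.sided")) {
  side <- match.arg(side)
  n <- n_het + n_hom_ref + n_hom_alt
  n_a <- 2 * n_hom_alt + n_het        # minor/alt allele count
  if (n_a > n) {                       # fold to the rarer allele
    n_a <- 2 * n - n_a
  }
  if (n_a == 0 || n_a == 1) return(1)  # monomorphic or singleton
  hs <- seq(n_a %% 2, n_a, by = 2)
  logp <- lfactorial(n) - lfactorial((n_a - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (n_a + hs) / 2) + hs * log(2) +
    lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n)
  p <- exp(logp)
  p <- p / sum(p)  # guard accumulated rounding
  if (side == "excess") {
    sum(p[hs >= n_het])
  } else {
    p_obs <- p[hs == n_het]
    sum(p[p <= p_obs + 1e-12])
  }
}

#' Filter SNPs showing heterozygote excess
#'
#' Applies the exact test per site and removes sites with p-value below the
#' threshold. Sites with any missing genotype are skipped (kept, with a
#' warning).
#'
#' @param snps A `polymorphism_set`.
#' @param p_threshold Removal threshold (default 0.01).
#' @param side Passed to [hwe_exact_test()].
#' @return List with `snps` (filtered), `removed` (count), `p` (per-site
#'   p-values; `NA` for skipped sites).
#' @export
filter_hwe <- function(snps, p_threshold = 0.01, side = "excess") {
  stopifnot(ncol(snps$gt) >= 2)
  gt <- snps$gt
  miss <- apply(is.na(gt), 1, any)
  if (any(miss)) warning(sum(miss), " sites with missing genotypes skipped")
  n_het <- rowSums(gt == 1, na.rm = TRUE)
  n_ref <- rowSums(gt == 0, na.rm = TRUE)
  n_alt <- rowSums(gt == 2, na.rm = TRUE)
  p <- rep(NA_real_, n_sites(snps))
  for (i in which(!miss)) p[i] <- hwe_exact_test(n_het[i], n_ref[i], n_alt[i],
                                                 side = side)
  drop <- !is.na(p) & p < p_threshold
  list(snps = subset_sites(snps, !drop), removed = sum(drop), p = p)
}
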