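---
title: "Methods: fine-scale mutation and recombination rate maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale mutation and recombination rate maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

# The two rate maps

## Divergence-based mutation rates

Under neutrality, the number of substitutions per site that a lineage
accumulates in `T` years is `K = (mu / G) * T`, with `G` the generation time
in years and `mu` the per-base-pair per-generation mutation rate. The package
measures windowed neutral divergence `d` as *divergent sites / accessible
sites* and converts both ways:

* `mutation_rate_from_divergence(d, G, T)` returns `mu = d G / T`;
* `divergence_time_from_rate(d, G, mu)` returns `T = d G / mu`.

`d` is single-lineage divergence to a reconstructed ancestor, so `T` enters
undoubled. Accessibility is explicit: `build_accessibility_mask()` subtracts
annotated features expanded by a `flank` (default 10 kb — far enough that
linked selection on functional sites no longer distorts neutral divergence at
the window scale) and any extra masks from a callable set. Two further rules,
both of which were genuinely open design decisions:

* **Segregating sites** are removed from the numerator only. A site carrying
  a within-species polymorphism cannot be counted as a fixed difference, but
  it *is* alignable and callable, so it stays in the denominator. A toggle
  (`drop_segregating_from_denominator`) implements the stricter reading.
* **Windows with fewer than 10% accessible sites** are reported as missing
  rather than as noisy ratios (`min_access = 0.1`, configurable). Zero
  accessible sites is always undefined, never zero. Partial terminal windows
  are kept and flagged `partial`.

The conversion table (`rate_conversion_table()`) rounds half-up at three
significant figures, which is the convention the printed table follows (base
R's `signif()` rounds half to even and reproduces none of the `.5`-boundary
cells). The published divergence value 0.043 is itself a rounded mean: with
`d = 0.043` the six divergence-time cells reproduce exactly, while the four
mutation-rate cells land within one unit of the third significant digit (an
unrounded mean near 0.0432 reproduces them exactly). The acceptance test
asserts exactly this, no more.

## LD-based recombination rates

The estimator is a pairwise composite likelihood over a Monte-Carlo two-locus
lookup table:

1. **Table** (`build_two_locus_table()`): for each value of the pairwise
   scaled rate `rho` on a grid (default `0, 0.1, …, 100`), simulate two-locus
   ancestral histories for `n` haplotypes under a piecewise-constant
   demography, in generations, with coalescence rate `k(k-1)/2 / (2N(t))` and
   recombination rate `rho / (4 N_ref)` per doubly-ancestral lineage
   (`N_ref` = present-day size). Conditioning on both loci biallelic is
   implemented by dropping exactly one mutation per locus uniformly over the
   marginal genealogy — the low-`theta` conditional likelihood that classical
   two-locus samplers tabulate — so the acceptance rate is 1 by construction.
   Configurations are folded (minor-allele orientation and locus exchange) to
   match unpolarized SNPs. Unobserved configurations receive a 0.5
   pseudocount before normalization so no data configuration has zero
   probability; with the default `reps = 10000` per grid point the
   pseudocount mass is below 2%.
2. **Objective** (`estimate_rho_window()`): `sum over pairs (i, j), j - i <=
   pair_span, of log P(config_ij | rho * dist_ij)`, with `pair_span = 30`
   SNPs (the window size recommended for the production estimator this
   mirrors), distance in bp between SNP positions, linear interpolation in
   `rho` between table grid points, and clamping at the grid ends. The
   candidate grid is `0` plus 25 log-spaced per-bp values from `1e-7` to
   `1e-2`; the argmax is returned together with the full objective so tests
   can compare against brute-force enumeration. Pairs crossing a window edge
   belong to the window containing the left SNP. Windows with fewer than two
   SNPs are undefined, never zero.
3. **Conversion**: `rho_to_r()` uses `N_e = theta_W / (4 mu)` with
   Watterson's `theta_W = S / (H_{n-1} L)` and a user-specified `mu`, then
   `r = rho / (4 N_e)` and `cM/Mb = 1e8 r`.
4. **Post-processing**: `filter_outlier_windows()` removes windows above
   `fold = 100` times the length-weighted genome mean (assembly-artifact
   regions show 100–300-fold excesses); `rescale_map()` multiplies all rates
   by `target_cM / total` so the map total matches the pedigree-based
   1525 cM while relative rates are untouched; `aggregate_windows()` forms
   bp-weighted means on a 1 Mb / 500 kb sliding grid.

The fused-block smoothing penalty of the production tool is deliberately not
replicated: smoothing here comes from constant-rate estimation windows, which
preserves the relative-rate structure that rescaling and the multi-scale
analysis rely on.

One property of this class of estimator is worth stating because a test
encodes it: on data simulated with `rho = 0`, every SNP pair shares a single
genealogy, so the per-replicate argmax of the composite objective has high
variance even though the *ensemble-mean* objective is maximized at zero. The
test suite asserts the ensemble property and strong concentration of
estimates at the grid floor rather than a fixed per-replicate success rate.

# The coalescent simulator

`simulate_haplotypes()` implements the sequentially Markov coalescent (SMC')
with recombination under piecewise-constant demography: a standard coalescent
tree at the left edge; breakpoints at rate `r(x) * L_gen` along the sequence
(`L_gen` = current tree length in generations); at each breakpoint a uniform
point on the tree detaches and re-coalesces into the full current tree at
rate `k(t) / (2 N(t))`, with back-coalescence leaving the genealogy
unchanged. Mutations are Poisson on branches (infinite sites on an integer
grid; coincident integer positions are dropped, which at the simulated
densities affects well under 1% of sites). SMC' was chosen over an exact
ancestral recombination graph because the benchmark region has total
`rho ≈ 640` where the ARG's lineage count is unwieldy, and because the
package cross-validates against an *external* exact simulator (msprime,
driven through the system Python in the test suite) on segregating-site
counts and mean pairwise r²: one internal simulator, one independent oracle.

The bottleneck-decline history is encoded by
`bottleneck_decline_model()`: ancestral `N = 11,695` until 1,133 generations
ago, then a decline "at a constant rate" to `N = 1,285` at present. Constant
rate is interpreted as a constant per-generation multiplicative rate —
exponential in `N` — because a constant absolute rate would make the model's
shape depend on the unit of time; a linear option is exposed
(`kind = "linear"`). The continuous decline is discretized into 16
piecewise-constant epochs (geometric-mean size per step), which keeps every
hazard integral closed-form; at 16 steps the discretization error in
coalescence probabilities is far below Monte-Carlo noise at the replicate
counts used anywhere in the package. The stepwise size history used by the
production lookup-table tool is stored verbatim
(`ayeaye_size_history()`), including its `epochtimes` string whose unit
convention the upstream documentation does not state; it is flagged as such
and interpreted as generations where needed, not silently rescaled.

# What the synthetic generator emulates — and what it does not

The generators produce: lineage substitutions with window-varying rates
(each accessible site mutates independently with probability
`mu * branch_gens`, erroring on saturation); SMC' haplotype panels; exon
annotations from an alternating-renewal process whose realized density
concentrates around the target on Mb scaffolds; motif placements with
probability proportional to `1 + (enrichment - 1) * rate / max(rate)`; and
IID sequence at a target GC content. All take a single integer seed and are
bit-reproducible.

They do **not** emulate: CpG or context-dependent mutation, gene conversion,
selection or background selection, sequencing error, missing genotypes, or
assembly artifacts. Passing tests therefore demonstrate that the *inference
machinery* is correct and internally consistent under the stated models —
not that real aye-aye data are free of the confounders the real pipeline
handles upstream (mapping, genotyping, liftover masking are out of scope
here, with blacklist masking generalized to "subtract any user BED").

# Multi-scale analysis choices

Tracks are binned at 1 kb with per-bin accessible fractions. The
recombination track on the 1 kb grid is the piecewise-constant fine map
*projected* onto bins (`aggregate_windows(map, 1000, 1000)`): re-estimating
`rho` per kilobase is statistically meaningless at realistic SNP densities
(usually fewer than two SNPs per bin).

Each scaffold is split at its midpoint and each half truncated to the largest
`2^J` bins (`J <= 12`, scales 2–4096 kb) anchored at the inner edge. Masked
bins are imputed with the half's mean *for the rate tracks only* — GC and
exon content are defined from the assembly regardless of accessibility, and
mask-imputing them would erase exactly the exonic signal the exon track
exists to carry. The imputed fraction is reported and halves above 20%
imputation are flagged. The Haar pyramid is orthonormal
(`s_{j,k} = (s_{j-1,2k-1}+s_{j-1,2k})/sqrt(2)`,
`d_{j,k} = (s_{j-1,2k-1}-s_{j-1,2k})/sqrt(2)`), so energy conservation and
perfect reconstruction are exact to rounding and are asserted at `1e-9`.

Kendall's tau-b with tie correction is computed per track pair per scale,
with exact enumeration p-values when a scale has at most 10 coefficients and
the normal approximation otherwise; the 1% two-tailed flag carries no
multiple-testing correction, matching the fixed-level convention of the
analysis it reimplements. Log transformation (`ln(x + eps)`, `eps` = half the
smallest positive value) is applied to the three rate tracks before the
linear models only — tau is invariant under monotone transforms, so the
correlation panels are unaffected either way, and a property test pins that
down. The linear models force the intercept through the origin (detail
coefficients of any stationary track have mean zero by construction);
adjusted r² follows the no-intercept convention (total sum of squares about
zero). Rank-deficient designs error with the names of the collinear
predictors rather than silently dropping terms.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations so the whole
suite runs in a few minutes on one core: the benchmark grid uses the full
2 demographies x 2 mutation rates x 10 replicates design at 1.6 Mb in the
acceptance script and 200 kb in the test suite; lookup tables use 10,000
Monte-Carlo replicates per grid point (tables at that size build in
seconds thanks to the compiled two-locus sampler); SFS and diversity
calibrations use hundreds to thousands of sub-kilobase regions. Every random
quantity flows from an explicit integer seed, and the end-to-end pipeline
writes byte-identical outputs on reruns with the same configuration.

# Known limitations

* The composite likelihood treats pairs as independent; its variance on
  single windows is large (the worked example's single-replicate estimate of
  0.45 cM/Mb against a true 0.85 is typical scatter), and only medians over
  replicates are interpreted in the benchmark.
* `rho` is scaled by the *present-day* size of the supplied demography; under
  the decline history the mismatch between that scaling, the depressed
  Watterson's theta, and the true ancestral rates is precisely why the
  benchmark reports (not asserts) systematic underestimation under decline.
* The two-locus table conditions on biallelism in the low-mutation limit; at
  very high per-pair mutation rates the conditional is an approximation.
* Unphased input is accepted at the I/O layer but the estimator consumes
  phased haplotypes; statistical phasing is out of scope.
* The Haar-based analysis requires dyadic halves and discards up to half a
  scaffold minus `2^J` bins at each end; alternative paddings were not
  explored because truncation matches the analysis being reimplemented.
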