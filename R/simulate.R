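# Synthetic-data generators: lineage substitutions, SMC' haplotype panels,
# exon annotations and motif placements. Every generator consumes a single
# integer seed and restores the caller's RNG state on exit.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Normalise a mutation/recombination rate argument to a per-scaffold step
# function. `x` may be a scalar (already in per-bp per-generation units) or a
# rate_track (mutation tracks in mut/bp/gen; recombination tracks in cM/Mb,
# converted with 1 cM/Mb = 1e-8 crossovers/bp/gen).
rate_step_fun <- function(x, scaffold, length, cM_Mb = FALSE) {
  if (is.numeric(x) && base::length(x) == 1L) {
    data.frame(start = 0, end = length, rate = as.numeric(x))
  } else {
    stopifnot(inherits(x, "rate_track"))
    w <- x[x$scaffold == scaffold, , drop = FALSE]
    if (nrow(w) == 0) stop("rate track has no windows for scaffold ", scaffold)
    w <- w[order(w$start), ]
    if (w$start[1] > 0 || w$end[nrow(w)] < length) {
      stop("rate track does not cover scaffold ", scaffold)
    }
    r <- if (cM_Mb) w$rate * 1e-8 else w$rate
    data.frame(start = w$start, end = w$end, rate = r)
  }
}

step_integral <- function(sf, from, to) {
  a <- pmax(sf$start, from); b <- pmin(sf$end, to)
  sum(pmax(0, b - a) * sf$rate)
}

# First x' > from with integral_{from}^{x'} rate = target; Inf if unreachable.
step_advance <- function(sf, from, target) {
  for (i in seq_len(nrow(sf))) {
    if (sf$end[i] <= from) next
    a <- max(sf$start[i], from)
    seg <- (sf$end[i] - a) * sf$rate[i]
    if (seg >= target && sf$rate[i] > 0) return(a + target / sf$rate[i])
    target <- target - seg
  }
  Inf
}

#' Drop substitutions along a single lineage
#'
#' Each site mutates independently with probability `min(1, mu * branch_gens)`
#' where `mu` is the local per-site per-generation rate from `mu_track` and
#' `branch_gens` the lineage length in generations. Emulates branch-specific
#' point substitutions relative to a reconstructed ancestor.
#'
#' @param spec A [genome_spec()].
#' @param mu_track A [rate_track()] in mutations/bp/generation, or a scalar.
#' @param branch_gens Branch length in generations (> 0).
#' @param seed Integer seed.
#' @return A `substitution_set`: data frame `scaffold`, `pos` (0-based,
#'   sorted).
#' @export
#' @examples
#' spec <- genome_spec("s", 1e5)
#' subs <- simulate_substitutions(spec, 2.36e-9, branch_gens = 54.9e6 / 3, seed = 1)
simulate_substitutions <- function(spec, mu_track, branch_gens, seed = NULL) {
  stopifnot(branch_gens > 0)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(spec)), function(i) {
      sf <- rate_step_fun(mu_track, spec$scaffold[i], spec$length[i])
      p <- sf$rate * branch_gens
      if (any(p > 1)) stop("saturation: rate * branch_gens exceeds 1 in a window")
      pos <- lapply(seq_len(nrow(sf)), function(j) {
        len <- sf$end[j] - sf$start[j]
        k <- stats::rbinom(1, len, p[j])
        if (k == 0) return(integer(0))
        sf$start[j] + sort(sample.int(len, k)) - 1L
      })
      pos <- unlist(pos)
      if (length(pos) == 0) return(NULL)
      data.frame(scaffold = spec$scaffold[i], pos = as.integer(pos),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- data.frame(scaffold = character(0), pos = integer(0))
    class(out) <- c("substitution_set", "data.frame")
    out
  })
}

# ---- coalescent machinery ---------------------------------------------------

# Standard coalescent tree for n_hap haplotypes under a piecewise-constant
# demography. Nodes 1..n_hap are leaves at time 0; node 2*n_hap-1 is the root.
sim_coalescent_tree <- function(n_hap, model) {
  stopifnot(n_hap >= 2)
  n_nodes <- 2L * n_hap - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  active <- seq_len(n_hap)
  t <- 0
  nxt <- n_hap + 1L
  while (length(active) > 1) {
    k <- length(active)
    hz <- coal_hazard_pieces(t, 0, k, model, pair = TRUE)
    t <- sample_piecewise_exp(t, hz$breaks, hz$rates)
    pick <- sample.int(length(active), 2)
    time[nxt] <- t
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(time = time, parent = parent, n_hap = n_hap)
}

tree_branch_lengths <- function(tree) {
  nb <- length(tree$time)
  bl <- numeric(nb)
  has_par <- tree$parent > 0
  bl[has_par] <- tree$time[tree$parent[has_par]] - tree$time[has_par]
  bl
}

# Leaf sets below each node, as a list of integer vectors.
tree_leaf_sets <- function(tree) {
  n <- length(tree$time)
  sets <- vector("list", n)
  for (i in seq_len(tree$n_hap)) sets[[i]] <- i
  ord <- order(tree$time)
  for (i in ord) {
    p <- tree$parent[i]
    if (p > 0) sets[[p]] <- c(sets[[p]], sets[[i]])
  }
  sets
}

# One SMC' transition: recombination at a uniform point on the tree, floating
# lineage re-coalesces into the full current tree; coalescing back onto the
# branch it detached from leaves the tree unchanged.
smc_prime_update <- function(tree, model) {
  n_hap <- tree$n_hap
  bl <- tree_branch_lengths(tree)
  branches <- which(bl > 0)
  b <- branches[sample.int(length(branches), 1, prob = bl[branches])]
  u <- tree$time[b] + stats::runif(1) * bl[b]

  itimes <- sort(tree$time[(n_hap + 1):length(tree$time)])
  k_times <- c(0, itimes)
  k_values <- c(n_hap, n_hap - seq_along(itimes))
  k_values[k_values < 1] <- 1L
  hz <- coal_hazard_pieces(u, k_times, k_values, model, pair = FALSE)
  tstar <- sample_piecewise_exp(u, hz$breaks, hz$rates)

  ptime <- ifelse(tree$parent == 0, Inf, tree$time[pmax(tree$parent, 1L)])
  alive <- which(tree$time <= tstar & ptime > tstar)
  target <- alive[sample.int(length(alive), 1)]
  if (target == b) return(tree)  # back-coalescence: same genealogy

  parent <- tree$parent
  time <- tree$time
  v <- parent[b]
  ch <- which(parent == v)
  cc <- ch[ch != b]
  parent[cc] <- parent[v]          # splice v out
  tgt <- if (target == v) cc else target
  time[v] <- tstar                 # reuse v as the new coalescence node
  parent[v] <- parent[tgt]
  parent[tgt] <- v
  parent[b] <- v
  list(time = time, parent = parent, n_hap = n_hap)
}

#' Simulate a phased haplotype panel under the SMC' coalescent
#'
#' Sequentially Markov coalescent (SMC') with recombination under a
#' piecewise-constant demographic history, with infinite-sites mutations.
#' Local genealogies change at recombination breakpoints whose intensity is
#' proportional to the local recombination rate and the current tree length.
#'
#' @param model A [demographic_model()].
#' @param mu Mutation rate: scalar (per bp per generation) or a
#'   [rate_track()] in mut/bp/gen.
#' @param rec Recombination rate: scalar (crossovers per bp per generation)
#'   or a [rate_track()] in cM/Mb (converted with 1 cM/Mb = 1e-8).
#' @param n_hap Number of haplotypes (>= 2).
#' @param length Region length in bp.
#' @param seed Integer seed.
#' @param scaffold Scaffold name carried by the panel.
#' @return A `haplotype_panel`: list with `haplotypes` (0/1 matrix, one row
#'   per haplotype), `positions` (0-based, strictly increasing), `n_hap`,
#'   `length`, `scaffold`.
#' @export
#' @examples
#' p <- simulate_haplotypes(equilibrium_model(1e4), mu = 1e-8, rec = 1e-8,
#'                          n_hap = 4, length = 5e4, seed = 1)
#' dim(p$haplotypes)
simulate_haplotypes <- function(model, mu, rec, n_hap, length, seed = NULL,
                                scaffold = "scaffold_1") {
  if (!inherits(model, "demographic_model")) stop("empty or invalid demography")
  stopifnot(n_hap >= 2, length > 0)
  mu_sf <- rate_step_fun(mu, scaffold, length)
  rec_sf <- rate_step_fun(rec, scaffold, length, cM_Mb = TRUE)
  with_seed(seed, {
    tree <- sim_coalescent_tree(n_hap, model)
    pos <- numeric(0)
    carriers <- list()
    x <- 0
    repeat {
      bl <- tree_branch_lengths(tree)
      L_gen <- sum(bl)
      x_next <- step_advance(rec_sf, x, stats::rexp(1) / L_gen)
      seg_end <- min(x_next, length)
      # mutations on [x, seg_end)
      mu_mass <- step_integral(mu_sf, x, seg_end)
      n_mut <- stats::rpois(1, L_gen * mu_mass)
      if (n_mut > 0) {
        sets <- tree_leaf_sets(tree)
        br <- sample.int(base::length(bl), n_mut, replace = TRUE, prob = bl)
        # positions by inverting the cumulative mutation mass over the segment
        targ <- sort(stats::runif(n_mut) * mu_mass)
        p <- vapply(targ, function(g) step_advance(mu_sf, x, g), numeric(1))
        pos <- c(pos, p)
        carriers <- c(carriers, sets[br])
      }
      if (x_next >= length) break
      tree <- smc_prime_update(tree, model)
      x <- x_next
    }
    ip <- as.integer(floor(pos))
    ord <- order(ip)
    ip <- ip[ord]
    carriers <- carriers[ord]
    keep <- !duplicated(ip)  # infinite sites on an integer grid: drop clashes
    ip <- ip[keep]
    carriers <- carriers[keep]
    hap <- matrix(0L, nrow = n_hap, ncol = base::length(ip))
    for (j in seq_along(carriers)) hap[carriers[[j]], j] <- 1L
    structure(list(haplotypes = hap, positions = ip, n_hap = n_hap,
                   length = length, scaffold = scaffold),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", x$n_hap, "haplotypes,", length(x$positions),
      "segregating sites over", x$length, "bp on", x$scaffold, "\n")
  invisible(x)
}

#' Simulate non-overlapping exon annotations
#'
#' Exons are placed by an alternating-renewal process (exponential gap and
#' exon lengths) so the realized exon fraction concentrates around
#' `exon_density` on Mb-scale scaffolds.
#'
#' @param spec A [genome_spec()].
#' @param exon_density Target exon fraction in `[0, 1)`.
#' @param mean_exon_len Mean exon length in bp.
#' @param seed Integer seed.
#' @return An `annotation_set`: data frame `scaffold`, `start`, `end`,
#'   `type = "exon"` (0-based half-open, sorted, non-overlapping).
#' @export
simulate_annotations <- function(spec, exon_density, mean_exon_len = 200,
                                 seed = NULL) {
  stopifnot(exon_density >= 0, exon_density < 1, mean_exon_len >= 1)
  with_seed(seed, {
    rows <- list()
    if (exon_density > 0) {
      mean_gap <- mean_exon_len * (1 - exon_density) / exon_density
      for (i in seq_len(nrow(spec))) {
        len <- spec$length[i]
        # expected number of exon/gap cycles, padded for variability
        n_cyc <- ceiling(len / (mean_exon_len + mean_gap) * 1.5) + 10
        gaps <- stats::rexp(n_cyc, 1 / mean_gap)
        exl <- pmax(1, round(stats::rexp(n_cyc, 1 / mean_exon_len)))
        starts <- cumsum(gaps + c(0, exl[-n_cyc]))
        ends <- starts + exl
        keep <- starts < len
        if (!any(keep)) next
        starts <- floor(starts[keep]); ends <- pmin(ceiling(ends[keep]), len)
        ok <- ends > starts
        if (!any(ok)) next
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = spec$scaffold[i], start = as.integer(starts[ok]),
          end = as.integer(ends[ok]), type = "exon", stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scaffold = character(0), start = integer(0),
                 end = integer(0), type = character(0))
    class(out) <- c("annotation_set", "data.frame")
    out
  })
}

#' Simulate scaffold sequences matching a genome spec
#'
#' IID nucleotides with each scaffold's GC fraction; used for GC-content
#' binning.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A `Biostrings::DNAStringSet` named by scaffold.
#' @export
simulate_sequence <- function(spec, seed = NULL) {
  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(spec)), function(i) {
      gc <- spec$gc[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), spec$length[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- spec$scaffold
    out
  })
}

#' Place motif midpoints with rate-dependent enrichment
#'
#' Motif midpoints are sampled with probability proportional to
#' `1 + (enrichment - 1) * rate / max(rate)` in each rate-track window, so
#' `enrichment = 1` gives uniform placement and large values concentrate
#' motifs in high-recombination regions.
#'
#' @param spec A [genome_spec()].
#' @param rec_track A [rate_track()] (cM/Mb) over the genome.
#' @param enrichment Enrichment factor (>= 1).
#' @param n_motifs Number of motifs to place.
#' @param seed Integer seed.
#' @return A `motif_set`: data frame `scaffold`, `pos` (0-based midpoints).
#' @export
place_motifs <- function(spec, rec_track, enrichment, n_motifs, seed = NULL) {
  stopifnot(enrichment >= 1, n_motifs >= 0)
  if (n_motifs > sum(spec$length)) stop("more motifs than genome positions")
  with_seed(seed, {
    w <- rec_track[rec_track$scaffold %in% spec$scaffold, , drop = FALSE]
    mx <- max(w$rate)
    norm <- if (mx > 0) w$rate / mx else rep(0, nrow(w))
    wt <- (1 + (enrichment - 1) * norm) * (w$end - w$start)
    idx <- sample.int(nrow(w), n_motifs, replace = TRUE, prob = wt)
    off <- floor(stats::runif(n_motifs) * (w$end[idx] - w$start[idx]))
    out <- data.frame(scaffold = w$scaffold[idx],
                      pos = as.integer(w$start[idx] + off),
                      stringsAsFactors = FALSE)
    out <- out[order(out$scaffold, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("motif_set", "data.frame")
    out
  })
}
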