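# Shared fixtures and brute-force oracles, all built in code.

toy_spec <- function(len = 1e5, name = "s1", gc = 0.4) genome_spec(name, len, gc)

# Hand-built panel: haplotypes x sites matrix with explicit positions.
toy_panel <- function(hap, positions, length = max(positions) + 1,
                      scaffold = "s1") {
  structure(list(haplotypes = hap, positions = as.integer(positions),
                 n_hap = nrow(hap), length = length, scaffold = scaffold),
            class = "haplotype_panel")
}

# Brute-force per-site interval membership for mask oracles.
site_in_intervals <- function(sites, df) {
  vapply(sites, function(s) any(s >= df$start & s < df$end), logical(1))
}

# Brute-force composite log-likelihood by direct pair enumeration and manual
# linear interpolation into the lookup table (independent of the package's
# vectorized path).
brute_composite_ll <- function(panel, table, rho_bp, pair_span) {
  H <- panel$haplotypes
  pos <- panel$positions
  S <- length(pos)
  n <- panel$n_hap
  total <- 0
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):min(i + pair_span, S)) {
      n11 <- sum(H[, i] == 1 & H[, j] == 1)
      n10 <- sum(H[, i] == 1 & H[, j] == 0)
      n01 <- sum(H[, i] == 0 & H[, j] == 1)
      n00 <- sum(H[, i] == 0 & H[, j] == 0)
      key <- ayemaps:::fold_config_key(cbind(n00, n01, n10, n11), n)
      row <- match(key, table$keys)
      rho <- rho_bp * (pos[j] - pos[i])
      g <- table$grid
      rho <- min(max(rho, g[1]), g[length(g)])
      k <- findInterval(rho, g, rightmost.closed = TRUE)
      k2 <- min(k + 1, length(g))
      w <- if (k2 == k) 0 else (rho - g[k]) / (g[k2] - g[k])
      total <- total + log(table$prob[row, k] * (1 - w) + table$prob[row, k2] * w)
    }
  }
  total
}

# All permutations of a small vector (exact Kendall oracle).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Run msprime (via the system python) as an independent coalescent oracle:
# returns per-replicate segregating-site counts and mean pairwise r^2 under
# an equilibrium model.
msprime_panel_stats <- function(n_dip, N, mu, rec, L, reps, seed) {
  script <- tempfile(fileext = ".py")
  out_csv <- tempfile(fileext = ".csv")
  writeLines(sprintf('
import msprime, numpy as np
rows = []
for i in range(%d):
    ts = msprime.sim_ancestry(samples=%d, population_size=%d,
                              recombination_rate=%.10g, sequence_length=%d,
                              random_seed=%d + i)
    ts = msprime.sim_mutations(ts, rate=%.10g, random_seed=%d + i,
                               discrete_genome=False)
    G = ts.genotype_matrix()
    S = G.shape[0]
    r2 = np.nan
    if S >= 2:
        vals = []
        for a in range(S - 1):
            for b in range(a + 1, min(a + 31, S)):
                x, y = G[a], G[b]
                if x.std() > 0 and y.std() > 0:
                    vals.append(np.corrcoef(x, y)[0, 1] ** 2)
        if vals:
            r2 = float(np.mean(vals))
    rows.append((S, r2))
with open("%s", "w") as f:
    f.write("S,r2\\n")
    for S, r2 in rows:
        f.write(f"{S},{r2}\\n")
', reps, n_dip, N, rec, L, seed, mu, seed + 100000, out_csv), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  utils::read.csv(out_csv)
}

# Same statistics from the package simulator.
ayemaps_panel_stats <- function(n_dip, N, mu, rec, L, reps, seed) {
  do.call(rbind, lapply(seq_len(reps), function(i) {
    p <- simulate_haplotypes(equilibrium_model(N), mu, rec, 2 * n_dip, L,
                             seed = seed + i)
    G <- t(p$haplotypes)
    S <- nrow(G)
    r2 <- NA_real_
    if (S >= 2) {
      vals <- c()
      for (a in seq_len(S - 1)) {
        for (b in (a + 1):min(a + 30, S)) {
          x <- G[a, ]; y <- G[b, ]
          if (stats::sd(x) > 0 && stats::sd(y) > 0) {
            vals <- c(vals, stats::cor(x, y)^2)
          }
        }
      }
      if (length(vals)) r2 <- mean(vals)
    }
    data.frame(S = S, r2 = r2)
  }))
}
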