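#' Genome specification for synthetic data
#'
#' Scaffold names, lengths and per-scaffold GC base composition used by the
#' synthetic-data generators.
#'
#' @param scaffold Character vector of scaffold names.
#' @param length Integer vector of scaffold lengths (bp), positive.
#' @param gc Numeric vector of per-scaffold GC fractions in `[0, 1]`
#'   (recycled).
#' @return A `genome_spec`: a data frame with columns `scaffold`, `length`,
#'   `gc`.
#' @export
#' @examples
#' genome_spec("scaf1", 5e6, gc = 0.41)
genome_spec <- function(scaffold, length, gc = 0.4) {
  length <- as.numeric(length)
  gc <- rep_len(as.numeric(gc), base::length(scaffold))
  if (any(length <= 0)) stop("scaffold lengths must be positive")
  if (any(gc < 0 | gc > 1)) stop("GC fraction must lie in [0, 1]")
  if (anyDuplicated(scaffold)) stop("duplicate scaffold names")
  structure(
    data.frame(scaffold = as.character(scaffold), length = length, gc = gc,
               stringsAsFactors = FALSE),
    class = c("genome_spec", "data.frame")
  )
}

#' Per-window true rate track
#'
#' Ground-truth rate values (mutations/bp/generation or cM/Mb) on a window
#' grid tiling a scaffold; used to drive the simulators and to assess
#' recovery.
#'
#' @param scaffold Scaffold name (single value or vector).
#' @param start,end Integer window bounds, 0-based half-open; must tile each
#'   scaffold without overlap.
#' @param rate Non-negative numeric rate per window.
#' @param units Unit label, e.g. `"mut/bp/gen"` or `"cM/Mb"`.
#' @return A `rate_track` data frame with columns `scaffold`, `start`, `end`,
#'   `rate`.
#' @export
rate_track <- function(scaffold, start, end, rate, units = "rate") {
  df <- data.frame(scaffold = as.character(scaffold), start = as.numeric(start),
                   end = as.numeric(end), rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start)) stop("invalid window bounds")
  if (any(df$rate < 0)) stop("rates must be non-negative")
  for (s in unique(df$scaffold)) {
    w <- df[df$scaffold == s, ]
    w <- w[order(w$start), ]
    if (nrow(w) > 1 && any(w$start[-1] != w$end[-nrow(w)])) {
      stop("windows must tile the scaffold without gaps or overlap")
    }
  }
  attr(df, "units") <- units
  class(df) <- c("rate_track", "data.frame")
  df
}

#' Uniform rate track covering a genome spec
#'
#' @param spec A [genome_spec()].
#' @param rate Single rate applied everywhere.
#' @param window Window width in bp used for the grid.
#' @param units Unit label.
#' @export
uniform_rate_track <- function(spec, rate, window = 1e6, units = "rate") {
  pieces <- lapply(seq_len(nrow(spec)), function(i) {
    starts <- seq(0, spec$length[i] - 1, by = window)
    data.frame(scaffold = spec$scaffold[i], start = starts,
               end = pmin(starts + window, spec$length[i]),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, pieces)
  rate_track(w$scaffold, w$start, w$end, rep(rate, nrow(w)), units = units)
}

#' Sliding windows over scaffolds
#'
#' Generates 0-based half-open sliding windows; the last window of each
#' scaffold is clipped at the scaffold end and flagged `partial`.
#'
#' @param spec A [genome_spec()] (or data frame with `scaffold`, `length`).
#' @param window Window size in bp.
#' @param step Step size in bp, `step <= window`.
#' @param keep_partial Keep windows clipped by the scaffold end (flagged
#'   `partial`)? Divergence/diversity maps keep them; aggregation to display
#'   windows drops them by default.
#' @return Data frame `scaffold`, `start`, `end`, `partial`.
#' @export
#' @examples
#' sliding_windows(genome_spec("s", 2.5e6), window = 1e6, step = 5e5)
sliding_windows <- function(spec, window, step = window, keep_partial = TRUE) {
  stopifnot(window > 0, step > 0, step <= window)
  pieces <- lapply(seq_len(nrow(spec)), function(i) {
    len <- spec$length[i]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    df <- data.frame(scaffold = spec$scaffold[i], start = starts, end = ends,
                     partial = ends - starts < window, stringsAsFactors = FALSE)
    if (!keep_partial && nrow(df) > 1) df <- df[!df$partial | df$start == 0, ]
    df
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# ---- interval helpers (GRanges-backed) --------------------------------------

# data.frame (scaffold,start,end) [0-based half-open] <-> GRanges [1-based]
df_to_gr <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

gr_to_df <- function(gr) {
  data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

spec_seqlengths <- function(spec) stats::setNames(as.integer(spec$length), spec$scaffold)
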