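#' Piecewise-constant demographic model
#'
#' A demographic history as piecewise-constant diploid effective sizes looking
#' backward in time. Epoch `i` spans `[times[i], times[i+1])` generations
#' before present (the last epoch extends to infinity), during which the
#' diploid effective size is `sizes[i]`.
#'
#' @param sizes Numeric vector of diploid effective population sizes, one per
#'   epoch, all positive.
#' @param times Numeric vector of epoch start times in generations before
#'   present; strictly ascending, first element 0; same length as `sizes`.
#' @return An object of class `demographic_model`.
#' @export
#' @examples
#' demographic_model(sizes = c(1285, 11695), times = c(0, 1133))
demographic_model <- function(sizes, times = 0) {
  sizes <- as.numeric(sizes)
  times <- as.numeric(times)
  if (length(sizes) == 0L) stop("empty demography: at least one epoch required")
  if (length(sizes) != length(times)) {
    stop("`sizes` and `times` must have equal length (one epoch each)")
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) stop("epoch sizes must be positive")
  if (times[1] != 0) stop("first epoch must start at time 0")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("epoch times must be strictly ascending")
  structure(list(sizes = sizes, times = times), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Piecewise-constant demographic model (", length(x$sizes), " epochs)\n", sep = "")
  print(data.frame(start_gen = x$times, diploid_Ne = x$sizes), row.names = FALSE)
  invisible(x)
}

#' Diploid effective size at a time in the past
#'
#' @param model A [demographic_model()].
#' @param t Numeric vector of times (generations before present).
#' @return Numeric vector of diploid sizes.
#' @export
pop_size_at <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"), all(t >= 0))
  model$sizes[findInterval(t, model$times)]
}

#' Constant-size (equilibrium) model
#'
#' @param n Diploid effective size (default 11,695, the inferred ancestral
#'   aye-aye size).
#' @export
equilibrium_model <- function(n = AYE_N_ANCESTRAL) demographic_model(n, 0)

#' Bottleneck-decline model
#'
#' The aye-aye demographic history used for benchmarking: an ancestral
#' population of `n_ancestral` diploids declines at a constant per-generation
#' rate starting `decline_gens` generations ago, reaching `n_present` at
#' present. "Constant rate" is taken as exponential in N (a fixed
#' per-generation multiplicative rate); a linear decline in N is available via
#' `kind = "linear"`. The continuous decline is discretized into `steps`
#' piecewise-constant epochs (geometric-mean size per step for the exponential
#' form, midpoint size for the linear form).
#'
#' @param n_ancestral,n_present Diploid sizes before and after the decline.
#' @param decline_gens Duration of the decline in generations.
#' @param steps Number of piecewise-constant steps used to discretize the
#'   decline.
#' @param kind `"exponential"` (default) or `"linear"` decline in N.
#' @return A [demographic_model()].
#' @export
#' @examples
#' bottleneck_decline_model()
bottleneck_decline_model <- function(n_ancestral = AYE_N_ANCESTRAL,
                                     n_present = AYE_N_PRESENT,
                                     decline_gens = AYE_DECLINE_GENS,
                                     steps = 16,
                                     kind = c("exponential", "linear")) {
  kind <- match.arg(kind)
  stopifnot(n_ancestral > 0, n_present > 0, decline_gens > 0, steps >= 1)
  bounds <- seq(0, decline_gens, length.out = steps + 1)
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  n_at <- function(t) {
    # t in generations before present; N(0) = n_present, N(decline_gens) = n_ancestral
    if (kind == "exponential") {
      n_present * (n_ancestral / n_present)^(t / decline_gens)
    } else {
      n_present + (n_ancestral - n_present) * t / decline_gens
    }
  }
  demographic_model(
    sizes = c(n_at(mid), n_ancestral),
    times = c(bounds[-length(bounds)], decline_gens)
  )
}

# Sample a waiting time from a piecewise-constant hazard.
# breaks: ascending interval end times (last must be Inf); rates: hazard per
# interval, starting at t0. Returns the event time (possibly Inf if total
# integrated hazard is finite and exceeded).
sample_piecewise_exp <- function(t0, breaks, rates) {
  u <- stats::rexp(1)
  t <- t0
  for (i in seq_along(rates)) {
    end <- breaks[i]
    if (rates[i] > 0) {
      cap <- (end - t) * rates[i]
      if (is.infinite(end) || u <= cap) return(t + u / rates[i])
      u <- u - cap
    }
    t <- end
  }
  Inf
}

# Hazard intervals for a coalescence-type rate k(t)/(2N(t)) where k(t) is a
# step function given by (k_times, k_values) and N(t) comes from `model`.
# Returns list(breaks, rates) suitable for sample_piecewise_exp starting at t0.
coal_hazard_pieces <- function(t0, k_times, k_values, model, pair = FALSE) {
  cuts <- sort(unique(c(k_times, model$times)))
  cuts <- cuts[cuts > t0]
  starts <- c(t0, cuts)
  breaks <- c(cuts, Inf)
  k <- k_values[findInterval(starts, k_times)]
  n_t <- model$sizes[findInterval(starts, model$times)]
  rate <- if (pair) k * (k - 1) / 2 / (2 * n_t) else k / (2 * n_t)
  list(breaks = breaks, rates = rate)
}
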