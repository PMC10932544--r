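#' Parameters of the drift-barrier mixture model
#'
#' The model views the splice variants of a genome as a mixture: a small
#' fraction of major-isoform introns produce functional variants with a
#' relatively high AS rate (normal-distributed), while the rest only
#' produce splicing errors whose per-intron rate is gamma-distributed with
#' a low, effective-population-size (Ne)-dependent mean. Two thirds of
#' splicing errors induce frameshifts; functional variants always preserve
#' the reading frame.
#'
#' Defaults: 5% functional introns, functional AS ~ Normal(25%, 5%), error
#' rates ~ Gamma(shape 1) with mean 1.2% (the low-Ne setting; see
#' [drift_barrier_presets()] for the high/medium/low-Ne means 0.2%, 0.6%
#' and 1.2%).
#'
#' @param n_introns Number of major-isoform introns to simulate.
#' @param functional_fraction Fraction of introns with a functional SV.
#' @param functional_mean,functional_sd Mean and sd of the functional AS
#'   rate (fractions).
#' @param error_shape Gamma shape of the error-rate distribution.
#' @param error_mean Mean splicing-error rate (fraction).
#' @param frameshift_fraction_errors Fraction of splicing errors that
#'   disrupt the reading frame.
#' @param as_threshold AS threshold separating low-AS from high-AS introns.
#' @return A validated `model_params` list.
#' @export
model_params <- function(n_introns = 1000000L, functional_fraction = 0.05,
                         functional_mean = 0.25, functional_sd = 0.05,
                         error_shape = 1, error_mean = 0.012,
                         frameshift_fraction_errors = 2 / 3,
                         as_threshold = 0.05) {
  p <- list(n_introns = as.integer(n_introns),
            functional_fraction = functional_fraction,
            functional_mean = functional_mean,
            functional_sd = functional_sd,
            error_shape = error_shape, error_mean = error_mean,
            frameshift_fraction_errors = frameshift_fraction_errors,
            as_threshold = as_threshold)
  fr <- c("functional_fraction", "functional_mean", "functional_sd",
          "error_mean", "frameshift_fraction_errors", "as_threshold")
  bad <- fr[vapply(p[fr], function(x) !is.numeric(x) || x < 0 || x > 1,
                   TRUE)]
  if (length(bad))
    stop("parameter(s) outside [0,1]: ", paste(bad, collapse = ", "))
  if (!is.numeric(p$error_shape) || p$error_shape <= 0)
    stop("error_shape must be > 0")
  if (p$n_introns < 1L) stop("n_introns must be >= 1")
  class(p) <- "model_params"
  p
}

#' Ne presets of the drift-barrier model
#'
#' Mean splicing-error rates for the three hypothetical species: 0.2%
#' (high Ne), 0.6% (medium Ne) and 1.2% (low Ne).
#'
#' @return Named numeric vector `c(high = 0.002, medium = 0.006,
#'   low = 0.012)`.
#' @export
drift_barrier_presets <- function() {
  c(high = 0.002, medium = 0.006, low = 0.012)
}

#' Simulate per-intron AS rates under the drift-barrier model
#'
#' Each intron is functional with probability `functional_fraction`;
#' functional AS rates are drawn from a normal distribution truncated to
#' \[0, 1\] (out-of-range draws are redrawn), error rates from a gamma
#' distribution with the given shape and mean, clamped at 1. Functional
#' variants always preserve the reading frame; errors do so with
#' probability `1 - frameshift_fraction_errors`. At the default parameters
#' both truncations are vanishingly rare.
#'
#' @param params A [model_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with `as_rate`, `is_functional`,
#'   `frame_preserving`.
#' @export
simulate_species <- function(params, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_introns
  func <- runif(n) < params$functional_fraction
  as_rate <- numeric(n)
  nf <- sum(func)
  if (nf) {
    x <- rnorm(nf, params$functional_mean, params$functional_sd)
    while (any(bad <- x < 0 | x > 1)) {
      x[bad] <- rnorm(sum(bad), params$functional_mean,
                      params$functional_sd)
    }
    as_rate[func] <- x
  }
  ne <- n - nf
  if (ne) {
    as_rate[!func] <- pmin(
      rgamma(ne, shape = params$error_shape,
             scale = params$error_mean / params$error_shape), 1)
  }
  frame <- logical(n)
  frame[func] <- TRUE
  frame[!func] <- runif(ne) < 1 - params$frameshift_fraction_errors
  data.frame(as_rate = as_rate, is_functional = func,
             frame_preserving = frame)
}

#' Genome-wide summaries of a simulated species
#'
#' @param sim A data.frame from [simulate_species()].
#' @param threshold AS threshold separating low-AS (`AS <= threshold`) from
#'   high-AS introns (default 0.05).
#' @return A one-row data.frame: `mean_as_all`, `mean_as_low`,
#'   `mean_as_high`, `prop_frame_preserving_high`, `prop_functional_high`
#'   (fields over an empty stratum are `NA`).
#' @export
summarize_model <- function(sim, threshold = 0.05) {
  stopifnot(nrow(sim) > 0)
  hi <- sim$as_rate > threshold
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(
    mean_as_all = mean(sim$as_rate),
    mean_as_low = mean_or_na(sim$as_rate[!hi]),
    mean_as_high = mean_or_na(sim$as_rate[hi]),
    prop_frame_preserving_high = mean_or_na(sim$frame_preserving[hi]),
    prop_functional_high = mean_or_na(sim$is_functional[hi]))
}

#' Closed-form expectations of the drift-barrier model
#'
#' Computes the [summarize_model()] fields from mixture integrals (normal
#' and gamma distribution functions) instead of sampling, including the
#' truncation of the functional component to \[0, 1\] and the clamp of the
#' error component at 1. Serves as the independent oracle for the
#' simulator.
#'
#' @param params A [model_params()] object.
#' @param threshold AS threshold (default `params$as_threshold`).
#' @return A one-row data.frame with the same fields as
#'   [summarize_model()].
#' @export
analytic_expectations <- function(params, threshold = params$as_threshold) {
  stopifnot(inherits(params, "model_params"))
  f <- params$functional_fraction
  mu <- params$functional_mean
  sg <- params$functional_sd
  k <- params$error_shape
  th <- params$error_mean / k

  # truncated normal on [0,1]: probabilities and partial expectations
  z <- function(x) (x - mu) / sg
  Zn <- pnorm(z(1)) - pnorm(z(0))
  p_f <- function(a, b) (pnorm(z(b)) - pnorm(z(a))) / Zn
  e_f <- function(a, b) {
    (mu * (pnorm(z(b)) - pnorm(z(a))) +
       sg * (dnorm(z(a)) - dnorm(z(b)))) / Zn
  }
  # gamma clamped at 1: P(E <= t) and E[E ; E <= t] for t in [0,1]
  p_e <- function(t) if (t >= 1) 1 else pgamma(t, k, scale = th)
  e_e <- function(t) {
    # E[min(G,1) ; min(G,1) <= t]
    if (t >= 1) {
      params$error_mean * pgamma(1, k + 1, scale = th) +
        (1 - pgamma(1, k, scale = th))
    } else {
      params$error_mean * pgamma(t, k + 1, scale = th)
    }
  }
  t <- threshold
  p_low <- f * p_f(0, t) + (1 - f) * p_e(t)
  p_high <- f * p_f(t, 1) + (1 - f) * (1 - p_e(t))
  mean_all <- f * e_f(0, 1) + (1 - f) * e_e(1)
  mean_low <- if (p_low > 0)
    (f * e_f(0, t) + (1 - f) * e_e(t)) / p_low else NA_real_
  mean_high <- if (p_high > 0)
    (f * (e_f(0, 1) - e_f(0, t)) + (1 - f) * (e_e(1) - e_e(t))) / p_high
  else NA_real_
  w <- if (p_high > 0) f * p_f(t, 1) / p_high else NA_real_
  data.frame(
    mean_as_all = mean_all,
    mean_as_low = mean_low,
    mean_as_high = mean_high,
    prop_frame_preserving_high =
      w + (1 - w) * (1 - params$frameshift_fraction_errors),
    prop_functional_high = w)
}
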