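#' Simulation parameters for the birth-death rate-evolution process
#'
#' Bundles every constant of the forward-time simulation: the starting
#' speciation and substitution rates, the (constant) extinction rate, the
#' rate-update event rate `q`, the instantaneous variance-covariance matrix
#' of the joint Brownian motion of the two rates, and the target number of
#' extant tips used by the Generalised Sampling Approach.
#'
#' Defaults are a bird-like parameterisation calibrated so that simulated
#' 75-tip trees have a mean crown (root) age of about 28.4 My and a mean
#' within-tree range of log speciation rates at the tips of about 0.44
#' (see the package vignette for the calibration protocol).
#'
#' Rates evolve by Brownian motion on the log scale by default, which keeps
#' them strictly positive.  `rate_scale = "natural"` switches to additive
#' increments on the natural scale with reflection at `rate_floor`.
#'
#' @param lambda0 initial speciation rate, events/lineage/My.
#' @param r0 initial substitution rate, substitutions/site/My.
#' @param mu extinction rate, events/lineage/My; constant over the tree.
#' @param q rate-update (jump) event rate, events/lineage/My.  Large `q`
#'   approximates continuous Brownian motion; summary statistics are
#'   insensitive to `q` above about 10.
#' @param sigma2_lambda instantaneous variance of speciation-rate evolution
#'   (per My, on the scale set by `rate_scale`).
#' @param sigma2_r instantaneous variance of substitution-rate evolution.
#' @param rho correlation coefficient between the speciation-rate and
#'   substitution-rate increments; the increment covariance is
#'   `rho * sqrt(sigma2_lambda * sigma2_r)`.
#' @param cov_lr optional increment covariance; if supplied, `rho` is
#'   derived from it (convenient for quoting the covariance directly, e.g.
#'   0.0044 for the Continuous model).
#' @param n_tips target number of extant tips for conditioning.
#' @param rate_scale `"log"` (default) or `"natural"`.
#' @param rate_floor reflection floor for `rate_scale = "natural"`.
#'
#' @return An object of class `sim_params`.
#' @seealso [model_params()] for the three named model presets,
#'   [simulate_time_tree()] for the simulator.
#' @export
sim_params <- function(lambda0 = 0.224, r0 = 0.01, mu = lambda0 / 2, q = 50,
                       sigma2_lambda = 4.9e-4, sigma2_r = 0.04,
                       rho = 0, cov_lr = NULL,
                       n_tips = 75,
                       rate_scale = c("log", "natural"),
                       rate_floor = 1e-8) {
  rate_scale <- match.arg(rate_scale)
  if (!is.null(cov_lr)) {
    denom <- sqrt(sigma2_lambda * sigma2_r)
    if (denom <= 0 && cov_lr != 0)
      stop("cov_lr requires positive sigma2_lambda and sigma2_r")
    rho <- if (denom > 0) cov_lr / denom else 0
  }
  stopifnot(
    "lambda0 must be > 0" = is.numeric(lambda0) && lambda0 > 0,
    "r0 must be > 0" = is.numeric(r0) && r0 > 0,
    "mu must be >= 0" = is.numeric(mu) && mu >= 0,
    "q must be > 0" = is.numeric(q) && q > 0,
    "sigma2_lambda must be >= 0" = sigma2_lambda >= 0,
    "sigma2_r must be >= 0" = sigma2_r >= 0,
    "rho must lie in [-1, 1]" = is.numeric(rho) && rho >= -1 && rho <= 1,
    "n_tips must be >= 2" = n_tips >= 2
  )
  structure(
    list(lambda0 = lambda0, r0 = r0, mu = mu, q = q,
         sigma2_lambda = sigma2_lambda, sigma2_r = sigma2_r, rho = rho,
         n_tips = as.integer(n_tips),
         rate_scale = rate_scale, rate_floor = rate_floor),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", x$rate_scale, "-scale rate evolution)\n",
      sep = "")
  cat(sprintf("  lambda0 = %g /lineage/My, mu = %g, q = %g\n",
              x$lambda0, x$mu, x$q))
  cat(sprintf("  r0 = %g subs/site/My\n", x$r0))
  cat(sprintf("  sigma2_lambda = %g, sigma2_r = %g, rho = %g (Cov = %g)\n",
              x$sigma2_lambda, x$sigma2_r, x$rho,
              x$rho * sqrt(x$sigma2_lambda * x$sigma2_r)))
  cat(sprintf("  n_tips = %d\n", x$n_tips))
  invisible(x)
}

#' Instantaneous variance-covariance matrix of the rate increments
#'
#' @param params a [sim_params()] object.
#' @return 2x2 matrix `[[sigma2_lambda, cov], [cov, sigma2_r]]` with
#'   `cov = rho * sqrt(sigma2_lambda * sigma2_r)`.
#' @export
sigma_matrix <- function(params) {
  cv <- params$rho * sqrt(params$sigma2_lambda * params$sigma2_r)
  matrix(c(params$sigma2_lambda, cv, cv, params$sigma2_r), 2L, 2L,
         dimnames = list(c("lambda", "r"), c("lambda", "r")))
}

#' Named model presets: Unlinked, Continuous, Punctuated
#'
#' The three models share every parameter except the increment covariance:
#' Unlinked and Punctuated use covariance 0, Continuous uses 0.0044.  The
#' Punctuated model additionally adds substitution bursts at speciation
#' events (see [burst_config()]); the preset here only fixes the
#' rate-evolution parameters.
#'
#' @param model one of `"unlinked"`, `"continuous"`, `"punctuated"`.
#' @param ... overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
model_params <- function(model = c("unlinked", "continuous", "punctuated"),
                         ...) {
  model <- match.arg(model)
  if (model == "continuous") sim_params(cov_lr = 0.0044, ...)
  else sim_params(rho = 0, ...)
}

#' Configuration of punctuated substitution bursts
#'
#' Per tree, the fraction of total tree length (in substitutions/site)
#' contributed by node-associated bursts is drawn from a normal
#' distribution truncated to (0, 1); per speciation event and daughter
#' lineage, a raw burst magnitude is drawn i.i.d. from `family` and all
#' bursts are then rescaled by a common factor so the realized burst share
#' of the pruned tree equals the drawn fraction exactly.
#'
#' @param mean_fraction mean per-tree burst fraction of tree length.
#' @param sd_fraction between-tree standard deviation of the fraction.
#' @param family raw per-event burst distribution: `"exponential"`
#'   (default) or `"fixed"` (all bursts equal before rescaling).
#' @param rate rate parameter of the exponential family (immaterial after
#'   rescaling; kept for completeness).
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(mean_fraction = 0.16, sd_fraction = 0.054,
                         family = c("exponential", "fixed"), rate = 1) {
  family <- match.arg(family)
  stopifnot(
    "mean_fraction must be in (0, 1)" =
      mean_fraction > 0 && mean_fraction < 1,
    "sd_fraction must be >= 0" = sd_fraction >= 0,
    "rate must be > 0" = rate > 0
  )
  structure(list(mean_fraction = mean_fraction, sd_fraction = sd_fraction,
                 family = family, rate = rate),
            class = "burst_config")
}

#' Nucleotide substitution model for sequence simulation
#'
#' A general time-reversible (GTR) model with discrete-gamma among-site
#' rate variation and no invariant-site class.  Defaults are a synthetic
#' bird-mitochondrial-like parameterisation: strongly unequal base
#' frequencies, transition/transversion bias, and substantial among-site
#' rate heterogeneity (gamma shape 0.30 with 4 categories).
#'
#' @param base_freq base frequencies (A, C, G, T); must sum to 1.
#' @param rates the six GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param gamma_shape shape of the gamma distribution of site rates.
#' @param n_categories number of discrete gamma categories.
#' @param length alignment length in sites.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(base_freq = c(A = 0.31, C = 0.30, G = 0.12, T = 0.27),
                        rates = c(ac = 0.9, ag = 12, at = 0.9,
                                  cg = 0.6, ct = 14, gt = 1),
                        gamma_shape = 0.30, n_categories = 4L,
                        length = 2000L) {
  stopifnot(
    "base_freq must have 4 elements summing to 1" =
      length(base_freq) == 4L && abs(sum(base_freq) - 1) < 1e-8,
    "rates must have 6 positive elements" =
      length(rates) == 6L && all(rates > 0),
    "gamma_shape must be > 0" = gamma_shape > 0,
    "n_categories must be >= 1" = n_categories >= 1,
    "length must be >= 1" = length >= 1
  )
  structure(list(base_freq = base_freq, rates = rates,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 length = as.integer(length)),
            class = "subst_model")
}
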