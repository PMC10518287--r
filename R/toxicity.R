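#' Power-law toxicity rate
#'
#' First-order viability decay rate at CPA concentration C:
#' \eqn{k = \beta C^\alpha} per minute, C in mol/L.
#'
#' @param C CPA concentration, M (vectorised).
#' @param tox A [toxicity_params()].
#' @return Rate, 1/min.
#' @export
toxicity_rate <- function(C, tox = toxicity_params()) {
  if (any(C < 0)) stop("concentration must be non-negative")
  tox$beta * C^tox$alpha
}

#' Cumulative toxicity cost of a concentration time course
#'
#' Trapezoidal integral of the toxicity rate over the exposure:
#' \eqn{J_{tox} = \int \beta C(t)^\alpha dt} with t in minutes and C in M.
#' Predicted viability after the exposure is `exp(-J_tox)`.
#'
#' @param time_min Increasing time grid, min.
#' @param conc_M CPA concentration at each time, M.
#' @param tox A [toxicity_params()].
#' @return Dimensionless cumulative cost.
#' @export
toxicity_cost <- function(time_min, conc_M, tox = toxicity_params()) {
  stopifnot(length(time_min) == length(conc_M))
  if (any(diff(time_min) <= 0)) stop("time must be increasing")
  if (any(conc_M < 0)) stop("concentration must be non-negative")
  J <- .cum_trapz_cost(time_min, conc_M, tox)
  J[length(J)]
}

#' Viability predicted from a toxicity cost
#'
#' @param J_tox Cumulative toxicity cost, >= 0.
#' @return Surviving fraction `exp(-J_tox)`.
#' @export
viability_from_cost <- function(J_tox) {
  if (any(J_tox < 0)) stop("J_tox must be non-negative")
  exp(-J_tox)
}

#' Characteristic diffusion time of a slice
#'
#' \eqn{t_{char} = l^2 / (2D)}: the time scale for a solute with
#' diffusivity D to penetrate a slab of half-thickness l, used to size the
#' step-equilibration intervals of the slice assay.
#'
#' @param l Characteristic length (slice half-thickness), m.
#' @param D Diffusivity, m^2/s.
#' @return Time, s.
#' @export
characteristic_diffusion_time <- function(l, D) {
  if (any(l < 0)) stop("length must be non-negative")
  if (any(D <= 0)) stop("diffusivity must be positive")
  l^2 / (2 * D)
}

#' Slice viability dataset
#'
#' Replicated viabilities of tissue slices after timed exposures to a grid
#' of CPA concentrations, normalised to untreated controls.
#'
#' @param concentration_M Exposure concentration, M.
#' @param time_min Exposure duration, min.
#' @param replicate Replicate identifier.
#' @param viability Fraction of control, >= 0.
#' @return An object of class `slice_dataset`.
#' @export
slice_dataset <- function(concentration_M, time_min, replicate, viability) {
  n <- length(concentration_M)
  stopifnot(length(time_min) == n, length(replicate) == n,
            length(viability) == n)
  if (any(viability < 0)) stop("viability must be non-negative")
  d <- data.frame(concentration_M = concentration_M, time_min = time_min,
                  replicate = replicate, viability = viability)
  cnt <- tapply(d$time_min, d$concentration_M,
                function(x) length(unique(x)))
  if (any(cnt < 2))
    stop("need at least 2 exposure times per concentration")
  structure(d, class = c("slice_dataset", "data.frame"))
}

#' Per-concentration toxicity rates from slice viabilities
#'
#' For each concentration, pools replicates and fits the exponential decay
#' \eqn{\ln(\mathrm{viability}) = -k t} through the origin (controls define
#' viability 1 at t = 0) by least squares. Non-positive viabilities cannot
#' be log-transformed and are excluded with a warning.
#'
#' @param data A [slice_dataset()].
#' @param fit Either `"loglinear"` (default, zero-intercept fit of
#'   log-viability) or `"exponential"` (nonlinear least squares on the
#'   viability scale; differs only under noise).
#' @return A data frame with `concentration_M`, `k` (1/min), `r_squared`.
#' @export
fit_k_per_concentration <- function(data, fit = c("loglinear", "exponential")) {
  stopifnot(inherits(data, "slice_dataset"))
  fit <- match.arg(fit)
  bad <- data$viability <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive viabilities", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no usable viabilities remain")
  res <- lapply(split(data, data$concentration_M), function(d) {
    if (fit == "loglinear") {
      ly <- log(d$viability)
      k <- -sum(ly * d$time_min) / sum(d$time_min^2)
      pred <- -k * d$time_min
      ss_res <- sum((ly - pred)^2)
      ss_tot <- sum((ly - mean(ly))^2)
      r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
      n <- length(ly)
      se_k <- if (n > 1) sqrt(ss_res / (n - 1) / sum(d$time_min^2)) else
        NA_real_
    } else {
      nl <- stats::nls(viability ~ exp(-k * time_min), data = d,
                       start = list(k = 1e-3),
                       lower = 0, algorithm = "port")
      k <- stats::coef(nl)[[1L]]
      pred <- exp(-k * d$time_min)
      ss_tot <- sum((d$viability - mean(d$viability))^2)
      r2 <- if (ss_tot == 0) NA_real_ else
        1 - sum((d$viability - pred)^2) / ss_tot
      se_k <- tryCatch(summary(nl)$coefficients[1L, 2L],
                       error = function(e) NA_real_)
    }
    data.frame(concentration_M = d$concentration_M[1L], k = k,
               r_squared = r2, se_k = se_k)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Power-law fit of toxicity rate against concentration
#'
#' Linear regression of log k on log C: the slope is the exponent alpha and
#' the intercept exponentiates to the prefactor beta. Non-positive rates
#' are excluded with a warning.
#'
#' By default the regression is precision-weighted when the rate table
#' carries standard errors (`se_k`, as produced by
#' [fit_k_per_concentration()]): weights are the inverse variances of
#' log k, i.e. (k/se_k)^2. This matters because rates at low
#' concentrations are often dominated by assay noise (viabilities near 1),
#' and on the log scale such a rate can be arbitrarily wrong; weighting
#' keeps it from distorting the exponent. With exact rates all weights are
#' equal and the fit reduces to ordinary least squares.
#'
#' @param rates Data frame with `concentration_M`, `k` and optionally
#'   `se_k`, e.g. from [fit_k_per_concentration()].
#' @param weights `"precision"` (default) or `"equal"`.
#' @return A [toxicity_params()] with the fit's `r_squared` as an
#'   attribute.
#' @examples
#' rates <- data.frame(concentration_M = c(2.1, 4.2, 6.3, 8.4),
#'                     k = 9.39e-6 * c(2.1, 4.2, 6.3, 8.4)^3.12)
#' fit_alpha_beta(rates)   # recovers alpha = 3.12, beta = 9.39e-6
#' @export
fit_alpha_beta <- function(rates, weights = c("precision", "equal")) {
  stopifnot(all(c("concentration_M", "k") %in% names(rates)))
  weights <- match.arg(weights)
  bad <- rates$k <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive rates", sum(bad)))
    rates <- rates[!bad, , drop = FALSE]
  }
  if (nrow(rates) < 2) stop("need at least 2 concentrations with k > 0")
  w <- rep(1, nrow(rates))
  if (weights == "precision" && "se_k" %in% names(rates)) {
    se_ln <- rates$se_k / rates$k
    if (all(is.finite(se_ln)) && all(se_ln > 0)) w <- 1 / se_ln^2
  }
  fit <- stats::lm(log(k) ~ log(concentration_M), data = rates,
                   weights = w)
  cf <- stats::coef(fit)
  ss_tot <- sum((log(rates$k) - mean(log(rates$k)))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / ss_tot
  out <- toxicity_params(alpha = cf[[2L]], beta = exp(cf[[1L]]))
  attr(out, "r_squared") <- r2
  out
}
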