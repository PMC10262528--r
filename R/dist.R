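#' @importFrom flexsurv dgengamma.orig pgengamma.orig qgengamma.orig
NULL

FAMILIES <- c("lognormal", "gamma", "weibull", "gengamma")

# Number of free parameters per family (used for parsimony tie-breaks).
family_npar <- c(lognormal = 2L, gamma = 2L, weibull = 2L, gengamma = 3L)

# Density / CDF / quantile dispatchers. The generalised gamma uses the Stacy
# parameterisation f(x) = (p / a^d) x^(d-1) exp(-(x/a)^p) / Gamma(d/p) with
# scale a > 0, shape d > 0, power p > 0; p = 1 recovers the gamma
# distribution and d = p the Weibull (flexsurv's "orig" family with
# shape = p, scale = a, k = d/p is this density).
dist_pdf <- function(x, family, params, log = FALSE) {
  switch(family,
    lognormal = stats::dlnorm(x, params[["meanlog"]], params[["sdlog"]], log = log),
    gamma     = stats::dgamma(x, shape = params[["shape"]], rate = params[["rate"]], log = log),
    weibull   = stats::dweibull(x, shape = params[["shape"]], scale = params[["scale"]], log = log),
    gengamma  = flexsurv::dgengamma.orig(x, shape = params[["p"]],
                                         scale = params[["a"]],
                                         k = params[["d"]] / params[["p"]], log = log))
}

dist_cdf <- function(q, family, params) {
  switch(family,
    lognormal = stats::plnorm(q, params[["meanlog"]], params[["sdlog"]]),
    gamma     = stats::pgamma(q, shape = params[["shape"]], rate = params[["rate"]]),
    weibull   = stats::pweibull(q, shape = params[["shape"]], scale = params[["scale"]]),
    gengamma  = flexsurv::pgengamma.orig(q, shape = params[["p"]],
                                         scale = params[["a"]],
                                         k = params[["d"]] / params[["p"]]))
}

dist_quantile <- function(prob, family, params) {
  switch(family,
    lognormal = stats::qlnorm(prob, params[["meanlog"]], params[["sdlog"]]),
    gamma     = stats::qgamma(prob, shape = params[["shape"]], rate = params[["rate"]]),
    weibull   = stats::qweibull(prob, shape = params[["shape"]], scale = params[["scale"]]),
    gengamma  = flexsurv::qgengamma.orig(prob, shape = params[["p"]],
                                         scale = params[["a"]],
                                         k = params[["d"]] / params[["p"]]))
}

gengamma_loglik <- function(theta, x) {
  # theta on log scale: (log a, log d, log p)
  a <- exp(theta[1]); d <- exp(theta[2]); p <- exp(theta[3])
  ll <- sum(flexsurv::dgengamma.orig(x, shape = p, scale = a, k = d / p, log = TRUE))
  if (!is.finite(ll)) return(-1e12)
  ll
}

# Moment-matched and nested-family starting values for the gengamma MLE.
# Including the fitted gamma (p = 1) and Weibull (d = p) solutions as starts
# guarantees the maximized log-likelihood is at least theirs.
gengamma_starts <- function(x, gamma_fit = NULL, weibull_fit = NULL) {
  m <- mean(x); v <- stats::var(x)
  g_shape <- m^2 / v; g_scale <- v / m
  starts <- list(
    c(log(g_scale), log(g_shape), log(1)),          # moment-matched gamma
    c(log(g_scale), log(g_shape), log(0.7)),
    c(log(g_scale), log(g_shape), log(1.5)),
    c(log(m), log(1.3), log(1.3))                   # near-Weibull
  )
  if (!is.null(gamma_fit)) {
    starts <- c(starts, list(c(-log(gamma_fit$params[["rate"]]),
                               log(gamma_fit$params[["shape"]]), 0)))
  }
  if (!is.null(weibull_fit)) {
    sh <- weibull_fit$params[["shape"]]
    starts <- c(starts, list(c(log(weibull_fit$params[["scale"]]), log(sh), log(sh))))
  }
  starts
}

fit_one_family <- function(x, family) {
  if (family == "lognormal") {
    f <- fitdistrplus::fitdist(x, "lnorm", method = "mle")
    params <- c(meanlog = unname(f$estimate["meanlog"]),
                sdlog = unname(f$estimate["sdlog"]))
    return(list(params = params, loglik = f$loglik, converged = TRUE))
  }
  if (family == "gamma") {
    f <- fitdistrplus::fitdist(x, "gamma", method = "mle",
                               start = list(shape = mean(x)^2 / stats::var(x),
                                            rate = mean(x) / stats::var(x)))
    return(list(params = c(shape = unname(f$estimate["shape"]),
                           rate = unname(f$estimate["rate"])),
                loglik = f$loglik, converged = TRUE))
  }
  if (family == "weibull") {
    f <- fitdistrplus::fitdist(x, "weibull", method = "mle")
    return(list(params = c(shape = unname(f$estimate["shape"]),
                           scale = unname(f$estimate["scale"])),
                loglik = f$loglik, converged = TRUE))
  }
  # gengamma: multi-start BFGS on log-parameters
  gamma_fit <- tryCatch(fit_one_family(x, "gamma"), error = function(e) NULL)
  weib_fit <- tryCatch(fit_one_family(x, "weibull"), error = function(e) NULL)
  best <- NULL
  for (s in gengamma_starts(x, gamma_fit, weib_fit)) {
    o <- tryCatch(
      stats::optim(s, gengamma_loglik, x = x, method = "BFGS",
                   control = list(fnscale = -1, reltol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    # the start itself stays a candidate, so the nested-family log-likelihoods
    # (gamma at p = 1, Weibull at d = p) are lower bounds by construction
    v0 <- gengamma_loglik(s, x)
    if (is.null(o) || o$value < v0) o <- list(par = s, value = v0, convergence = 0L)
    if (is.null(best) || o$value > best$value) best <- o
  }
  if (is.null(best)) {
    stop_frailty("generalised gamma fit failed to converge from any start",
                 class = "fit_error")
  }
  list(params = c(a = exp(best$par[1]), d = exp(best$par[2]), p = exp(best$par[3])),
       loglik = best$value, converged = best$convergence == 0)
}

#' Fit a parametric distribution to a frailty-index sample
#'
#' Maximum-likelihood fit of one of four positive-support families:
#' lognormal, gamma, Weibull, or the three-parameter generalised gamma in
#' Stacy form, `f(x) = (p / a^d) x^(d-1) exp(-(x/a)^p) / Gamma(d/p)`, which
#' nests the gamma (`p = 1`), the Weibull (`d = p`) and, as a limit, the
#' lognormal. The generalised-gamma optimizer is multi-start (moment-matched
#' plus the fitted gamma and Weibull solutions), so its log-likelihood is
#' never below its nested members'. Exact zeros, which a frailty index can
#' produce, are shifted to `1 / (2 * n_deficits)` before fitting (half the
#' smallest attainable positive FI).
#'
#' @param x Numeric sample on the non-negative half-line, typically FI
#'   values in \[0, 1\] (or an `fi_table`).
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`, `"gengamma"`.
#' @param n_deficits Number of deficits in the index, used for the zero
#'   shift; required only when the sample contains zeros and `zero_shift` is
#'   not given.
#' @param zero_shift Value replacing exact zeros (overrides `n_deficits`).
#' @return Object of class `fi_distfit`: `family`, `params` (named, all
#'   positive), `loglik`, `n`, `ks` (Kolmogorov-Smirnov D against the fitted
#'   CDF), `converged`.
#' @export
fit_fi_distribution <- function(x, family = c("gengamma", "lognormal", "gamma", "weibull"),
                                n_deficits = NULL, zero_shift = NULL) {
  family <- match.arg(family)
  if (is.data.frame(x)) x <- x$fi[!x$excluded]
  x <- x[!is.na(x)]
  if (length(x) < 30) {
    stop_frailty("need at least 30 observations to fit (got %d)", length(x),
                 class = "fit_error")
  }
  if (stats::sd(x) == 0) {
    stop_frailty("degenerate (constant) sample; nothing to fit", class = "fit_error")
  }
  if (any(x < 0)) {
    stop_frailty("sample values must be non-negative", class = "domain_error")
  }
  if (any(x == 0)) {
    if (is.null(zero_shift)) {
      if (is.null(n_deficits)) {
        stop_frailty("sample contains zeros: supply n_deficits (or zero_shift) for the positive-support shift",
                     class = "fit_error")
      }
      zero_shift <- 1 / (2 * n_deficits)
    }
    x[x == 0] <- zero_shift
  }
  f <- fit_one_family(x, family)
  if (!f$converged) {
    stop_frailty("%s fit did not converge", family, class = "fit_error")
  }
  # scale/shape parameters must be positive; the lognormal meanlog is a
  # log-scale location and may be negative
  positive <- setdiff(names(f$params), "meanlog")
  if (any(f$params[positive] <= 0)) {
    stop_frailty("%s fit produced non-positive parameters", family, class = "fit_error")
  }
  out <- structure(
    list(family = family, params = f$params, loglik = f$loglik,
         n = length(x), converged = f$converged, ks = NA_real_),
    class = "fi_distfit")
  out$ks <- ks_statistic(x, out)
  out
}

#' @export
print.fi_distfit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s\n", x$family, x$n,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", ")))
  cat(sprintf("  logLik %.2f, KS D = %.4f\n", x$loglik, x$ks))
  invisible(x)
}

#' @export
logLik.fi_distfit <- function(object, ...) {
  structure(object$loglik, df = family_npar[[object$family]],
            nobs = object$n, class = "logLik")
}

#' @export
coef.fi_distfit <- function(object, ...) object$params

#' Quantile of a fitted distribution
#' @param x An `fi_distfit`.
#' @param probs Probabilities.
#' @param ... Unused.
#' @return Quantiles (inverse CDF) at `probs`.
#' @export
quantile.fi_distfit <- function(x, probs = 0.99, ...) {
  dist_quantile(probs, x$family, x$params)
}

#' CDF of a fitted distribution
#' @param fitted An `fi_distfit`.
#' @param q Evaluation points.
#' @return `P(X <= q)` under the fitted distribution.
#' @export
cdf_fi_distribution <- function(fitted, q) {
  dist_cdf(q, fitted$family, fitted$params)
}

#' Kolmogorov-Smirnov statistic of a sample against a fitted distribution
#'
#' `D = sup_x |ECDF(x) - F(x)|`, evaluated using both one-sided ECDF limits
#' at each sample point. Used here as a relative goodness-of-fit measure for
#' comparing candidate families; no p-value is attached (parameters are
#' estimated from the same sample, so the classical null distribution does
#' not apply).
#'
#' @param x Numeric sample.
#' @param fitted An `fi_distfit` (or a function computing the CDF).
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(x, fitted) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  Fx <- if (is.function(fitted)) fitted(x) else dist_cdf(x, fitted$family, fitted$params)
  d_plus <- max(seq_len(n) / n - Fx)
  d_minus <- max(Fx - (seq_len(n) - 1) / n)
  max(d_plus, d_minus)
}

#' Fit several families and select the best by KS statistic
#'
#' Fits each requested family and returns them all together with the family
#' attaining the smallest KS D; ties (within `tie_tol`) are broken toward the
#' family with fewer parameters.
#'
#' @inheritParams fit_fi_distribution
#' @param families Families to fit (default all four).
#' @param tie_tol KS difference treated as a tie (default 1e-3).
#' @return List of class `fi_distfit_selection`: `fits` (named list),
#'   `best` (family name), `ks` (named D values), `failed` (named error
#'   messages for families that failed to fit).
#' @export
select_best_fit <- function(x, families = FAMILIES, n_deficits = NULL,
                            zero_shift = NULL, tie_tol = 1e-3) {
  fits <- list(); failed <- character()
  for (fam in families) {
    f <- tryCatch(
      fit_fi_distribution(x, fam, n_deficits = n_deficits, zero_shift = zero_shift),
      error = function(e) e)
    if (inherits(f, "error")) failed[fam] <- conditionMessage(f) else fits[[fam]] <- f
  }
  if (length(fits) == 0) {
    stop_frailty("all distribution fits failed: %s",
                 paste(sprintf("%s (%s)", names(failed), failed), collapse = "; "),
                 class = "fit_error")
  }
  ks <- vapply(fits, `[[`, numeric(1), "ks")
  best_ks <- min(ks)
  candidates <- names(ks)[ks <= best_ks + tie_tol]
  best <- candidates[which.min(family_npar[candidates])]
  structure(list(fits = fits, best = best, ks = ks, failed = failed),
            class = "fi_distfit_selection")
}

#' @export
print.fi_distfit_selection <- function(x, ...) {
  cat("Distribution fit comparison (KS D):\n")
  for (fam in names(x$ks)) {
    cat(sprintf("  %-10s D = %.4f  logLik = %.2f%s\n", fam, x$ks[[fam]],
                x$fits[[fam]]$loglik, if (fam == x$best) "  <- selected" else ""))
  }
  invisible(x)
}

#' Model-based summary of a fitted FI distribution
#'
#' The exportable, individual-data-free summary of an FI sample: category
#' prevalences obtained as CDF differences over the category intervals and an
#' upper centile from the inverse CDF. The quantile is verified against the
#' CDF (`CDF(quantile(q)) = q` to 1e-8).
#'
#' @param fitted An `fi_distfit`.
#' @param boundaries Category cut-points (default `c(0.12, 0.24, 0.36)`).
#' @param q Upper centile (default 0.99).
#' @return List of class `fi_dist_summary`: `family`, `params`, `prevalence`
#'   (percent over robust/mild/moderate/severe, the severe class absorbing
#'   all mass above the last boundary), `quantile` (the q-th centile),
#'   `mass_above_1` (model mass beyond the FI upper bound, a model-adequacy
#'   diagnostic).
#' @export
model_summary <- function(fitted, boundaries = c(0.12, 0.24, 0.36), q = 0.99) {
  stopifnot(inherits(fitted, "fi_distfit"))
  edges <- c(0, boundaries)
  cdf_vals <- dist_cdf(edges, fitted$family, fitted$params)
  prev <- 100 * c(diff(cdf_vals), 1 - cdf_vals[length(cdf_vals)])
  names(prev) <- c("robust", "mild", "moderate", "severe")
  qq <- dist_quantile(q, fitted$family, fitted$params)
  roundtrip <- dist_cdf(qq, fitted$family, fitted$params)
  if (abs(roundtrip - q) > 1e-8) {
    stop_frailty("quantile/CDF inverse identity violated: CDF(q%.0f) = %.10f",
                 100 * q, roundtrip, class = "fit_error")
  }
  structure(
    list(family = fitted$family, params = fitted$params, prevalence = prev,
         quantile = qq, q = q,
         mass_above_1 = 1 - dist_cdf(1, fitted$family, fitted$params)),
    class = "fi_dist_summary")
}

#' @export
print.fi_dist_summary <- function(x, ...) {
  cat(sprintf("Model-based FI summary (%s):\n", x$family))
  cat(sprintf("  %.0fth centile %.3f; robust %.1f%% | mild %.1f%% | moderate %.1f%% | severe %.1f%%\n",
              100 * x$q, x$quantile, x$prevalence["robust"], x$prevalence["mild"],
              x$prevalence["moderate"], x$prevalence["severe"]))
  invisible(x)
}
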