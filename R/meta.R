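#' Random-effects pooling of per-trial coefficients
#'
#' DerSimonian-Laird random-effects meta-analysis of log-scale coefficients
#' (log IRR or log OR per 0.1-unit FI) and their standard errors:
#' fixed-effect weights `w_i = 1/se_i^2` give the heterogeneity statistic
#' `Q = sum w_i (b_i - b_FE)^2`; the between-trial variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; pooling then
#' uses `w*_i = 1/(se_i^2 + tau2)` with a normal-quantile 95% CI. Computed
#' via `metafor::rma.uni(method = "DL")`.
#'
#' @param beta Numeric vector of per-trial log-scale coefficients.
#' @param se Matching standard errors (all > 0).
#' @param trial Optional trial labels.
#' @param method `"DL"` (default, the tested path) or `"REML"`.
#' @return Object of class `fi_meta`: `beta`, `se`, `ci95`, `effect`
#'   (`exp(beta)`), `tau2`, `Q`, `I2` (percent), `k`, and `studies` (a data
#'   frame with per-trial estimates and random-effects weights in percent).
#' @export
pool_random_effects <- function(beta, se, trial = NULL, method = c("DL", "REML")) {
  method <- match.arg(method)
  if (length(beta) == 0) {
    stop_frailty("no estimates to pool", class = "meta_error")
  }
  if (length(se) != length(beta) || any(!is.finite(se)) || any(se <= 0)) {
    stop_frailty("standard errors must be positive and match beta in length",
                 class = "meta_error")
  }
  trial <- trial %||% paste0("trial_", seq_along(beta))
  m <- metafor::rma.uni(yi = beta, sei = se, method = method)
  pooled_b <- as.numeric(stats::coef(m))
  pooled_se <- m$se
  w <- 1 / (se^2 + m$tau2)
  studies <- data.frame(
    trial = trial, beta = beta, se = se, effect = exp(beta),
    ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    weight = 100 * w / sum(w), stringsAsFactors = FALSE)
  structure(
    list(beta = pooled_b, se = pooled_se,
         ci95 = exp(pooled_b + c(-1.96, 1.96) * pooled_se),
         effect = exp(pooled_b),
         tau2 = m$tau2, Q = m$QE, I2 = m$I2, k = length(beta),
         method = method, studies = studies),
    class = "fi_meta")
}

#' @export
print.fi_meta <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s, k = %d)\n", x$method, x$k))
  cat(sprintf("  pooled effect %.3f [95%% CI %.3f, %.3f]; tau2 = %.4f, Q = %.3f, I2 = %.1f%%\n",
              x$effect, x$ci95[1], x$ci95[2], x$tau2, x$Q, x$I2))
  invisible(x)
}

#' Forest-plot table for a pooled result
#'
#' Per-trial rows (effect, CI, random-effects weight) followed by the pooled
#' row, ready for plotting or rendering; weights sum to 100%.
#'
#' @param meta An `fi_meta`.
#' @return Data frame with columns `row`, `trial`, `effect`, `ci_lo`,
#'   `ci_hi`, `weight`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "fi_meta"))
  s <- meta$studies
  rbind(
    data.frame(row = "study", trial = s$trial, effect = s$effect,
               ci_lo = s$ci_lo, ci_hi = s$ci_hi, weight = s$weight,
               stringsAsFactors = FALSE),
    data.frame(row = "pooled", trial = "RE pooled", effect = meta$effect,
               ci_lo = meta$ci95[1], ci_hi = meta$ci95[2], weight = 100,
               stringsAsFactors = FALSE))
}

#' Forest plot of per-trial and pooled effects
#'
#' @param x An `fi_meta`.
#' @param xlab Axis label (e.g. "IRR per 0.1 FI").
#' @param ... Passed to [metafor::forest.rma] alternatives; ignored here.
#' @return Invisibly, the forest table plotted.
#' @export
plot.fi_meta <- function(x, xlab = "Effect per 0.1 FI", ...) {
  tab <- forest_table(x)
  k <- nrow(tab)
  ys <- rev(seq_len(k))
  plot(tab$effect, ys, xlim = range(c(tab$ci_lo, tab$ci_hi, 1)),
       ylim = c(0.5, k + 0.5), pch = c(rep(15, k - 1), 18),
       xlab = xlab, ylab = "", yaxt = "n", log = "x")
  segments(tab$ci_lo, ys, tab$ci_hi, ys)
  abline(v = 1, lty = 2, col = "grey50")
  axis(2, at = ys, labels = tab$trial, las = 1, cex.axis = 0.8)
  invisible(tab)
}
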