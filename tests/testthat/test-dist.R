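test_that("gamma maximum-likelihood fit recovers known parameters", {
  set.seed(2024)
  x <- stats::rgamma(10000, shape = 4, scale = 0.035)
  f <- fit_fi_distribution(x, "gamma")
  expect_lt(abs(f$params[["shape"]] - 4) / 4, 0.05)
  expect_lt(abs(1 / f$params[["rate"]] - 0.035) / 0.035, 0.05)
  # the three-parameter family can never fit worse than its nested member
  g <- fit_fi_distribution(x, "gengamma")
  expect_gte(g$loglik, f$loglik - 1e-4)
})

test_that("generalised gamma fit recovers Stacy parameters within 10%", {
  set.seed(99)
  a <- 0.2; d <- 2; p <- 1.5
  x <- flexsurv::rgengamma.orig(10000, shape = p, scale = a, k = d / p)
  f <- fit_fi_distribution(x, "gengamma")
  expect_lt(abs(f$params[["a"]] - a) / a, 0.10)
  expect_lt(abs(f$params[["d"]] - d) / d, 0.10)
  expect_lt(abs(f$params[["p"]] - p) / p, 0.10)
  # coarse-grid profile-likelihood oracle: no grid point beats the optimum
  grid <- expand.grid(a = seq(0.1, 0.4, 0.05), d = seq(0.8, 4, 0.4),
                      p = seq(0.5, 3, 0.25))
  grid_ll <- apply(grid, 1, function(g) {
    sum(flexsurv::dgengamma.orig(x, shape = g[["p"]], scale = g[["a"]],
                                 k = g[["d"]] / g[["p"]], log = TRUE))
  })
  expect_gte(f$loglik, max(grid_ll) - 1e-6)
})

test_that("nesting inequalities hold across heterogeneous samples", {
  set.seed(5)
  samples <- list(
    stats::rgamma(800, 3, 20),
    stats::rweibull(800, shape = 1.8, scale = 0.2),
    stats::rlnorm(800, -2, 0.5),
    stats::rbeta(800, 2, 10))
  for (x in samples) {
    gg <- fit_fi_distribution(x, "gengamma")
    expect_gte(gg$loglik, fit_fi_distribution(x, "gamma")$loglik - 1e-4)
    expect_gte(gg$loglik, fit_fi_distribution(x, "weibull")$loglik - 1e-4)
    expect_true(all(gg$params > 0))
  }
})

test_that("KS statistic matches its closed forms and stats::ks.test", {
  # single observation: D = max(F(x), 1 - F(x))
  f_unif <- function(q) stats::punif(q)
  expect_equal(ks_statistic(0.3, f_unif), 0.7)
  expect_equal(ks_statistic(0.9, f_unif), 0.9)
  set.seed(31)
  x <- stats::rgamma(500, 3, 10)
  fit <- fit_fi_distribution(x, "gamma")
  ref <- unname(stats::ks.test(x, "pgamma", shape = fit$params[["shape"]],
                               rate = fit$params[["rate"]])$statistic)
  expect_equal(ks_statistic(x, fit), ref, tolerance = 1e-10)
  # order invariance
  expect_equal(ks_statistic(rev(x), fit), ks_statistic(sample(x), fit))
})

test_that("KS is small for self-generated data and near 1 for a gross mismatch", {
  set.seed(77)
  x <- stats::rgamma(10000, 4, 25)
  fit <- fit_fi_distribution(x, "gamma")
  expect_lt(ks_statistic(x, fit), 0.02)
  narrow <- structure(list(family = "lognormal",
                           params = c(meanlog = log(0.5), sdlog = 1e-4)),
                      class = "fi_distfit")
  expect_gt(ks_statistic(stats::runif(1000), narrow), 0.45)
})

test_that("family selection prefers the true family, with parsimony tie-breaks", {
  set.seed(12)
  x_gamma <- stats::rgamma(4000, 4, 25)
  sel <- select_best_fit(x_gamma)
  # gamma and gengamma fit near-identically; the tie-break keeps gamma out
  # of the three-parameter family
  expect_lt(abs(sel$ks[["gamma"]] - sel$ks[["gengamma"]]), 0.01)
  if (abs(sel$ks[["gamma"]] - sel$ks[["gengamma"]]) < 1e-3) {
    expect_false(sel$best == "gengamma")
  }
  x_gg <- flexsurv::rgengamma.orig(4000, shape = 2.5, scale = 0.15, k = 0.6)
  sel2 <- select_best_fit(x_gg, families = c("gamma", "weibull", "gengamma"))
  expect_lte(sel2$ks[["gengamma"]], min(sel2$ks) + 1e-3)
  one <- select_best_fit(x_gamma, families = "weibull")
  expect_equal(one$best, "weibull")
})

test_that("model summaries expose CDF prevalences and verified quantiles", {
  # gengamma reduced to the unit exponential: q99 = -ln(0.01)
  expo <- structure(list(family = "gengamma", params = c(a = 1, d = 1, p = 1)),
                    class = "fi_distfit")
  ms <- model_summary(expo)
  expect_equal(ms$quantile, -log(0.01), tolerance = 1e-10)
  set.seed(8)
  fit <- fit_fi_distribution(stats::rbeta(2000, 2, 10), "gengamma")
  ms2 <- model_summary(fit)
  expect_equal(sum(ms2$prevalence), 100, tolerance = 1e-8)
  expect_equal(cdf_fi_distribution(fit, quantile(fit, 0.99)), 0.99,
               tolerance = 1e-8)
  expect_equal(cdf_fi_distribution(fit, quantile(fit, 0.5)), 0.5,
               tolerance = 1e-8)
})

test_that("quantile and CDF are mutual inverses across all families", {
  set.seed(21)
  x <- stats::rbeta(1000, 2, 9)
  for (fam in c("lognormal", "gamma", "weibull", "gengamma")) {
    fit <- fit_fi_distribution(x, fam)
    probs <- c(0.01, 0.25, 0.5, 0.9, 0.99)
    expect_equal(cdf_fi_distribution(fit, quantile(fit, probs)), probs,
                 tolerance = 1e-8)
  }
})

test_that("degenerate and invalid samples are rejected; zeros are shifted", {
  expect_error(fit_fi_distribution(rep(0.2, 100), "gamma"), "constant",
               class = "frailtytrials_error")
  expect_error(fit_fi_distribution(stats::runif(10), "gamma"), "at least 30",
               class = "frailtytrials_error")
  set.seed(3)
  x <- c(rep(0, 5), stats::rbeta(295, 2, 10))
  expect_error(fit_fi_distribution(x, "gamma"), "zeros",
               class = "frailtytrials_error")
  f <- fit_fi_distribution(x, "gamma", n_deficits = 40)
  expect_true(all(f$params > 0))
  f2 <- fit_fi_distribution(x, "gamma", zero_shift = 1 / 80)
  expect_equal(f$params, f2$params)
})
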