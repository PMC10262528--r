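test_that("censoring at first SAE sets the event flag and observation time", {
  raw <- data.frame(id = c("A", "B", "C"),
                    first_sae_time = c(NA, 100, 50),
                    attrition = c(0, 0, 1))
  rec <- prepare_outcomes(raw, follow_up = 365)
  expect_equal(rec$sae_event, c(0L, 1L, 1L))
  expect_equal(rec$observation_time, c(365, 100, 50))
  expect_equal(rec$attrition, c(0L, 0L, 1L))
  expect_error(prepare_outcomes(
    data.frame(id = "A", first_sae_time = 400, attrition = 0), 365),
    "exceeds", class = "frailtytrials_error")
  expect_error(prepare_outcomes(
    data.frame(id = "A", first_sae_time = -1, attrition = 0), 365),
    "negative", class = "frailtytrials_error")
})

test_that("two-group Poisson reproduces the closed-form rate ratio", {
  d <- two_group_data(events_a = 10, events_b = 20)
  fit <- fit_sae_poisson(d$records, d$fi, adjust = FALSE)
  # rates 10/100 vs 20/100 py, FI gap one 0.1 unit -> IRR per 0.1 = 2
  expect_equal(fit$effect, 2.0, tolerance = 1e-6)
  expect_true(fit$ci95[1] < fit$effect && fit$effect < fit$ci95[2])
})

test_that("two-group logistic reproduces the closed-form odds ratio", {
  d <- two_group_data(attr_a = 20, attr_b = 40)
  fit <- fit_attrition_logistic(d$records, d$fi, adjust = FALSE)
  expect_equal(fit$effect, (40 / 60) / (20 / 80), tolerance = 1e-6)
  expect_equal(fit$effect, 8 / 3, tolerance = 1e-6)
})

test_that("GLM slopes agree with an independent likelihood optimizer", {
  set.seed(17)
  n <- 60
  fi <- stats::runif(n, 0.05, 0.4)
  t_obs <- stats::runif(n, 50, 365)
  y <- stats::rbinom(n, 1, pmin(0.9, fi * 1.5))
  records <- data.frame(id = sprintf("P%02d", 1:n), sae_event = y,
                        observation_time = t_obs, attrition = y)
  fi_tab <- data.frame(id = records$id, fi = fi, excluded = FALSE)
  pois <- fit_sae_poisson(records, fi_tab, adjust = FALSE)
  expect_equal(pois$beta, oracle_poisson_beta(y, fi * 10, t_obs),
               tolerance = 1e-3)
  logi <- fit_attrition_logistic(records, fi_tab, adjust = FALSE)
  expect_equal(logi$beta, oracle_logistic_beta(y, fi * 10), tolerance = 1e-3)
})

test_that("null associations converge to 1 in large samples", {
  set.seed(23)
  n <- 20000
  fi <- stats::runif(n, 0.05, 0.45)
  records <- data.frame(id = seq_len(n),
                        sae_event = stats::rbinom(n, 1, 0.15),
                        observation_time = 300,
                        attrition = stats::rbinom(n, 1, 0.25))
  fi_tab <- data.frame(id = records$id, fi = fi, excluded = FALSE)
  expect_equal(fit_sae_poisson(records, fi_tab, adjust = FALSE)$effect, 1,
               tolerance = 0.05)
  expect_equal(fit_attrition_logistic(records, fi_tab, adjust = FALSE)$effect,
               1, tolerance = 0.05)
})

test_that("coefficient scale is exactly per 0.1 FI and time units cancel", {
  set.seed(29)
  n <- 500
  fi <- stats::runif(n, 0.05, 0.45)
  records <- data.frame(id = seq_len(n),
                        sae_event = stats::rbinom(n, 1, fi),
                        observation_time = stats::runif(n, 100, 365),
                        attrition = stats::rbinom(n, 1, fi))
  fi_tab <- data.frame(id = records$id, fi = fi, excluded = FALSE)
  scaled <- fit_sae_poisson(records, fi_tab, adjust = FALSE)
  raw_glm <- stats::glm(records$sae_event ~ fi,
                        offset = log(records$observation_time),
                        family = stats::poisson())
  expect_equal(scaled$beta, unname(stats::coef(raw_glm)["fi"]) / 10,
               tolerance = 1e-9)
  days <- records
  days$observation_time <- days$observation_time * 365.25
  expect_equal(fit_sae_poisson(days, fi_tab, adjust = FALSE)$beta, scaled$beta,
               tolerance = 1e-9)
})

test_that("degenerate outcome data is rejected", {
  d <- two_group_data(events_a = 0, events_b = 0)
  expect_error(fit_sae_poisson(d$records, d$fi, adjust = FALSE), "no SAE",
               class = "frailtytrials_error")
  all_wd <- two_group_data(attr_a = 100, attr_b = 100)
  expect_error(fit_attrition_logistic(all_wd$records, all_wd$fi, adjust = FALSE),
               class = "frailtytrials_error")
  # FI perfectly separating attrition -> separation error
  sep <- two_group_data(attr_a = 0, attr_b = 100)
  expect_error(fit_attrition_logistic(sep$records, sep$fi, adjust = FALSE),
               class = "frailtytrials_error")
})

sim_sexed_trial <- function(n, irr_f, irr_m, seed) {
  set.seed(seed)
  female <- stats::rbinom(n, 1, 0.5)
  fi <- stats::rbeta(n, 2, 9)
  beta <- ifelse(female == 1, log(irr_f), log(irr_m))
  rate <- exp(-6.2 + beta * fi * 10)
  t_ev <- stats::rexp(n, rate)
  fup <- 365
  list(records = data.frame(id = seq_len(n),
                            sae_event = as.integer(t_ev <= fup),
                            observation_time = pmin(t_ev, fup),
                            attrition = stats::rbinom(n, 1, 0.2)),
       fi = data.frame(id = seq_len(n), fi = fi, excluded = FALSE),
       baseline = data.frame(id = seq_len(n),
                             age_years = stats::rnorm(n, 72, 6),
                             sex = ifelse(female == 1, "F", "M")))
}

test_that("sex-by-FI interaction test keeps nominal size and detects real effect modification", {
  pvals <- vapply(1:200, function(i) {
    d <- sim_sexed_trial(400, 1.6, 1.6, seed = 5000 + i)
    fit_sae_poisson(d$records, d$fi, d$baseline, interaction = TRUE)$interaction$p
  }, numeric(1))
  rejection <- mean(pvals < 0.05)
  expect_gte(rejection, 0.02)
  expect_lte(rejection, 0.09)
  hits <- vapply(1:30, function(i) {
    d <- sim_sexed_trial(4000, 2.0, 1.3, seed = 9000 + i)
    f <- fit_sae_poisson(d$records, d$fi, d$baseline, interaction = TRUE)
    (f$interaction$beta > 0) && (f$interaction$p < 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("interaction models require both sexes", {
  d <- sim_sexed_trial(200, 1.6, 1.6, seed = 44)
  d$baseline$sex <- "F"
  expect_error(fit_sae_poisson(d$records, d$fi, d$baseline, interaction = TRUE),
               "both sexes", class = "frailtytrials_error")
  expect_error(fit_attrition_logistic(d$records, d$fi, d$baseline,
                                      interaction = TRUE),
               "both sexes", class = "frailtytrials_error")
})

test_that("adjusted models report covariates and optional quadratic term", {
  d <- sim_sexed_trial(1000, 1.6, 1.6, seed = 55)
  fit <- fit_sae_poisson(d$records, d$fi, d$baseline)
  expect_true(all(c("age_years", "female") %in% rownames(fit$covariates)))
  quad <- fit_sae_poisson(d$records, d$fi, d$baseline, quadratic = TRUE)
  expect_true("I(fi10^2)" %in% rownames(summary(quad$fit)$coefficients))
  row <- as.data.frame(fit)
  expect_equal(row$effect, fit$effect)
  expect_equal(row$n, 1000)
})
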