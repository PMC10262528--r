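#' Apply the first-event censoring rule to a raw outcome table
#'
#' Builds per-participant outcome records: the serious-adverse-event (SAE)
#' indicator is 1 when the first SAE occurs on or before the end of
#' follow-up, and observation time is the time to first SAE or the follow-up
#' length, whichever comes first. Later events are ignored. The attrition
#' flag (withdrawal before the stipulated endpoint, any reason) is carried
#' through unchanged.
#'
#' @param raw Data frame with columns `id`, `first_sae_time` (time of first
#'   SAE, `NA` if none observed) and `attrition` (0/1).
#' @param follow_up Trial follow-up length (same time unit as
#'   `first_sae_time`; the unit cancels from the incidence rate ratio).
#' @return Data frame (class `outcome_records`) with columns `id`,
#'   `sae_event`, `observation_time`, `attrition`.
#' @export
prepare_outcomes <- function(raw, follow_up) {
  stopifnot(is.data.frame(raw), follow_up > 0)
  for (col in c("id", "first_sae_time", "attrition")) {
    if (is.null(raw[[col]])) {
      stop_frailty("outcome table needs a '%s' column", col, class = "data_error")
    }
  }
  t1 <- raw$first_sae_time
  if (any(!is.na(t1) & t1 < 0)) {
    stop_frailty("negative SAE event times", class = "data_error")
  }
  if (any(!is.na(t1) & t1 > follow_up)) {
    stop_frailty("SAE event time exceeds follow-up length (%g)", follow_up,
                 class = "data_error")
  }
  sae <- as.integer(!is.na(t1))
  obs <- ifelse(sae == 1, t1, follow_up)
  if (any(obs <= 0)) {
    stop_frailty("observation time must be positive (event at time 0?)",
                 class = "data_error")
  }
  out <- data.frame(id = raw$id, sae_event = sae, observation_time = obs,
                    attrition = as.integer(raw$attrition),
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome_records", "data.frame")
  out
}

# Assemble the modelling frame: outcomes joined to FI (x10 so coefficients
# are per 0.1-unit FI), age and sex; excluded participants dropped.
model_frame <- function(records, fi_table, baseline = NULL) {
  fi <- if (is.data.frame(fi_table)) fi_table else
    data.frame(id = names(fi_table) %||% seq_along(fi_table), fi = fi_table,
               excluded = is.na(fi_table))
  d <- merge(records, fi[, c("id", "fi", "excluded")], by = "id")
  if (!is.null(baseline)) {
    d <- merge(d, baseline[, c("id", "age_years", "sex")], by = "id")
  }
  if (is.null(d$age_years) || is.null(d$sex)) {
    stop_frailty("age_years and sex are required (supply `baseline`)",
                 class = "data_error")
  }
  d <- d[!d$excluded & !is.na(d$fi), ]
  d$fi10 <- d$fi * 10
  d$female <- encode_sex(d$sex)
  d
}

# Fit a glm while trapping the warnings that signal separation or
# non-convergence (instead of leaking them to the caller).
safe_glm <- function(form, family, data) {
  warns <- character()
  fit <- withCallingHandlers(
    stats::glm(form, family = family, data = data),
    warning = function(w) {
      if (grepl("did not converge|fitted (rates|probabilities) numerically",
                conditionMessage(w))) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, warns = warns)
}

check_separation <- function(fit, context, warns = character()) {
  coefs <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(coefs)) || any(abs(coefs[-1]) > 15)) {
    worst <- names(coefs)[-1][which.max(abs(coefs[-1]))]
    stop_frailty("%s: (quasi-)complete separation or non-convergence (covariate '%s')",
                 context, worst, class = "fit_error")
  }
  if (any(grepl("did not converge", warns))) {
    stop_frailty("%s: IRLS did not converge", context, class = "fit_error")
  }
}

wrap_glm <- function(fit, model, n, interaction = FALSE) {
  sm <- summary(fit)$coefficients
  beta <- sm["fi10", "Estimate"]
  se <- sm["fi10", "Std. Error"]
  int_row <- grep(":", rownames(sm), value = TRUE)
  res <- list(
    model = model,
    beta = beta, se = se,
    effect = exp(beta),
    ci95 = exp(beta + c(-1.96, 1.96) * se),
    covariates = sm[setdiff(rownames(sm), c("fi10", int_row)), , drop = FALSE],
    n = n, fit = fit, interaction = NULL)
  if (interaction) {
    res$interaction <- list(beta = sm[int_row, "Estimate"],
                            se = sm[int_row, "Std. Error"],
                            p = sm[int_row, "Pr(>|z|)"])
  }
  class(res) <- "fi_assoc"
  res
}

#' Poisson model of SAE incidence against frailty
#'
#' Log-link Poisson regression of the first-SAE indicator with an offset for
#' log observation time, adjusted for age (linear, in years) and sex
#' (female = 1). The frailty index is rescaled by 10 internally, so the
#' exponentiated coefficient is the incidence rate ratio (IRR) per 0.1-unit
#' FI increase. With censoring at the first event the outcome count is 0/1
#' and this is exactly the exponential-hazard likelihood.
#'
#' @param records [prepare_outcomes()] output.
#' @param fi_table An `fi_table` (or a named FI vector).
#' @param baseline Baseline table providing `age_years` and `sex` (optional
#'   if `records` already carries them).
#' @param adjust Adjust for age and sex (default `TRUE`; unadjusted fits are
#'   mainly for closed-form checks).
#' @param interaction Add a sex x FI interaction term and report its Wald p.
#' @param quadratic Add a quadratic FI term (exploratory non-linearity
#'   check; off by default).
#' @return Object of class `fi_assoc` with `beta`, `se`, `effect` (IRR),
#'   `ci95`, `covariates`, `n`, and `interaction` (when requested).
#' @export
fit_sae_poisson <- function(records, fi_table, baseline = NULL, adjust = TRUE,
                            interaction = FALSE, quadratic = FALSE) {
  d <- if (adjust || interaction) model_frame(records, fi_table, baseline) else {
    fi <- if (is.data.frame(fi_table)) fi_table else
      data.frame(id = names(fi_table), fi = fi_table, excluded = is.na(fi_table))
    m <- merge(records, fi[, c("id", "fi", "excluded")], by = "id")
    m <- m[!m$excluded & !is.na(m$fi), ]
    m$fi10 <- m$fi * 10
    m
  }
  if (sum(d$sae_event) == 0) {
    stop_frailty("no SAE events; Poisson model cannot be fitted", class = "fit_error")
  }
  form <- build_formula("sae_event", adjust, interaction, quadratic)
  if (interaction && length(unique(d$female)) < 2) {
    stop_frailty("sex x FI interaction needs both sexes in the sample",
                 class = "fit_error")
  }
  d$log_obs_time <- log(d$observation_time)
  form <- stats::update(form, . ~ . + offset(log_obs_time))
  g <- safe_glm(form, stats::poisson(link = "log"), d)
  check_separation(g$fit, "Poisson SAE model", g$warns)
  wrap_glm(g$fit, "poisson_sae", nrow(d), interaction)
}

#' Logistic model of trial attrition against frailty
#'
#' Logit-link binomial regression of the attrition indicator, adjusted for
#' age and sex; the exponentiated FI coefficient is the odds ratio (OR) per
#' 0.1-unit FI increase.
#'
#' @inheritParams fit_sae_poisson
#' @return Object of class `fi_assoc` with `effect` being the OR.
#' @export
fit_attrition_logistic <- function(records, fi_table, baseline = NULL,
                                   adjust = TRUE, interaction = FALSE,
                                   quadratic = FALSE) {
  d <- if (adjust || interaction) model_frame(records, fi_table, baseline) else {
    fi <- if (is.data.frame(fi_table)) fi_table else
      data.frame(id = names(fi_table), fi = fi_table, excluded = is.na(fi_table))
    m <- merge(records, fi[, c("id", "fi", "excluded")], by = "id")
    m <- m[!m$excluded & !is.na(m$fi), ]
    m$fi10 <- m$fi * 10
    m
  }
  if (length(unique(d$attrition)) < 2) {
    stop_frailty("attrition is constant; logistic model cannot be fitted",
                 class = "fit_error")
  }
  if (interaction && length(unique(d$female)) < 2) {
    stop_frailty("sex x FI interaction needs both sexes in the sample",
                 class = "fit_error")
  }
  form <- build_formula("attrition", adjust, interaction, quadratic)
  g <- safe_glm(form, stats::binomial(link = "logit"), d)
  check_separation(g$fit, "logistic attrition model", g$warns)
  wrap_glm(g$fit, "logistic_attrition", nrow(d), interaction)
}

build_formula <- function(outcome, adjust, interaction, quadratic) {
  rhs <- "fi10"
  if (quadratic) rhs <- paste(rhs, "+ I(fi10^2)")
  if (adjust) rhs <- paste(rhs, "+ age_years + female")
  if (interaction) rhs <- paste(rhs, "+ female:fi10")
  stats::as.formula(paste(outcome, "~", rhs))
}

#' @export
print.fi_assoc <- function(x, ...) {
  lab <- if (x$model == "poisson_sae") "IRR" else "OR"
  cat(sprintf("%s (n = %d): %s per 0.1 FI = %.3f [95%% CI %.3f, %.3f]\n",
              x$model, x$n, lab, x$effect, x$ci95[1], x$ci95[2]))
  if (!is.null(x$interaction)) {
    cat(sprintf("  sex x FI interaction: beta = %.3f (SE %.3f), Wald p = %.3f\n",
                x$interaction$beta, x$interaction$se, x$interaction$p))
  }
  invisible(x)
}

#' @export
coef.fi_assoc <- function(object, ...) stats::coef(object$fit)

#' @export
summary.fi_assoc <- function(object, ...) summary(object$fit, ...)

#' Flatten an `fi_assoc` to a one-row data frame
#' @param x An `fi_assoc`.
#' @param ... Unused.
#' @return One-row data frame (model, beta, se, effect, ci_lo, ci_hi, n).
#' @export
as.data.frame.fi_assoc <- function(x, ...) {
  data.frame(model = x$model, beta = x$beta, se = x$se, effect = x$effect,
             ci_lo = x$ci95[1], ci_hi = x$ci95[2], n = x$n,
             stringsAsFactors = FALSE)
}
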