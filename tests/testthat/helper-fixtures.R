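# In-code fixtures and independent oracles shared across test files.

# A minimal catalog of `n` binary column-sourced physical deficits.
binary_catalog <- function(n, systems = c("cardiovascular", "respiratory",
                                          "renal", "neurological", "ADL")) {
  defs <- lapply(seq_len(n), function(j) {
    deficit_definition(id = sprintf("def%02d", j),
                       system = systems[(j - 1) %% length(systems) + 1],
                       kind = "binary")
  })
  deficit_catalog(defs, name = sprintf("binary-%d", n))
}

# Uniform loadings for a binary catalog (polypharmacy-free).
flat_loadings <- function(catalog, alpha, lambda = 0, gamma = 0) {
  data.frame(id = catalog_ids(catalog), alpha = alpha, lambda = lambda,
             gamma = gamma, stringsAsFactors = FALSE)
}

# Medication map fixture used in the catalog tests.
fixture_med_map <- function() {
  medication_map(list(
    list(pattern = "statin", condition = "cvd-risk"),
    list(pattern = "metformin", condition = "diabetes"),
    list(pattern = "antihypertensive", condition = "hypertension")))
}

# Brute-force frailty-index oracle: explicit loop, independent of compute_fi.
oracle_fi <- function(scores, max_missing = 0.20) {
  n_total <- length(scores)
  n_avail <- 0L
  total <- 0
  for (s in scores) {
    if (!is.na(s)) {
      n_avail <- n_avail + 1L
      total <- total + s
    }
  }
  if ((n_total - n_avail) / n_total > max_missing) return(NA_real_)
  total / n_avail
}

# Independent Poisson log-likelihood maximised by optim (not glm): intercept
# plus one slope on x, offset log(t), outcome y in {0,1}.
oracle_poisson_beta <- function(y, x, t) {
  nll <- function(par) {
    mu <- exp(par[1] + par[2] * x + log(t))
    -sum(stats::dpois(y, mu, log = TRUE))
  }
  stats::optim(c(log(mean(y / t)), 0), nll, method = "BFGS")$par[2]
}

# Same idea for the logistic slope.
oracle_logistic_beta <- function(y, x) {
  nll <- function(par) {
    p <- stats::plogis(par[1] + par[2] * x)
    -sum(stats::dbinom(y, 1, p, log = TRUE))
  }
  stats::optim(c(stats::qlogis(mean(y)), 0), nll, method = "BFGS")$par[2]
}

bundled_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_catalog(system.file("extdata", "deficit_catalog.yaml",
                                         package = "frailtytrials"))
    }
    cache
  }
})

# Two-group data with fixed event counts (no randomness); time 1 per
# participant so rates equal event proportions. Returns outcome records and
# the matching FI table (group a: FI 0.1, group b: FI 0.2).
two_group_data <- function(n_per = 100, events_a = 10, events_b = 20,
                           attr_a = 20, attr_b = 40) {
  id <- sprintf("P%03d", seq_len(2 * n_per))
  grp <- rep(c("a", "b"), each = n_per)
  records <- data.frame(
    id = id,
    sae_event = c(rep(1, events_a), rep(0, n_per - events_a),
                  rep(1, events_b), rep(0, n_per - events_b)),
    observation_time = 1,
    attrition = c(rep(1, attr_a), rep(0, n_per - attr_a),
                  rep(1, attr_b), rep(0, n_per - attr_b)),
    stringsAsFactors = FALSE)
  fi <- data.frame(id = id, fi = ifelse(grp == "a", 0.1, 0.2),
                   excluded = FALSE, stringsAsFactors = FALSE)
  list(records = records, fi = fi)
}
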