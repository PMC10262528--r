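test_that("deficit scoring maps raw values onto the 0-1 grid", {
  ord5 <- deficit_definition("x", system = "s", kind = "ordinal", n_levels = 5)
  expect_equal(score_deficit(1, ord5), 0.25)
  expect_equal(vapply(0:4, score_deficit, numeric(1), definition = ord5),
               c(0, 0.25, 0.5, 0.75, 1))
  bin <- deficit_definition("b", system = "s", kind = "binary")
  expect_equal(score_deficit(0, bin), 0)
  expect_equal(score_deficit(1, bin), 1)
  ord3 <- deficit_definition("y", system = "s", kind = "ordinal", n_levels = 3)
  expect_equal(score_deficit(2, ord3), 1.0)
  thr <- deficit_definition("t", system = "s", kind = "threshold",
                            threshold = 160, direction = "above")
  expect_equal(score_deficit(170, thr), 1)
  expect_equal(score_deficit(159.9, thr), 0)
  expect_equal(score_deficit(160, thr), 1)
  expect_true(is.na(score_deficit(NA, bin)))
})

test_that("out-of-range ordinal levels raise errors naming participant and deficit", {
  ord5 <- deficit_definition("adl_bathing", system = "ADL", kind = "ordinal",
                             n_levels = 5)
  err <- expect_error(score_deficit(7, ord5, participant = "P007"),
                      class = "frailtytrials_error")
  expect_match(conditionMessage(err), "adl_bathing")
  expect_match(conditionMessage(err), "P007")
})

test_that("the frailty index is the ratio of accumulated to available deficits", {
  mk <- function(x) stats::setNames(x, sprintf("d%02d", seq_along(x)))
  expect_equal(compute_fi(mk(rep(0, 40)))$fi, 0)
  expect_equal(compute_fi(mk(c(rep(1, 10), rep(0, 30))))$fi, 0.25)
  # 2 missing, 19 of the remaining 38 scored 1 -> 19/38
  s <- mk(c(rep(NA, 2), rep(1, 19), rep(0, 19)))
  r <- compute_fi(s)
  expect_equal(r$fi, 0.5)
  expect_equal(r$n_available, 38)
  expect_false(r$excluded)
})

test_that("participants missing >20% of deficits are excluded; exactly 20% retained", {
  mk <- function(x) stats::setNames(x, sprintf("d%02d", seq_along(x)))
  r9 <- compute_fi(mk(c(rep(NA, 9), rep(1, 31))))   # 22.5% missing
  expect_true(r9$excluded)
  expect_true(is.na(r9$fi))
  r8 <- compute_fi(mk(c(rep(NA, 8), rep(1, 32))))   # exactly 20% missing
  expect_false(r8$excluded)
  expect_equal(r8$fi, 1)
  expect_error(compute_fi(stats::setNames(numeric(), character())),
               class = "frailtytrials_error")
})

test_that("compute_fi matches the brute-force oracle on random score matrices", {
  set.seed(101)
  ids <- sprintf("d%02d", 1:20)
  for (i in 1:300) {
    s <- stats::runif(20)
    s[stats::runif(20) < 0.25] <- NA
    names(s) <- ids
    r <- compute_fi(s)
    expected <- oracle_fi(s)
    if (is.na(expected)) expect_true(r$excluded)
    else expect_equal(r$fi, expected)
  }
  # exclusion boundary swept exactly
  for (n_miss in 0:10) {
    s <- stats::setNames(c(rep(NA, n_miss), rep(0.5, 20 - n_miss)), ids)
    expect_equal(compute_fi(s)$excluded, n_miss / 20 > 0.2)
  }
})

test_that("fi is permutation-invariant and monotone in any single deficit", {
  set.seed(7)
  ids <- sprintf("d%02d", 1:15)
  s <- stats::setNames(stats::runif(15), ids)
  shuffled <- s[sample(ids)]
  expect_equal(compute_fi(shuffled, variant_ids = ids)$fi,
               compute_fi(s, variant_ids = ids)$fi)
  for (j in sample(15, 5)) {
    bumped <- s
    bumped[j] <- min(1, s[j] + 0.3)
    expect_gte(compute_fi(bumped)$fi, compute_fi(s)$fi)
  }
})

test_that("build_fi_table reproduces hand-scored rows for a small fixture", {
  defs <- list(
    deficit_definition("cond", system = "cardiovascular", kind = "binary"),
    deficit_definition("lab", system = "laboratory", kind = "threshold",
                       threshold = 12, direction = "below"),
    deficit_definition("adl", system = "ADL", kind = "ordinal", n_levels = 5),
    deficit_definition("cog", system = "cognition", kind = "ordinal",
                       n_levels = 3, variant_class = "cognitive"))
  cat_ <- deficit_catalog(defs, name = "tiny", cognitive_n = 1L)
  baseline <- data.frame(
    id = c("A", "B", "C"),
    age_years = c(70, 80, 75), sex = c("F", "M", "F"),
    cond = c(1, 0, NA), lab = c(11, 13, NA), adl = c(2, 0, NA),
    cog = c(1, 2, NA), stringsAsFactors = FALSE)
  phys <- build_fi_table(baseline, cat_, variant = "physical")
  # A: (1 + 1 + 0.5)/3; B: (0 + 0 + 0)/3
  expect_equal(phys$fi[phys$id == "A"], 2.5 / 3)
  expect_equal(phys$fi[phys$id == "B"], 0)
  expect_true(phys$excluded[phys$id == "C"])  # all missing
  expect_equal(attr(phys, "n_excluded"), 1)
  both <- build_fi_table(baseline, cat_, variant = "physical_cognitive")
  # the cognitive deficit only adds a numerator/denominator term
  expect_equal(both$fi[both$id == "A"], (2.5 + 0.5) / 4)
  expect_equal(both$fi[both$id == "B"], 1 / 4)
})

test_that("unresolvable deficits fail before any scoring", {
  cat_ <- binary_catalog(5)
  baseline <- data.frame(id = "A", age_years = 70, sex = "F",
                         def01 = 1, stringsAsFactors = FALSE)
  expect_error(build_fi_table(baseline, cat_, variant = "physical"),
               "def02", class = "frailtytrials_error")
})

test_that("frailty categories follow the half-open eFI convention", {
  expect_equal(as.character(categorize_fi(c(0.10, 0.30, 0.24, 0.12, 0.36, 0.37, 0, 1))),
               c("robust", "moderate", "mild", "robust", "moderate", "severe",
                 "robust", "severe"))
  expect_error(categorize_fi(1.2), class = "frailtytrials_error")
  expect_error(categorize_fi(-0.1), class = "frailtytrials_error")
})

test_that("summarize_fi reports moments, 99th centile and prevalences", {
  s <- summarize_fi(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(s$mean, 0.25)
  expect_equal(unname(s$prevalence), rep(25, 4))
  expect_equal(sum(s$prevalence), 100)
  const <- summarize_fi(c(0.14, 0.14, 0.14))
  expect_equal(const$sd, 0)
  expect_equal(const$q99, 0.14)
  expect_error(summarize_fi(c(0.5)), class = "frailtytrials_error")
  expect_error(summarize_fi(rep(NA_real_, 5)), class = "frailtytrials_error")
})

test_that("threshold prevalence equals moderate + severe at the 0.24 boundary", {
  expect_equal(prevalence_over_threshold(c(robust = 5.5, mild = 45.9,
                                           moderate = 41.1, severe = 7.5)),
               48.6)
  expect_equal(prevalence_over_threshold(c(robust = 43.2, mild = 50.0,
                                           moderate = 6.7, severe = 0.2)), 6.9)
  expect_equal(prevalence_over_threshold(rep(0.05, 10)), 0)
  expect_error(prevalence_over_threshold(c(robust = 50, mild = 50, moderate = 0,
                                           severe = 0), threshold = 0.3),
               "raw FI", class = "frailtytrials_error")
  # raw-value route agrees with the category route on any sample
  set.seed(11)
  x <- stats::rbeta(500, 2, 8)
  s <- summarize_fi(x)
  expect_equal(prevalence_over_threshold(x),
               sum(s$prevalence[c("moderate", "severe")]))
  expect_equal(prevalence_over_threshold(s), prevalence_over_threshold(x))
})
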