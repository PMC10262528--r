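read_table_maybe <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      stop_frailty("%s file not found: %s", what, x, class = "config_error")
    }
    return(utils::read.csv(x, stringsAsFactors = FALSE))
  }
  stop_frailty("%s must be a data frame or a CSV path", what, class = "config_error")
}

#' Describe one trial for the analysis pipeline
#'
#' @param name Trial label.
#' @param baseline Baseline table (data frame or CSV path) with columns
#'   `id`, `age_years`, `sex`, `medications` and one column per
#'   column-sourced deficit.
#' @param outcomes Raw outcome table (data frame or CSV path) with columns
#'   `id`, `first_sae_time`, `attrition`.
#' @param follow_up Follow-up length (days).
#' @return A `trial_entry` list.
#' @export
trial_entry <- function(name, baseline, outcomes, follow_up) {
  stopifnot(is.character(name), follow_up > 0)
  structure(list(name = name, baseline = baseline, outcomes = outcomes,
                 follow_up = follow_up), class = "trial_entry")
}

#' Run the full frailty analysis across one or more trials
#'
#' End-to-end orchestration: score each trial's baseline table against the
#' catalog, compute the frailty index per participant for each variant,
#' summarise each FI sample empirically and parametrically (best-fitting
#' family among the candidates by KS statistic), fit the per-trial SAE
#' Poisson and attrition logistic models, and pool log-coefficients across
#' trials by DerSimonian-Laird random-effects meta-analysis.
#'
#' @param trials List of [trial_entry()] objects (or `sim_trial` objects
#'   from [generate_trial()], which carry their own tables).
#' @param catalog A validated `deficit_catalog`; defaults to the bundled
#'   synthetic catalog.
#' @param variants Index variants to run.
#' @param boundaries Frailty category cut-points.
#' @param families Candidate distribution families for the parametric
#'   summary.
#' @param output_dir Optional directory; when given, per-participant FI
#'   tables (CSV), the descriptive summary table (CSV + JSON), regression and
#'   meta results (JSON) and a manifest are written there.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `fi_pipeline`: `per_trial` (nested by trial then
#'   variant: `fi_table`, `summary`, `dist`, `dist_summary`, `sae`,
#'   `attrition`), `meta` (by outcome then variant), `table2` (data frame),
#'   `manifest`.
#' @export
run_pipeline <- function(trials, catalog = NULL,
                         variants = c("physical", "physical_cognitive"),
                         boundaries = c(0.12, 0.24, 0.36),
                         families = c("lognormal", "gamma", "weibull", "gengamma"),
                         output_dir = NULL, seed = NA_integer_) {
  if (length(trials) == 0) {
    stop_frailty("no trials supplied", class = "config_error")
  }
  if (inherits(trials, c("trial_entry", "sim_trial"))) {
    trials <- list(trials)  # allow a single un-wrapped entry
  }
  trials <- lapply(trials, function(tr) {
    if (inherits(tr, "sim_trial")) {
      trial_entry(tr$truth$name, tr$baseline, tr$outcomes, tr$truth$follow_up)
    } else if (inherits(tr, "trial_entry")) tr
    else do.call(trial_entry, tr)
  })
  catalog <- catalog %||% load_catalog(
    system.file("extdata", "deficit_catalog.yaml", package = "frailtytrials"))

  # startup validation before any computation
  trials <- lapply(trials, function(tr) {
    tr$baseline <- read_table_maybe(tr$baseline, sprintf("trial '%s' baseline", tr$name))
    tr$outcomes <- read_table_maybe(tr$outcomes, sprintf("trial '%s' outcomes", tr$name))
    tr
  })

  per_trial <- list()
  for (tr in trials) {
    res_v <- list()
    for (v in variants) {
      fi_tab <- build_fi_table(tr$baseline, catalog, variant = v)
      smry <- summarize_fi(fi_tab, boundaries = boundaries)
      n_def <- length(catalog_ids(catalog, v))
      sel <- select_best_fit(fi_tab, families = families, n_deficits = n_def)
      dsum <- model_summary(sel$fits[[sel$best]], boundaries = boundaries)
      recs <- prepare_outcomes(tr$outcomes, tr$follow_up)
      sae <- fit_sae_poisson(recs, fi_tab, baseline = tr$baseline)
      attr_ <- fit_attrition_logistic(recs, fi_tab, baseline = tr$baseline)
      res_v[[v]] <- list(fi_table = fi_tab, summary = smry, dist = sel,
                         dist_summary = dsum, sae = sae, attrition = attr_,
                         n_excluded = attr(fi_tab, "n_excluded"))
    }
    per_trial[[tr$name]] <- res_v
  }

  meta <- list()
  for (outc in c("sae", "attrition")) {
    meta[[outc]] <- list()
    for (v in variants) {
      beta <- vapply(per_trial, function(x) x[[v]][[outc]]$beta, numeric(1))
      se <- vapply(per_trial, function(x) x[[v]][[outc]]$se, numeric(1))
      meta[[outc]][[v]] <- pool_random_effects(beta, se, trial = names(per_trial))
    }
  }

  tab2 <- report_table2(per_trial)
  manifest <- list(
    package_version = as.character(utils::packageVersion("frailtytrials")),
    catalog = catalog$name, catalog_version = catalog$version,
    variants = variants, boundaries = boundaries, seed = seed,
    trials = vapply(trials, `[[`, "", "name"),
    n_excluded = lapply(per_trial, function(x)
      vapply(x, `[[`, integer(1), "n_excluded")))

  out <- structure(list(per_trial = per_trial, meta = meta, table2 = tab2,
                        manifest = manifest),
                   class = "fi_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

#' Render a publication-style descriptive summary table
#'
#' One row per trial x variant: mean (SD), 99th centile, and the four
#' frailty-category prevalences, percentages rounded half-up to one decimal.
#'
#' @param per_trial Nested per-trial results from [run_pipeline()] (or a
#'   list of `fi_summary` objects, one per row, named `trial.variant`).
#' @return Data frame with columns `trial`, `variant`, `n`, `n_excluded`,
#'   `mean`, `sd`, `q99`, `robust`, `mild`, `moderate`, `severe`.
#' @export
report_table2 <- function(per_trial) {
  round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d
  rows <- list()
  for (tn in names(per_trial)) {
    entry <- per_trial[[tn]]
    if (inherits(entry, "fi_summary")) entry <- list(summary = entry)
    for (vn in names(entry)) {
      s <- if (inherits(entry[[vn]], "fi_summary")) entry[[vn]] else entry[[vn]]$summary
      if (is.null(s)) next
      rows[[paste(tn, vn)]] <- data.frame(
        trial = tn, variant = vn, n = s$n, n_excluded = s$n_excluded,
        mean = round(s$mean, 2), sd = round(s$sd, 2), q99 = round(s$q99, 2),
        robust = round_half_up(s$prevalence[["robust"]]),
        mild = round_half_up(s$prevalence[["mild"]]),
        moderate = round_half_up(s$prevalence[["moderate"]]),
        severe = round_half_up(s$prevalence[["severe"]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    stop_frailty("no summaries to tabulate", class = "config_error")
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  for (tn in names(res$per_trial)) {
    for (vn in names(res$per_trial[[tn]])) {
      x <- res$per_trial[[tn]][[vn]]
      utils::write.csv(x$fi_table,
                       file.path(dir, sprintf("fi_%s_%s.csv", tn, vn)),
                       row.names = FALSE)
    }
  }
  exportable <- lapply(res$per_trial, function(tv) lapply(tv, function(x) {
    list(summary = x$summary[c("n", "n_excluded", "mean", "sd", "q99", "prevalence")],
         dist = list(family = x$dist$best,
                     params = as.list(x$dist$fits[[x$dist$best]]$params),
                     loglik = x$dist$fits[[x$dist$best]]$loglik,
                     ks = unname(x$dist$ks[x$dist$best]),
                     model_prevalence = as.list(x$dist_summary$prevalence),
                     model_q99 = x$dist_summary$quantile),
         sae = as.data.frame(x$sae), attrition = as.data.frame(x$attrition))
  }))
  jsonlite::write_json(exportable, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  meta_out <- lapply(res$meta, function(by_v) lapply(by_v, function(m) {
    list(effect = m$effect, ci_lo = m$ci95[1], ci_hi = m$ci95[2],
         beta = m$beta, se = m$se, tau2 = m$tau2, Q = m$Q, I2 = m$I2, k = m$k)
  }))
  jsonlite::write_json(meta_out, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (outc in names(res$meta)) {
    for (vn in names(res$meta[[outc]])) {
      utils::write.csv(forest_table(res$meta[[outc]][[vn]]),
                       file.path(dir, sprintf("forest_%s_%s.csv", outc, vn)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.fi_pipeline <- function(x, ...) {
  cat("Frailty pipeline results\n")
  cat("\nDescriptive summaries:\n")
  print(x$table2, row.names = FALSE)
  cat("\nPooled associations (per 0.1 FI):\n")
  for (outc in names(x$meta)) {
    for (vn in names(x$meta[[outc]])) {
      m <- x$meta[[outc]][[vn]]
      lab <- if (outc == "sae") "IRR" else "OR"
      cat(sprintf("  %-9s %-18s %s = %.2f [%.2f, %.2f]  tau2 = %.3f\n",
                  outc, vn, lab, m$effect, m$ci95[1], m$ci95[2], m$tau2))
    }
  }
  invisible(x)
}
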