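#' Score a raw baseline value against a deficit definition
#'
#' Maps a raw variable to a deficit score in \[0, 1\]. Binary deficits score 0
#' (absent) or 1 (present); ordinal deficits at 0-indexed level `k` of `n`
#' levels score `k / (n - 1)` (e.g. 0, 0.25, 0.5, 0.75, 1 for a 5-level
#' variable); threshold deficits score 1 when the raw value lies beyond the
#' cut-point in the deficit direction, else 0. `NA` propagates as missing.
#'
#' @param raw_value Raw baseline value (numeric, or logical for binary).
#' @param definition A [deficit_definition()].
#' @param participant Optional id used in error messages.
#' @return Score in \[0, 1\], or `NA_real_` when the raw value is missing.
#' @export
score_deficit <- function(raw_value, definition, participant = NULL) {
  if (is.null(raw_value) || length(raw_value) == 0 || is.na(raw_value)) {
    return(NA_real_)
  }
  who <- if (is.null(participant)) "" else sprintf(" (participant %s)", participant)
  switch(definition$kind,
    binary = {
      v <- if (is.logical(raw_value)) as.numeric(raw_value) else as.numeric(raw_value)
      if (!v %in% c(0, 1)) {
        stop_frailty("deficit '%s'%s: binary raw value must be 0/1, got %s",
                     definition$id, who, format(raw_value), class = "data_error")
      }
      v
    },
    ordinal = {
      k <- as.numeric(raw_value)
      n <- definition$n_levels
      if (k != round(k) || k < 0 || k > n - 1) {
        stop_frailty("deficit '%s'%s: ordinal level %s outside 0..%d",
                     definition$id, who, format(raw_value), n - 1L,
                     class = "data_error")
      }
      k / (n - 1)
    },
    threshold = {
      v <- as.numeric(raw_value)
      beyond <- if (definition$direction == "above") v >= definition$threshold
                else v <= definition$threshold
      as.numeric(beyond)
    }
  )
}

#' Compute a frailty index for one participant
#'
#' The frailty index is the ratio of accumulated deficits to deficits
#' assessed: the sum of available (non-missing) scores divided by the number
#' of available deficits. Missing deficits are removed from both numerator
#' and denominator; participants missing strictly more than `max_missing`
#' (default 20%) of the variant's deficits are excluded (exactly 20% missing
#' is retained).
#'
#' @param scores Named numeric vector of deficit scores in \[0, 1\] with `NA`
#'   for missing; names are deficit ids.
#' @param variant_ids Deficit ids making up the index variant; defaults to
#'   all of `names(scores)`.
#' @param max_missing Exclusion threshold on the missing fraction.
#' @param id Participant id carried into the result.
#' @param variant Variant label carried into the result.
#' @return A one-row data frame (class `fi_result`) with columns `id`,
#'   `variant`, `n_total`, `n_available`, `missing_fraction`, `excluded`,
#'   `fi` (`NA` when excluded).
#' @export
compute_fi <- function(scores, variant_ids = names(scores),
                       max_missing = 0.20, id = NA_character_,
                       variant = "physical") {
  if (length(variant_ids) == 0) {
    stop_frailty("variant deficit set is empty", class = "config_error")
  }
  missing_ids <- setdiff(variant_ids, names(scores))
  if (length(missing_ids)) {
    stop_frailty("scores lack variant deficits: %s",
                 paste(missing_ids, collapse = ", "), class = "config_error")
  }
  s <- scores[variant_ids]
  bad <- !is.na(s) & (s < 0 | s > 1)
  if (any(bad)) {
    stop_frailty("scores outside [0, 1] for: %s",
                 paste(variant_ids[bad], collapse = ", "), class = "data_error")
  }
  n_total <- length(s)
  n_avail <- sum(!is.na(s))
  miss_frac <- 1 - n_avail / n_total
  excluded <- miss_frac > max_missing
  fi <- if (excluded) NA_real_ else sum(s, na.rm = TRUE) / n_avail
  out <- data.frame(id = id, variant = variant, n_total = n_total,
                    n_available = n_avail, missing_fraction = miss_frac,
                    excluded = excluded, fi = fi,
                    stringsAsFactors = FALSE)
  class(out) <- c("fi_result", "data.frame")
  out
}

# Resolve the score of one deficit for all participants in a baseline table.
# Vectorised over participants; error semantics match score_deficit().
score_deficit_column <- function(baseline, definition, med_list, map) {
  n <- nrow(baseline)
  if (definition$source == "medication") {
    pats <- vapply(map$rules, `[[`, "", "pattern")
    conds <- vapply(map$rules, `[[`, "", "condition")
    my_pats <- pats[conds == definition$id]
    return(vapply(med_list, function(m) as.numeric(any(my_pats %in% m)),
                  numeric(1)))
  }
  if (definition$source == "polypharmacy") {
    return(vapply(med_list, function(m) as.numeric(polypharmacy_score(m)),
                  numeric(1)))
  }
  col <- as.numeric(baseline[[definition$id]])
  ok <- is.na(col)
  bad_at <- function(is_bad) {
    i <- which(is_bad & !is.na(col))
    if (length(i)) {
      first_bad <- score_deficit(col[i[1]], definition,
                                 participant = baseline$id[i[1]])
      stop("unreachable") # score_deficit raises with participant + deficit id
    }
  }
  switch(definition$kind,
    binary = {
      bad_at(!col %in% c(0, 1))
      col
    },
    ordinal = {
      K <- definition$n_levels
      bad_at(col != round(col) | col < 0 | col > K - 1)
      col / (K - 1)
    },
    threshold = {
      beyond <- if (definition$direction == "above") col >= definition$threshold
                else col <= definition$threshold
      as.numeric(beyond)
    }
  )
}

parse_medications <- function(x) {
  if (is.null(x)) return(rep(list(character()), 0))
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ";")[[1]])
  })
}

#' Score a full baseline table against a catalog
#'
#' Produces the participants x deficits score matrix (entries in \[0, 1\] or
#' `NA`) that underlies the frailty index. Column-sourced deficits read the
#' baseline column named by their id; medication-sourced deficits are
#' inferred from the semicolon-delimited `medications` column through the
#' catalog's medication map; the polypharmacy deficit scores 1 at five or
#' more distinct medications.
#'
#' @param baseline Baseline data frame with columns `id`, `age_years`, `sex`,
#'   `medications`, and one column per column-sourced deficit.
#' @param catalog A validated `deficit_catalog`.
#' @return Numeric matrix, rownames participant ids, colnames deficit ids.
#' @export
score_matrix <- function(baseline, catalog) {
  stopifnot(is.data.frame(baseline), inherits(catalog, "deficit_catalog"))
  if (is.null(baseline$id)) {
    stop_frailty("baseline table needs an 'id' column", class = "data_error")
  }
  ids <- catalog_ids(catalog)
  needs_meds <- any(vapply(catalog$deficits, function(d)
    d$source != "column", logical(1)))
  missing_cols <- vapply(catalog$deficits, function(d)
    d$source == "column" && is.null(baseline[[d$id]]), logical(1))
  if (any(missing_cols)) {
    stop_frailty("baseline table lacks columns for deficits: %s",
                 paste(ids[missing_cols], collapse = ", "),
                 class = "config_error")
  }
  if (needs_meds && is.null(baseline$medications)) {
    stop_frailty("catalog has medication-sourced deficits but baseline has no 'medications' column",
                 class = "config_error")
  }
  med_list <- parse_medications(baseline$medications %||% rep("", nrow(baseline)))
  m <- vapply(catalog$deficits, function(d) {
    score_deficit_column(baseline, d, med_list, catalog$medication_map)
  }, numeric(nrow(baseline)))
  m <- matrix(m, nrow = nrow(baseline),
              dimnames = list(as.character(baseline$id), ids))
  m
}

#' Compute frailty indices for every participant in a baseline table
#'
#' @inheritParams score_matrix
#' @param variant `"physical"` or `"physical_cognitive"`.
#' @param max_missing Exclusion threshold on the missing fraction
#'   (default 0.20; strictly greater is excluded).
#' @return Data frame (class `fi_table`) with one [compute_fi()] row per
#'   participant, plus attributes `variant` and `n_excluded`.
#' @export
build_fi_table <- function(baseline, catalog, variant = "physical",
                           max_missing = 0.20) {
  ids <- catalog_ids(catalog, variant)
  if (length(ids) == 0) {
    stop_frailty("variant '%s' selects no deficits", variant, class = "config_error")
  }
  m <- score_matrix(baseline, catalog)
  # vectorised equivalent of compute_fi() row by row (see tests for the
  # element-wise consistency check)
  mv <- m[, ids, drop = FALSE]
  n_total <- length(ids)
  n_avail <- rowSums(!is.na(mv))
  miss_frac <- 1 - n_avail / n_total
  excluded <- miss_frac > max_missing
  fi <- ifelse(excluded | n_avail == 0, NA_real_,
               rowSums(mv, na.rm = TRUE) / n_avail)
  out <- data.frame(id = rownames(m), variant = variant, n_total = n_total,
                    n_available = n_avail, missing_fraction = miss_frac,
                    excluded = excluded, fi = fi, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "variant") <- variant
  attr(out, "n_excluded") <- sum(out$excluded)
  class(out) <- c("fi_table", "data.frame")
  out
}

#' Frailty categories on the electronic-frailty-index cut-points
#'
#' Categorises FI values as robust (FI <= 0.12), mild (0.12 < FI <= 0.24),
#' moderate (0.24 < FI <= 0.36) or severe (FI > 0.36). Boundaries are
#' half-open on the right so that "FI > 0.24" is exactly moderate + severe.
#'
#' @param fi Numeric vector of FI values in \[0, 1\] (`NA` allowed,
#'   propagated).
#' @param boundaries Increasing internal cut-points (default
#'   `c(0.12, 0.24, 0.36)`).
#' @return Factor with levels robust, mild, moderate, severe.
#' @export
categorize_fi <- function(fi, boundaries = c(0.12, 0.24, 0.36)) {
  ok <- is.na(fi) | (fi >= 0 & fi <= 1)
  if (!all(ok)) {
    stop_frailty("FI values outside [0, 1]: %s",
                 paste(format(fi[!ok]), collapse = ", "), class = "domain_error")
  }
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  cut(fi, breaks = c(0, boundaries, 1), include.lowest = TRUE, right = TRUE,
      labels = c("robust", "mild", "moderate", "severe"))
}

#' Summarise a frailty-index sample
#'
#' Mean, SD, empirical 99th centile (linear-interpolation quantile) and
#' category prevalences (percent) of the non-excluded FI values.
#'
#' @param results An `fi_table` from [build_fi_table()], or a numeric vector
#'   of FI values.
#' @param boundaries Category cut-points, as in [categorize_fi()].
#' @param q Upper centile to report (default 0.99).
#' @return List of class `fi_summary`: `n`, `n_excluded`, `mean`, `sd`,
#'   `q99`, `prevalence` (named percentages summing to 100).
#' @export
summarize_fi <- function(results, boundaries = c(0.12, 0.24, 0.36), q = 0.99) {
  if (is.data.frame(results)) {
    n_excluded <- sum(results$excluded)
    fi <- results$fi[!results$excluded]
    variant <- attr(results, "variant") %||% NA_character_
  } else {
    fi <- results[!is.na(results)]
    n_excluded <- sum(is.na(results))
    variant <- NA_character_
  }
  if (length(fi) < 2) {
    stop_frailty("need at least 2 non-excluded FI values (got %d)", length(fi),
                 class = "empty_sample_error")
  }
  cats <- categorize_fi(fi, boundaries)
  prev <- 100 * as.numeric(table(cats)) / length(fi)
  names(prev) <- levels(cats)
  structure(
    list(variant = variant, n = length(fi), n_excluded = n_excluded,
         mean = mean(fi), sd = stats::sd(fi),
         q99 = unname(stats::quantile(fi, q, type = 7)),
         prevalence = prev, boundaries = boundaries),
    class = "fi_summary")
}

#' @export
print.fi_summary <- function(x, ...) {
  cat(sprintf("FI summary%s: n = %d (%d excluded)\n",
              if (is.na(x$variant)) "" else sprintf(" [%s]", x$variant),
              x$n, x$n_excluded))
  cat(sprintf("  mean %.3f (SD %.3f), 99th centile %.2f\n", x$mean, x$sd, x$q99))
  cat(sprintf("  robust %.1f%% | mild %.1f%% | moderate %.1f%% | severe %.1f%%\n",
              x$prevalence["robust"], x$prevalence["mild"],
              x$prevalence["moderate"], x$prevalence["severe"]))
  invisible(x)
}

#' Prevalence of frailty above a threshold
#'
#' Percentage of participants with FI strictly above `threshold`. Accepts
#' either raw FI values, an `fi_table`, an `fi_summary`, or a named vector of
#' category prevalences; for category input the threshold must coincide with
#' a category boundary (the default 0.24 gives moderate% + severe%).
#'
#' @param x FI values, `fi_table`, `fi_summary`, or named prevalence vector
#'   (percent, names among robust/mild/moderate/severe).
#' @param threshold Frailty threshold (default 0.24).
#' @param boundaries Category boundaries in force for category input.
#' @return Percentage in \[0, 100\].
#' @export
prevalence_over_threshold <- function(x, threshold = 0.24,
                                      boundaries = c(0.12, 0.24, 0.36)) {
  if (inherits(x, "fi_summary")) {
    boundaries <- x$boundaries
    x <- x$prevalence
  }
  if (is.data.frame(x)) x <- x$fi[!x$excluded]
  if (!is.null(names(x)) && all(names(x) %in% c("robust", "mild", "moderate", "severe"))) {
    cuts <- c(0, boundaries)
    pos <- which(abs(cuts - threshold) < 1e-12)
    if (length(pos) == 0) {
      stop_frailty(
        "threshold %.3f is not a category boundary; supply raw FI values instead",
        threshold, class = "config_error")
    }
    # cuts[k] is the lower edge of category k, so FI > threshold spans pos..4
    labs <- c("robust", "mild", "moderate", "severe")[pos:4]
    return(sum(x[labs], na.rm = TRUE))
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop_frailty("no FI values supplied", class = "empty_sample_error")
  100 * mean(x > threshold)
}
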