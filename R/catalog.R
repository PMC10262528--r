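#' Define a single health deficit
#'
#' A deficit is any health-related item (symptom, condition, laboratory
#' abnormality, functional limitation) whose prevalence increases with age and
#' which does not saturate too early. Each deficit maps a raw baseline
#' variable to a score in \[0, 1\].
#'
#' @param id Short, stable identifier (unique within a catalog).
#' @param label Human-readable name.
#' @param system Physiological-system tag (e.g. "cardiovascular", "renal",
#'   "cognition", "ADL", "laboratory", "clinical-measurement").
#' @param kind One of `"binary"`, `"ordinal"`, `"threshold"`.
#' @param variant_class `"physical"` or `"cognitive"`; cognitive deficits
#'   belong only to the combined physical+cognitive index variant.
#' @param n_levels Number of ordinal levels (>= 2); ordinal kind only.
#'   Raw values are 0-indexed levels `0 .. n_levels - 1`, rescaled to the
#'   grid `k / (n_levels - 1)`.
#' @param threshold Cut-point on a continuous raw variable; threshold kind
#'   only. Scored 1 when the raw value lies beyond the cut-point in
#'   `direction`, else 0.
#' @param direction `"above"` (deficit when raw >= threshold) or `"below"`
#'   (deficit when raw <= threshold); threshold kind only.
#' @param source Where the raw value comes from: `"column"` (a baseline
#'   column named `id`), `"medication"` (presence inferred from concomitant
#'   medication classes via the catalog's medication map), or
#'   `"polypharmacy"` (scored 1 when 5+ distinct medications are recorded).
#'
#' @return An object of class `deficit_definition`.
#' @export
deficit_definition <- function(id, label = id, system, kind,
                               variant_class = "physical",
                               n_levels = NULL, threshold = NULL,
                               direction = NULL, source = "column") {
  kind <- match.arg(kind, c("binary", "ordinal", "threshold"))
  variant_class <- match.arg(variant_class, c("physical", "cognitive"))
  source <- match.arg(source, c("column", "medication", "polypharmacy"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_frailty("deficit id must be a non-empty string", class = "validation_error")
  }
  if (kind == "ordinal") {
    if (is.null(n_levels) || n_levels < 2) {
      stop_frailty("deficit '%s': ordinal kind requires n_levels >= 2", id,
                   class = "validation_error")
    }
    n_levels <- as.integer(n_levels)
  } else {
    n_levels <- NULL
  }
  if (kind == "threshold") {
    if (is.null(threshold) || !is.finite(threshold)) {
      stop_frailty("deficit '%s': threshold kind requires a finite cut-point", id,
                   class = "validation_error")
    }
    if (is.null(direction)) {
      stop_frailty("deficit '%s': threshold kind requires a direction", id,
                   class = "validation_error")
    }
    direction <- match.arg(direction, c("above", "below"))
  } else {
    threshold <- NULL
    direction <- NULL
  }
  structure(
    list(id = id, label = label, system = system, kind = kind,
         variant_class = variant_class, n_levels = n_levels,
         threshold = threshold, direction = direction, source = source),
    class = "deficit_definition"
  )
}

#' Assemble a deficit catalog
#'
#' A catalog is the declarative recipe for a frailty index: an ordered list of
#' deficit definitions plus (optionally) a medication-to-condition map. The
#' standard construction criteria require at least 30 deficits spanning at
#' least 5 physiological systems; `validate_catalog()` enforces these in
#' strict mode.
#'
#' @param deficits List of [deficit_definition()] objects.
#' @param name Catalog label.
#' @param version Version string.
#' @param medication_map Optional [medication_map()].
#' @param cognitive_n Expected number of cognitive deficits (default 5);
#'   checked by `validate_catalog()` when the catalog contains any
#'   cognitive deficits.
#' @return Object of class `deficit_catalog`.
#' @export
deficit_catalog <- function(deficits, name = "catalog", version = "1",
                            medication_map = NULL, cognitive_n = 5L) {
  stopifnot(length(deficits) > 0)
  deficits <- lapply(deficits, function(d) {
    if (!inherits(d, "deficit_definition")) {
      d <- do.call(deficit_definition, d)
    }
    d
  })
  ids <- vapply(deficits, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_frailty("duplicate deficit id(s): %s", paste(dup, collapse = ", "),
                 class = "validation_error")
  }
  names(deficits) <- ids
  structure(
    list(name = name, version = as.character(version), deficits = deficits,
         medication_map = medication_map, cognitive_n = as.integer(cognitive_n)),
    class = "deficit_catalog"
  )
}

#' @export
print.deficit_catalog <- function(x, ...) {
  ids <- catalog_ids(x)
  phys <- catalog_ids(x, "physical")
  cat(sprintf("Deficit catalog '%s' (version %s)\n", x$name, x$version))
  cat(sprintf("  %d deficits: %d physical, %d cognitive; %d systems\n",
              length(ids), length(phys), length(ids) - length(phys),
              length(unique(vapply(x$deficits, `[[`, "", "system")))))
  if (!is.null(x$medication_map)) {
    cat(sprintf("  medication map: %d rules\n", length(x$medication_map$rules)))
  }
  invisible(x)
}

#' Deficit ids in a catalog, optionally restricted to an index variant
#'
#' @param catalog A `deficit_catalog`.
#' @param variant `NULL` for all deficits, `"physical"` for the physical
#'   index, or `"physical_cognitive"` for the combined index.
#' @return Character vector of deficit ids in catalog order.
#' @export
catalog_ids <- function(catalog, variant = NULL) {
  ids <- vapply(catalog$deficits, `[[`, "", "id")
  if (is.null(variant)) return(unname(ids))
  cls <- vapply(catalog$deficits, `[[`, "", "variant_class")
  if (identical(variant, "physical")) return(unname(ids[cls == "physical"]))
  if (identical(variant, "physical_cognitive")) return(unname(ids))
  stop_frailty("unknown variant '%s' (use 'physical' or 'physical_cognitive')",
               variant, class = "config_error")
}

#' Validate a deficit catalog against the standard construction criteria
#'
#' Checks: unique ids (already enforced at construction), a minimum of 30
#' deficits in the physical variant, coverage of at least 5 distinct
#' physiological systems, the configured number of cognitive deficits (when
#' any are present), and that medication-map targets exist in the catalog.
#'
#' @param catalog A `deficit_catalog`.
#' @param strict If `TRUE` (default) violations are errors; otherwise
#'   warnings.
#' @param min_physical Minimum size of the physical variant (default 30).
#' @return The catalog, invisibly, if valid.
#' @export
validate_catalog <- function(catalog, strict = TRUE, min_physical = 30L) {
  problems <- character()
  phys <- catalog_ids(catalog, "physical")
  all_ids <- catalog_ids(catalog)
  cog_n <- length(all_ids) - length(phys)
  if (length(phys) < min_physical) {
    problems <- c(problems, sprintf(
      "physical variant has %d deficits; a minimum of %d is required (ids: %s%s)",
      length(phys), min_physical, paste(utils::head(phys, 5), collapse = ", "),
      if (length(phys) > 5) ", ..." else ""))
  }
  systems <- unique(vapply(catalog$deficits, `[[`, "", "system"))
  if (length(systems) < 5) {
    problems <- c(problems, sprintf(
      "deficits span only %d physiological systems; at least 5 are required",
      length(systems)))
  }
  if (cog_n > 0 && cog_n != catalog$cognitive_n) {
    problems <- c(problems, sprintf(
      "catalog has %d cognitive deficits but declares cognitive_n = %d",
      cog_n, catalog$cognitive_n))
  }
  if (!is.null(catalog$medication_map)) {
    targets <- vapply(catalog$medication_map$rules, `[[`, "", "condition")
    missing <- setdiff(unique(targets), all_ids)
    if (length(missing)) {
      problems <- c(problems, sprintf(
        "medication map targets absent from catalog: %s",
        paste(missing, collapse = ", ")))
    }
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) stop_frailty("invalid catalog: %s", msg, class = "validation_error")
    warning(sprintf("catalog '%s': %s", catalog$name, msg), call. = FALSE)
  }
  invisible(catalog)
}

#' Medication-class to condition map
#'
#' Maps concomitant-medication class codes to condition deficits, used when a
#' trial's medical history is unavailable and comorbidity must be inferred
#' from the medications a participant takes.
#'
#' @param rules List of `list(pattern = <medication class code>,
#'   condition = <deficit id>)` entries. A medication code may appear in
#'   several rules (triggering several conditions) but each rule maps a code
#'   to exactly one condition.
#' @return Object of class `medication_map`.
#' @export
medication_map <- function(rules) {
  rules <- lapply(rules, function(r) {
    stopifnot(is.character(r$pattern), is.character(r$condition))
    list(pattern = r$pattern, condition = r$condition)
  })
  structure(list(rules = rules), class = "medication_map")
}

#' Infer condition deficits from medication class codes
#'
#' Applies every map rule to the given codes and returns the set of condition
#' deficit ids triggered. Set semantics: duplicated codes add nothing and the
#' result is idempotent. Unknown codes are not an error; their count is
#' available via the `"n_unknown"` attribute.
#'
#' @param meds Character vector of medication class codes.
#' @param map A [medication_map()].
#' @return Character vector of condition deficit ids (sorted, unique), with
#'   attribute `n_unknown` giving the number of distinct codes matching no
#'   rule.
#' @export
map_medications <- function(meds, map) {
  stopifnot(inherits(map, "medication_map"))
  meds <- unique(as.character(meds[!is.na(meds) & nzchar(meds)]))
  pats <- vapply(map$rules, `[[`, "", "pattern")
  conds <- vapply(map$rules, `[[`, "", "condition")
  hit <- conds[pats %in% meds]
  unknown <- sum(!meds %in% pats)
  structure(sort(unique(hit)), n_unknown = unknown)
}

#' Polypharmacy indicator
#'
#' Scores 1 when a participant takes five or more distinct medications
#' (deduplicated by code), else 0.
#'
#' @param meds Character vector of medication codes (duplicates allowed).
#' @param cutoff Minimum distinct-medication count (default 5).
#' @return 0 or 1.
#' @export
polypharmacy_score <- function(meds, cutoff = 5L) {
  n <- length(unique(as.character(meds[!is.na(meds) & nzchar(meds)])))
  as.integer(n >= cutoff)
}

# ---- serialization -------------------------------------------------------

catalog_to_list <- function(catalog) {
  list(
    name = catalog$name,
    version = catalog$version,
    cognitive_n = catalog$cognitive_n,
    deficits = lapply(unname(catalog$deficits), function(d) {
      Filter(Negate(is.null), d[c("id", "label", "system", "kind",
                                  "variant_class", "n_levels", "threshold",
                                  "direction", "source")])
    }),
    medication_map = if (!is.null(catalog$medication_map)) {
      lapply(catalog$medication_map$rules, function(r) {
        list(pattern = r$pattern, condition = r$condition)
      })
    }
  )
}

#' Save a deficit catalog to YAML
#'
#' @param catalog A `deficit_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_catalog()]
#' @export
save_catalog <- function(catalog, path) {
  yaml::write_yaml(catalog_to_list(catalog), path)
  invisible(path)
}

#' Load and validate a deficit catalog from YAML or JSON
#'
#' The file must contain `name`, `version` and a `deficits` list; each deficit
#' must provide `id`, `system`, `kind` plus the kind-specific fields (see
#' [deficit_definition()]). An optional `medication_map` list of
#' `pattern`/`condition` pairs is attached to the catalog. Serialization
#' round-trips: `load_catalog(save_catalog(c))` equals `c` field for field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` catalog file.
#' @param strict Passed to [validate_catalog()]; `TRUE` by default.
#' @param min_physical Passed to [validate_catalog()].
#' @return A validated `deficit_catalog`.
#' @export
load_catalog <- function(path, strict = TRUE, min_physical = 30L) {
  if (!file.exists(path)) {
    stop_frailty("catalog file not found: %s", path, class = "parse_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("name", "deficits")) {
    if (is.null(raw[[field]])) {
      stop_frailty("catalog file %s: missing required field '%s'", path, field,
                   class = "parse_error")
    }
  }
  defs <- lapply(raw$deficits, function(d) {
    if (is.null(d$id) || is.null(d$system) || is.null(d$kind)) {
      stop_frailty(
        "catalog file %s: every deficit needs 'id', 'system' and 'kind' (offending entry: %s)",
        path, paste(deparse(d), collapse = ""), class = "parse_error")
    }
    deficit_definition(
      id = d$id, label = d$label %||% d$id, system = d$system, kind = d$kind,
      variant_class = d$variant_class %||% "physical",
      n_levels = d$n_levels, threshold = d$threshold,
      direction = d$direction, source = d$source %||% "column")
  })
  map <- if (!is.null(raw$medication_map)) medication_map(raw$medication_map)
  cat_obj <- deficit_catalog(defs, name = raw$name,
                             version = raw$version %||% "1",
                             medication_map = map,
                             cognitive_n = raw$cognitive_n %||% 5L)
  validate_catalog(cat_obj, strict = strict, min_physical = min_physical)
  cat_obj
}
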