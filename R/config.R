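COUNTING_MODES <- c("per_occurrence", "once", "threshold")
CONFIG_VERSIONS <- c("v1", "v2", "v3", "v4")

#' Construct a scoring item
#'
#' One line of the risk-score catalog: a set of codes, the event kind they
#' apply to, a lookback window, a weight and a counting rule.
#'
#' @param item_id Unique identifier within a config.
#' @param category One of the eight score categories (see `CATEGORIES`).
#' @param codes Character vector of code stems; matching is exact or by
#'   prefix at a sub-code boundary ("B90" matches "B90.01"). May be empty
#'   only for visit-count threshold items.
#' @param kind Event kind the item scans (default `"diagnosis"`).
#' @param lookback_years Length of the scoring window, in years, ending at
#'   the censoring date (half-open: events strictly after
#'   `censor_date - lookback` up to and including `censor_date` count).
#' @param weight Non-negative points contributed per qualifying unit.
#' @param counting `"per_occurrence"` (weight x count), `"once"`
#'   (weight if count >= 1) or `"threshold"` (weight if count >= `min_count`).
#' @param min_count Minimum count for `"threshold"` items.
#' @param cap Optional upper bound on the points the item can contribute.
#' @param value_below For `lab_result` items: the event only qualifies when
#'   its measured value (g/L) is strictly below this threshold.
#' @return A `scoring_item` list.
#' @export
scoring_item <- function(item_id, category, codes = character(), kind = "diagnosis",
                         lookback_years, weight, counting = "per_occurrence",
                         min_count = 1, cap = Inf, value_below = NULL) {
  counting <- match.arg(counting, COUNTING_MODES)
  kind <- match.arg(kind, EVENT_KINDS)
  if (!category %in% CATEGORIES) {
    stop("scoring_item '", item_id, "': unknown category '", category, "'")
  }
  if (!is.numeric(weight) || weight < 0) {
    stop("scoring_item '", item_id, "': weight must be >= 0")
  }
  if (!is.numeric(lookback_years) || lookback_years <= 0) {
    stop("scoring_item '", item_id, "': lookback_years must be > 0")
  }
  if (length(codes) == 0 && !(counting == "threshold" && kind == "gp_visit")) {
    stop("scoring_item '", item_id,
         "': codes may be empty only for gp_visit threshold items")
  }
  structure(list(item_id = item_id, category = category,
                 codes = as.character(codes), kind = kind,
                 lookback_years = lookback_years, weight = weight,
                 counting = counting, min_count = min_count,
                 cap = if (is.null(cap)) Inf else cap,
                 value_below = value_below),
            class = "scoring_item")
}

#' Construct and validate a scoring configuration
#'
#' @param version `"v1"` to `"v4"`.
#' @param items List of [scoring_item()]s.
#' @param category_weights Named numeric vector/list over the eight
#'   categories; all 1 for version 1.
#' @param ambiguous_diagnosis_codes Codes whose registration moves the
#'   censoring date (diagnoses that can cause a secondary antibody
#'   deficiency, e.g. lymphoma).
#' @param age_window Inclusive `[min, max]` age in completed years.
#' @param cutoffs Named list of score cut-offs (classification rule is
#'   always score >= cutoff).
#' @param item_groups Optional named map item_id -> group id (version 3).
#' @param group_weights Optional named numeric vector over group ids
#'   (version 3).
#' @param extra_covariates Optional named coefficients for added variables
#'   (version 4).
#' @return A validated `scoring_config`.
#' @export
scoring_config <- function(version = "v1", items, category_weights,
                           ambiguous_diagnosis_codes = character(),
                           age_window = c(12, 70),
                           cutoffs = list(),
                           item_groups = NULL, group_weights = NULL,
                           extra_covariates = NULL) {
  version <- match.arg(version, CONFIG_VERSIONS)
  cw <- unlist(category_weights)
  if (!setequal(names(cw), CATEGORIES)) {
    stop("scoring_config: category_weights must cover exactly the 8 categories; ",
         "got: ", paste(names(cw), collapse = ", "))
  }
  if (any(cw < 0)) {
    stop("scoring_config: negative category weight for: ",
         paste(names(cw)[cw < 0], collapse = ", "))
  }
  if (version == "v1" && any(cw != 1)) {
    stop("scoring_config: version 1 requires all category weights equal to 1")
  }
  ids <- vapply(items, function(it) it$item_id, character(1))
  if (anyDuplicated(ids)) {
    stop("scoring_config: duplicate item_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (it in items) {
    if (!inherits(it, "scoring_item")) stop("scoring_config: items must be scoring_item objects")
  }
  if (version == "v3") {
    if (is.null(item_groups) || is.null(group_weights)) {
      stop("scoring_config: version 3 requires item_groups and group_weights")
    }
    ungrouped <- setdiff(ids, names(item_groups))
    if (length(ungrouped) > 0) {
      stop("scoring_config: item(s) without a group: ",
           paste(ungrouped, collapse = ", "))
    }
    gmiss <- setdiff(unlist(item_groups), names(group_weights))
    if (length(gmiss) > 0) {
      stop("scoring_config: group(s) without a weight: ",
           paste(gmiss, collapse = ", "))
    }
  }
  stopifnot(length(age_window) == 2, age_window[1] <= age_window[2])
  names(items) <- ids
  structure(list(version = version, items = items,
                 category_weights = cw[CATEGORIES],
                 ambiguous_diagnosis_codes = as.character(ambiguous_diagnosis_codes),
                 age_window = as.numeric(age_window),
                 cutoffs = cutoffs,
                 item_groups = item_groups,
                 group_weights = if (is.null(group_weights)) NULL else unlist(group_weights),
                 extra_covariates = extra_covariates),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat(sprintf("<scoring_config %s: %d items, 8 categories>\n",
              x$version, length(x$items)))
  cw <- x$category_weights
  cat("  category weights: ",
      paste(sprintf("%s=%g", names(cw), cw), collapse = ", "), "\n", sep = "")
  if (!is.null(x$item_groups)) {
    cat(sprintf("  item groups: %d groups over %d items\n",
                length(unique(unlist(x$item_groups))), length(x$item_groups)))
  }
  if (length(x$cutoffs)) {
    cat("  cutoffs: ",
        paste(sprintf("%s>=%g", names(x$cutoffs), unlist(x$cutoffs)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Load a scoring configuration from YAML
#'
#' The schema mirrors [scoring_config()]: top-level keys `version`,
#' `age_window`, `category_weights`, `ambiguous_diagnosis_codes`, `cutoffs`,
#' `items` (a sequence of item maps), and optionally `item_groups`,
#' `group_weights`, `extra_covariates`. A commented example ships at
#' `system.file("extdata", "config-v1.yaml", package = "padscreen")`.
#'
#' @param path Path to a YAML file.
#' @return A validated `scoring_config`.
#' @export
load_scoring_config <- function(path) {
  if (!file.exists(path)) stop("load_scoring_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  items <- lapply(raw$items, function(it) {
    scoring_item(item_id = it$item_id, category = it$category,
                 codes = as.character(unlist(it$codes)),
                 kind = if (is.null(it$kind)) "diagnosis" else it$kind,
                 lookback_years = it$lookback_years, weight = it$weight,
                 counting = if (is.null(it$counting)) "per_occurrence" else it$counting,
                 min_count = if (is.null(it$min_count)) 1 else it$min_count,
                 cap = if (is.null(it$cap)) Inf else it$cap,
                 value_below = it$value_below)
  })
  scoring_config(
    version = raw$version,
    items = items,
    category_weights = raw$category_weights,
    ambiguous_diagnosis_codes = as.character(unlist(raw$ambiguous_diagnosis_codes)),
    age_window = unlist(raw$age_window),
    cutoffs = raw$cutoffs,
    item_groups = raw$item_groups,
    group_weights = raw$group_weights,
    extra_covariates = raw$extra_covariates
  )
}

#' Write a scoring configuration to YAML
#'
#' @param config A `scoring_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_config <- function(config, path) {
  stopifnot(inherits(config, "scoring_config"))
  items <- lapply(unname(config$items), function(it) {
    out <- list(item_id = it$item_id, category = it$category,
                codes = as.list(it$codes), kind = it$kind,
                lookback_years = it$lookback_years, weight = it$weight,
                counting = it$counting, min_count = it$min_count)
    if (is.finite(it$cap)) out$cap <- it$cap
    if (!is.null(it$value_below)) out$value_below <- it$value_below
    out
  })
  out <- list(version = config$version,
              age_window = as.list(config$age_window),
              category_weights = as.list(config$category_weights),
              ambiguous_diagnosis_codes = as.list(config$ambiguous_diagnosis_codes),
              cutoffs = config$cutoffs,
              items = items)
  if (!is.null(config$item_groups)) out$item_groups <- config$item_groups
  if (!is.null(config$group_weights)) out$group_weights <- as.list(config$group_weights)
  if (!is.null(config$extra_covariates)) out$extra_covariates <- as.list(config$extra_covariates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The shipped default (version 1) scoring configuration
#'
#' Loads the condensed default item catalog bundled with the package:
#' eight equally weighted categories with representative ICPC-coded items.
#' The item weights are a documented, user-editable placeholder scheme --
#' the original catalog's per-item weights are not public -- so any
#' production deployment should supply its own calibrated catalog via
#' [load_scoring_config()].
#'
#' @return A `scoring_config` of version `"v1"`.
#' @export
default_scoring_config <- function() {
  load_scoring_config(system.file("extdata", "config-v1.yaml",
                                  package = "padscreen", mustWork = TRUE))
}

#' Default exclusion rules
#'
#' Code-based rules are applied automatically; `manual_only` rules can only
#' fire through a record's `manual_exclusion_flags`.
#'
#' @return A list of `exclusion_rule` lists with fields `name`,
#'   `icpc_codes`, `manual_only`.
#' @export
default_exclusion_rules <- function() {
  rule <- function(name, codes = NULL) {
    list(name = name, icpc_codes = codes, manual_only = is.null(codes))
  }
  list(
    rule("leukaemia", c("B73")),
    rule("multiple_myeloma", c("B74.01")),
    rule("HIV", c("B90", "B90.01", "B90.02")),
    rule("anorexia_bulimia", c("T06", "T06.01", "T06.02")),
    rule("cystic_fibrosis", c("T99.10")),
    rule("severe_alcohol_addiction", c("P15.01", "P15.02", "P15.03")),
    rule("hard_drug_addiction", c("P19.03")),
    rule("previously_diagnosed_immunodeficiency", c("T99.01")),
    rule("nephrotic_syndrome"),
    rule("liver_cirrhosis_stage_3_4"),
    rule("current_systemic_chemotherapy"),
    rule("current_pregnancy"),
    rule("short_life_expectancy"),
    rule("treated_by_immunologist"),
    rule("unsuitable_per_gp")
  )
}
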