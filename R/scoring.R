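#' Match event codes against configured code stems
#'
#' A code matches a stem if it is identical, extends it at a sub-code
#' boundary ("B90" matches "B90.01"), or -- for dot-free code systems such
#' as ATC prescription codes -- is a plain prefix extension ("J01" matches
#' "J01CA04").
#'
#' @param codes Character vector of event codes.
#' @param stems Character vector of configured code stems.
#' @return Logical vector: does each code match any stem?
#' @keywords internal
code_matches <- function(codes, stems) {
  if (length(stems) == 0) return(rep(TRUE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (s in stems) {
    hit <- codes == s | startsWith(codes, paste0(s, "."))
    if (!grepl(".", s, fixed = TRUE)) {
      hit <- hit | (startsWith(codes, s) & !grepl(".", codes, fixed = TRUE))
    }
    out <- out | hit
  }
  out
}

#' Censoring date for one patient
#'
#' Events are counted up to a censoring date: normally the database
#' extraction date, but moved back to the registration date of any
#' "ambiguous" diagnosis -- one that can be both a PAD complication and the
#' cause of a secondary antibody deficiency (e.g. non-Hodgkin lymphoma).
#' With several ambiguous diagnoses the earliest registration wins, the
#' most conservative choice: it discards the whole span of history that a
#' secondary deficiency could have contaminated.
#'
#' @param record A [patient_record()].
#' @param config A `scoring_config` (supplies `ambiguous_diagnosis_codes`).
#' @param extraction_date Database extraction date.
#' @return A `Date`.
#' @export
compute_censoring_date <- function(record, config, extraction_date) {
  extraction_date <- as.Date(extraction_date)
  ev <- record$events
  if (nrow(ev) == 0 || length(config$ambiguous_diagnosis_codes) == 0) {
    return(extraction_date)
  }
  amb <- ev$kind == "diagnosis" &
    code_matches(ev$code, config$ambiguous_diagnosis_codes)
  if (!any(amb)) return(extraction_date)
  d <- min(ev$date[amb])
  if (d > extraction_date) {
    stop("compute_censoring_date: ambiguous diagnosis for patient ",
         record$patient_id, " dated after the extraction date")
  }
  d
}

lookback_start <- function(censor_date, lookback_years) {
  # years converted at 365.25 days; window is half-open (start, censor]
  censor_date - round(lookback_years * 365.25)
}

#' Score a single catalog item for one patient
#'
#' Counts qualifying events in the half-open window
#' `(censor_date - lookback, censor_date]` and converts the count to points
#' according to the item's counting rule: `per_occurrence` gives
#' `weight * count`, `once` gives `weight` if the count is at least 1,
#' `threshold` gives `weight` if the count reaches `min_count`. The result
#' is capped at `item$cap` when set.
#'
#' @param record A [patient_record()].
#' @param item A [scoring_item()].
#' @param censor_date Censoring date from [compute_censoring_date()].
#' @return Non-negative points contributed by the item.
#' @export
score_item <- function(record, item, censor_date) {
  ev <- record$events
  if (nrow(ev) == 0) return(0)
  censor_date <- as.Date(censor_date)
  start <- lookback_start(censor_date, item$lookback_years)
  keep <- ev$kind == item$kind & ev$date > start & ev$date <= censor_date
  if (length(item$codes) > 0) keep <- keep & code_matches(ev$code, item$codes)
  if (!is.null(item$value_below)) {
    keep <- keep & !is.na(ev$value) & ev$value < item$value_below
  }
  n <- sum(keep)
  pts <- switch(item$counting,
    per_occurrence = item$weight * n,
    once = item$weight * (n >= 1),
    threshold = item$weight * (n >= item$min_count)
  )
  min(pts, item$cap)
}

#' Score one patient under a scoring configuration
#'
#' Sums item points per category (`category_raw`), multiplies by the
#' category weight (`category_score`) and totals the result. Under a
#' version-3 config each item's points are additionally multiplied by the
#' weight of its item group before entering the category sum.
#'
#' @param record A [patient_record()].
#' @param config A `scoring_config`.
#' @param extraction_date Database extraction date.
#' @return A `score_breakdown`: list with `patient_id`, `censor_date`,
#'   `category_raw`, `category_score`, `total`, `rank` (`NA` until
#'   [rank_population()]), `excluded`, `exclusion_reasons`.
#' @export
score_patient <- function(record, config, extraction_date) {
  censor <- compute_censoring_date(record, config, extraction_date)
  raw <- setNames(numeric(length(CATEGORIES)), CATEGORIES)
  for (it in config$items) {
    pts <- score_item(record, it, censor)
    if (!is.null(config$item_groups)) {
      g <- config$item_groups[[it$item_id]]
      if (!is.null(g)) pts <- pts * config$group_weights[[g]]
    }
    raw[it$category] <- raw[it$category] + pts
  }
  score <- raw * config$category_weights[CATEGORIES]
  structure(list(patient_id = record$patient_id,
                 censor_date = censor,
                 category_raw = raw,
                 category_score = score,
                 total = sum(score),
                 rank = NA_integer_,
                 excluded = FALSE,
                 exclusion_reasons = character()),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown %s: total %.1f%s%s>\n", x$patient_id, x$total,
              if (!is.na(x$rank)) sprintf(", rank %d", x$rank) else "",
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Apply exclusion criteria to one patient
#'
#' A patient is ineligible when any rule's ICPC codes intersect their
#' diagnosis history, when a manual exclusion flag matching a rule name is
#' set, or when their age in completed years at the extraction date falls
#' outside the configured age window.
#'
#' @param record A [patient_record()].
#' @param rules List of exclusion rules (see [default_exclusion_rules()]).
#' @param config A `scoring_config` (supplies `age_window`).
#' @param extraction_date Database extraction date.
#' @return List with `eligible` (logical) and `reasons` (character vector
#'   naming every triggered rule).
#' @export
apply_exclusions <- function(record, rules, config, extraction_date) {
  reasons <- character()
  age <- age_at(record$birth_date, extraction_date)
  if (age < config$age_window[1] || age > config$age_window[2]) {
    reasons <- c(reasons, sprintf("age outside %g-%g",
                                  config$age_window[1], config$age_window[2]))
  }
  dx <- record$events$code[record$events$kind == "diagnosis"]
  for (r in rules) {
    if (isTRUE(r$manual_only)) {
      if (r$name %in% record$manual_exclusion_flags) {
        reasons <- c(reasons, r$name)
      }
    } else if (length(dx) > 0 && any(code_matches(dx, r$icpc_codes))) {
      reasons <- c(reasons, r$name)
    } else if (r$name %in% record$manual_exclusion_flags) {
      reasons <- c(reasons, r$name)
    }
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Rank scored patients
#'
#' Rank 1 is the highest total; ties are broken by lexicographic
#' `patient_id` so the "top-k" selection is a reproducible total order.
#' Excluded patients must be removed before ranking.
#'
#' @param breakdowns List of `score_breakdown`s, none excluded.
#' @return The same list, reordered by rank, with `rank` filled.
#' @export
rank_population <- function(breakdowns) {
  if (length(breakdowns) == 0) return(breakdowns)
  ids <- vapply(breakdowns, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("rank_population: duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(vapply(breakdowns, `[[`, logical(1), "excluded"))) {
    stop("rank_population: excluded patients must be removed before ranking")
  }
  totals <- vapply(breakdowns, `[[`, numeric(1), "total")
  ord <- order(-totals, ids)
  breakdowns <- breakdowns[ord]
  for (i in seq_along(breakdowns)) breakdowns[[i]]$rank <- i
  breakdowns
}

#' Score and rank a whole population
#'
#' Applies exclusion rules (if given), scores every patient, and ranks the
#' eligible ones.
#'
#' @param pop A [population()].
#' @param config A `scoring_config`.
#' @param rules Optional list of exclusion rules; `NULL` skips exclusion.
#' @return A `data.frame` with one row per patient: `patient_id`,
#'   `censor_date`, one `score_<category>` column per category, `total`,
#'   `rank` (`NA` for excluded), `excluded`, `reasons`
#'   (semicolon-separated).
#' @export
score_population <- function(pop, config, rules = NULL) {
  stopifnot(inherits(pop, "population"))
  bds <- vector("list", length(pop$patients))
  for (i in seq_along(pop$patients)) {
    rec <- pop$patients[[i]]
    bd <- score_patient(rec, config, pop$extraction_date)
    if (!is.null(rules)) {
      ex <- apply_exclusions(rec, rules, config, pop$extraction_date)
      bd$excluded <- !ex$eligible
      bd$exclusion_reasons <- ex$reasons
    }
    bds[[i]] <- bd
  }
  excl <- vapply(bds, `[[`, logical(1), "excluded")
  ranked <- rank_population(bds[!excl])
  bds <- c(ranked, bds[excl])
  tab <- data.frame(
    patient_id = vapply(bds, `[[`, character(1), "patient_id"),
    censor_date = as.Date(vapply(bds, function(b) format(b$censor_date),
                                 character(1))),
    stringsAsFactors = FALSE
  )
  for (cat_ in CATEGORIES) {
    tab[[paste0("score_", cat_)]] <-
      vapply(bds, function(b) b$category_score[[cat_]], numeric(1))
  }
  tab$total <- vapply(bds, `[[`, numeric(1), "total")
  tab$rank <- vapply(bds, `[[`, integer(1), "rank")
  tab$excluded <- vapply(bds, `[[`, logical(1), "excluded")
  tab$reasons <- vapply(bds, function(b)
    paste(b$exclusion_reasons, collapse = ";"), character(1))
  class(tab) <- c("pad_scores", "data.frame")
  tab
}
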