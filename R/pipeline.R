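#' Construct a screening funnel
#'
#' Per-stage counts of one screening run. Counts must be non-increasing
#' along the funnel; stages that were not run may be `NA`.
#'
#' @param n_population,n_after_code_exclusions,n_step1_high_risk,n_step2_selected,n_after_manual_screen,n_invited,n_tested,n_referral_advised,n_referred,n_pad
#'   Stage counts.
#' @param participation_rate Fraction of invitees tested, in (0, 1].
#' @param trace Optional per-patient decision trace (`data.frame`).
#' @return A `screening_funnel`.
#' @export
screening_funnel <- function(n_population, n_after_code_exclusions = NA,
                             n_step1_high_risk = NA, n_step2_selected = NA,
                             n_after_manual_screen = NA, n_invited = NA,
                             n_tested = NA, n_referral_advised = NA,
                             n_referred = NA, n_pad = NA,
                             participation_rate = 1, trace = NULL) {
  counts <- c(n_population = n_population,
              n_after_code_exclusions = n_after_code_exclusions,
              n_step1_high_risk = n_step1_high_risk,
              n_step2_selected = n_step2_selected,
              n_after_manual_screen = n_after_manual_screen,
              n_invited = n_invited, n_tested = n_tested,
              n_referral_advised = n_referral_advised,
              n_referred = n_referred, n_pad = n_pad)
  known <- counts[!is.na(counts)]
  if (any(known < 0)) stop("screening_funnel: counts must be non-negative")
  if (any(diff(known) > 0)) {
    stop("screening_funnel: counts must be non-increasing along the funnel")
  }
  if (participation_rate <= 0 || participation_rate > 1) {
    stop("screening_funnel: participation_rate must be in (0, 1]")
  }
  structure(c(as.list(counts),
              list(participation_rate = participation_rate, trace = trace)),
            class = "screening_funnel")
}

#' @export
print.screening_funnel <- function(x, ...) {
  cat("<screening_funnel>\n")
  for (nm in c("n_population", "n_after_code_exclusions", "n_step1_high_risk",
               "n_step2_selected", "n_after_manual_screen", "n_invited",
               "n_tested", "n_referral_advised", "n_referred", "n_pad")) {
    cat(sprintf("  %-26s %s\n", nm,
                if (is.na(x[[nm]])) "-" else format(x[[nm]])))
  }
  invisible(x)
}

#' Run the two-step screening workflow over a population
#'
#' Step 1 applies the broad (version 1) score to separate low-risk from
#' high-risk patients at `cutoff_step1`; step 2 rescores the high-risk
#' subset with the refined (version 3) config and selects patients at
#' `cutoff_step2` for manual record screening, invitation and serum
#' immunoglobulin testing. Code-based exclusions run before scoring;
#' manual-only exclusions fire at the manual-screening stage through each
#' record's `manual_exclusion_flags`. Participation is simulated as an
#' independent seeded coin flip per invitee. When immunoglobulin `panels`
#' are supplied, referral advice (reduced immunoglobulins or the SpAD
#' high-score rule) and -- given `ground_truth` -- detected PAD counts are
#' filled in, assuming advised patients are referred.
#'
#' @param pop A [population()].
#' @param v1_config,v3_config Scoring configs for the two steps.
#' @param cutoff_step1,cutoff_step2 Selection thresholds (rule: score >=
#'   cutoff); defaults 17 and 15.5.
#' @param rules Exclusion rules, default [default_exclusion_rules()].
#' @param participation_rate Fraction of invitees who participate, (0, 1].
#' @param seed Integer seed for participation thinning.
#' @param panels Optional list of [ig_panel()]s for tested patients.
#' @param ground_truth Optional named vector patient_id -> `"case"` /
#'   `"control"`.
#' @param spad_cutoff SpAD referral threshold on the step-2 score; default
#'   taken from `v3_config$cutoffs$spad_referral`, else the top decile of
#'   tested scores.
#' @return A `screening_funnel` whose `trace` records every per-patient
#'   decision.
#' @export
run_two_step <- function(pop, v1_config, v3_config, cutoff_step1 = 17,
                         cutoff_step2 = 15.5,
                         rules = default_exclusion_rules(),
                         participation_rate = 1, seed = 1,
                         panels = NULL, ground_truth = NULL,
                         spad_cutoff = NULL) {
  stopifnot(inherits(pop, "population"))
  if (!is.numeric(cutoff_step1) || !is.numeric(cutoff_step2)) {
    stop("run_two_step: cutoffs must be numeric")
  }
  if (participation_rate <= 0 || participation_rate > 1) {
    stop("run_two_step: participation_rate must be in (0, 1]")
  }
  code_rules <- Filter(function(r) !isTRUE(r$manual_only), rules)
  manual_rules <- Filter(function(r) isTRUE(r$manual_only), rules)

  ids <- names(pop$patients)
  n <- length(ids)
  trace <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    excl[[i]] <- apply_exclusions(pop$patients[[i]], code_rules, v1_config,
                                  pop$extraction_date)
  }
  trace$excluded_code <- !vapply(excl, `[[`, logical(1), "eligible")
  trace$exclusion_reasons <- vapply(excl, function(e)
    paste(e$reasons, collapse = ";"), character(1))

  trace$v1_total <- NA_real_
  eligible <- which(!trace$excluded_code)
  for (i in eligible) {
    trace$v1_total[i] <- score_patient(pop$patients[[i]], v1_config,
                                       pop$extraction_date)$total
  }
  trace$step1_selected <- !trace$excluded_code &
    !is.na(trace$v1_total) & trace$v1_total >= cutoff_step1

  trace$v3_total <- NA_real_
  for (i in which(trace$step1_selected)) {
    trace$v3_total[i] <- score_patient(pop$patients[[i]], v3_config,
                                       pop$extraction_date)$total
  }
  trace$step2_selected <- trace$step1_selected &
    !is.na(trace$v3_total) & trace$v3_total >= cutoff_step2

  trace$manual_excluded <- FALSE
  for (i in which(trace$step2_selected)) {
    ex <- apply_exclusions(pop$patients[[i]], manual_rules, v1_config,
                           pop$extraction_date)
    trace$manual_excluded[i] <- !ex$eligible
    if (!ex$eligible) {
      trace$exclusion_reasons[i] <- paste(ex$reasons, collapse = ";")
    }
  }
  trace$invited <- trace$step2_selected & !trace$manual_excluded

  set.seed(seed)
  participates <- rep(FALSE, n)
  inv <- which(trace$invited)
  participates[inv] <- rbinom(length(inv), 1, participation_rate) == 1
  trace$tested <- participates

  trace$advice <- NA_character_
  trace$referred <- NA
  trace$is_case <- if (is.null(ground_truth)) NA else
    unname(ground_truth[ids] == "case")

  if (!is.null(panels)) {
    panel_ids <- vapply(panels, `[[`, character(1), "patient_id")
    tested_idx <- which(trace$tested)
    tested_scores <- trace$v3_total[tested_idx]
    if (is.null(spad_cutoff)) {
      spad_cutoff <- v3_config$cutoffs$spad_referral
    }
    if (is.null(spad_cutoff) && length(tested_scores) > 0) {
      spad_cutoff <- unname(quantile(tested_scores, 0.9, type = 7))
    }
    for (i in tested_idx) {
      j <- match(ids[i], panel_ids)
      if (is.na(j)) next
      fl <- flag_reduced(panels[[j]])
      trace$advice[i] <- referral_advice(fl, trace$v3_total[i],
                                         spad_cutoff = spad_cutoff)
      trace$referred[i] <- trace$advice[i] == "refer_immunology"
    }
  }

  n_advised <- if (is.null(panels)) NA_integer_ else
    sum(trace$advice == "refer_immunology", na.rm = TRUE)
  n_referred <- if (is.null(panels)) NA_integer_ else
    sum(trace$referred, na.rm = TRUE)
  n_pad <- if (is.null(panels) || is.null(ground_truth)) NA_integer_ else
    sum(trace$referred & trace$is_case, na.rm = TRUE)

  screening_funnel(
    n_population = n,
    n_after_code_exclusions = sum(!trace$excluded_code),
    n_step1_high_risk = sum(trace$step1_selected),
    n_step2_selected = sum(trace$step2_selected),
    n_after_manual_screen = sum(trace$invited),
    n_invited = sum(trace$invited),
    n_tested = sum(trace$tested),
    n_referral_advised = n_advised,
    n_referred = n_referred,
    n_pad = n_pad,
    participation_rate = participation_rate,
    trace = trace
  )
}

#' Construct a cost model
#'
#' Unit costs of the three resource-consuming stages: manual EHR
#' screening of a selected record, one serum immunoglobulin panel, and a
#' specialist work-up (two hospital visits with additional laboratory
#' assessment).
#'
#' @param cost_per_ehr_screen,cost_per_ig_panel,cost_per_specialist_workup
#'   Non-negative unit costs.
#' @param currency Currency label, default `"EUR"`.
#' @return A `cost_model` list.
#' @export
cost_model <- function(cost_per_ehr_screen, cost_per_ig_panel,
                       cost_per_specialist_workup, currency = "EUR") {
  costs <- c(cost_per_ehr_screen, cost_per_ig_panel,
             cost_per_specialist_workup)
  if (any(costs < 0)) stop("cost_model: unit costs must be non-negative")
  structure(list(cost_per_ehr_screen = cost_per_ehr_screen,
                 cost_per_ig_panel = cost_per_ig_panel,
                 cost_per_specialist_workup = cost_per_specialist_workup,
                 currency = currency),
            class = "cost_model")
}

# Truncate (not round) to 2 decimals: 5258.668 -> 5258.66, matching the
# convention of quoting a per-patient cost that is never overstated.
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Cost per detected patient
#'
#' Total screening cost divided by detected cases, truncated to two
#' decimals.
#'
#' @param total Total cost.
#' @param n_cases Detected cases (> 0).
#' @return Cost per detected case.
#' @export
cost_per_detected <- function(total, n_cases) {
  if (is.na(n_cases) || n_cases <= 0) {
    stop("cost_per_detected: undefined for n_cases <= 0")
  }
  trunc2(total / n_cases)
}

#' Estimate screening costs from a funnel
#'
#' Total cost is the sum of stage count x unit cost over manual EHR
#' screens (`n_step2_selected`), immunoglobulin panels (`n_tested`) and
#' specialist work-ups (`n_referred`). The per-detected-patient cost is
#' the total divided by `n_pad`, truncated to two decimals; with no
#' detected cases it is `NA` and flagged.
#'
#' @param funnel A `screening_funnel` (or list with the needed counts).
#' @param model A [cost_model()].
#' @return List with `total`, `per_detected`, `per_detected_defined` and a
#'   `line_items` data.frame.
#' @export
estimate_costs <- function(funnel, model) {
  stopifnot(inherits(model, "cost_model"))
  counts <- c(ehr_screen = funnel$n_step2_selected,
              ig_panel = funnel$n_tested,
              specialist_workup = funnel$n_referred)
  if (any(is.na(counts))) {
    stop("estimate_costs: funnel counts n_step2_selected, n_tested and ",
         "n_referred must be present")
  }
  unit <- c(ehr_screen = model$cost_per_ehr_screen,
            ig_panel = model$cost_per_ig_panel,
            specialist_workup = model$cost_per_specialist_workup)
  line_items <- data.frame(stage = names(counts), n = as.integer(counts),
                           unit_cost = unname(unit),
                           cost = unname(counts * unit),
                           stringsAsFactors = FALSE)
  total <- sum(line_items$cost)
  defined <- !is.na(funnel$n_pad) && funnel$n_pad > 0
  list(total = total,
       per_detected = if (defined) cost_per_detected(total, funnel$n_pad)
                      else NA_real_,
       per_detected_defined = defined,
       currency = model$currency,
       line_items = line_items)
}
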