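IG_ANALYTES <- c("igm", "iga", "igg_total", "igg1", "igg2", "igg3", "igg4",
                 "calculated_globulin")

#' Default immunoglobulin reduction thresholds (g/L)
#'
#' Adult thresholds with paediatric bands where reference values differ;
#' `paed_max_age` is the inclusive upper age (completed years) of the
#' paediatric band, which differs per analyte (16 for IgM/IgG total/IgG1,
#' 18 for the other IgG subclasses). A value is "reduced" when strictly
#' below the age-appropriate threshold. Patients aged above the paediatric
#' band use the adult threshold.
#'
#' @return A `data.frame` with columns `analyte`, `adult`, `paediatric`,
#'   `paed_max_age`.
#' @export
default_ig_thresholds <- function() {
  data.frame(
    analyte = IG_ANALYTES,
    adult = c(0.4, 0.7, 7, 4.9, 1.5, 0.20, 0.08, 18),
    paediatric = c(0.28, NA, 5.2, 3.7, 1.06, 0.18, 0.035, NA),
    paed_max_age = c(16, NA, 16, 16, 18, 18, 18, NA),
    stringsAsFactors = FALSE
  )
}

#' Construct an immunoglobulin panel
#'
#' Serum measurements for one included patient. Calculated globulin, when
#' not supplied, is derived as total protein minus albumin when both are
#' given.
#'
#' @param patient_id Identifier.
#' @param age_years Age in completed years (must be within 12-70, the
#'   screened age window).
#' @param igm,iga,igg_total,igg1,igg2,igg3,igg4 Concentrations in g/L
#'   (`NA` = not measured).
#' @param calculated_globulin g/L, optional.
#' @param total_protein,albumin g/L, used to derive calculated globulin
#'   when it is absent.
#' @param ews_score Early Warning Signs questionnaire total (0-10),
#'   optional.
#' @return An `ig_panel` list.
#' @export
ig_panel <- function(patient_id, age_years, igm = NA, iga = NA,
                     igg_total = NA, igg1 = NA, igg2 = NA, igg3 = NA,
                     igg4 = NA, calculated_globulin = NA,
                     total_protein = NA, albumin = NA, ews_score = NA) {
  if (age_years < 12 || age_years > 70) {
    stop("ig_panel: age_years must be within the screened window 12-70")
  }
  if (is.na(calculated_globulin) && !is.na(total_protein) && !is.na(albumin)) {
    calculated_globulin <- total_protein - albumin
  }
  vals <- c(igm = igm, iga = iga, igg_total = igg_total, igg1 = igg1,
            igg2 = igg2, igg3 = igg3, igg4 = igg4,
            calculated_globulin = calculated_globulin)
  if (any(!is.na(vals) & vals < 0)) {
    stop("ig_panel: negative concentration for ",
         paste(names(vals)[!is.na(vals) & vals < 0], collapse = ", "))
  }
  if (!is.na(ews_score) && (ews_score < 0 || ews_score > 10)) {
    stop("ig_panel: ews_score must be within 0-10")
  }
  structure(c(list(patient_id = patient_id, age_years = age_years),
              as.list(vals), list(ews_score = ews_score)),
            class = "ig_panel")
}

#' Flag reduced immunoglobulins with age-banded thresholds
#'
#' Each measured analyte is compared strictly against the age-appropriate
#' threshold; unmeasured analytes yield `NA` flags, never positive ones.
#'
#' @param panel An [ig_panel()].
#' @param thresholds Threshold table as from [default_ig_thresholds()].
#' @return A `reduction_flags` list: `reduced` (named logical over
#'   analytes), `any_reduced_excluding_igg4`, `isolated_igg4_only`.
#' @export
flag_reduced <- function(panel, thresholds = default_ig_thresholds()) {
  stopifnot(inherits(panel, "ig_panel"))
  if (!all(IG_ANALYTES %in% thresholds$analyte)) {
    stop("flag_reduced: thresholds table incomplete")
  }
  red <- setNames(rep(NA, length(IG_ANALYTES)), IG_ANALYTES)
  for (a in IG_ANALYTES) {
    v <- panel[[a]]
    if (is.na(v)) next
    row <- thresholds[thresholds$analyte == a, ]
    thr <- row$adult
    if (!is.na(row$paed_max_age) && panel$age_years <= row$paed_max_age) {
      thr <- row$paediatric
    }
    red[a] <- v < thr
  }
  others <- red[setdiff(IG_ANALYTES, "igg4")]
  structure(list(
    reduced = red,
    any_reduced_excluding_igg4 = any(others, na.rm = TRUE),
    isolated_igg4_only = isTRUE(red[["igg4"]]) && !any(others, na.rm = TRUE)
  ), class = "reduction_flags")
}

#' Referral advice for one tested patient
#'
#' Referral to an immunologist is advised when any immunoglobulin other
#' than IgG4 is reduced, or -- to catch specific antibody deficiency
#' (SpAD), which presents with normal immunoglobulins -- when the patient's
#' refined algorithm score is high: at or above an explicit `spad_cutoff`,
#' or within the top decile of `population_scores`. An isolated reduced
#' IgG4 alone never triggers referral (little clinical relevance). An
#' optional elevated-immunoglobulin rule, off by default, advises an
#' internist consult for incidental elevations.
#'
#' @param flags A `reduction_flags` from [flag_reduced()].
#' @param v_score The patient's refined (e.g. version-3) algorithm score.
#' @param spad_cutoff Explicit score cutoff for the SpAD rule (e.g. 21.5).
#' @param population_scores Refined scores of the tested population; used
#'   to derive the top-decile SpAD cutoff when `spad_cutoff` is `NULL`.
#' @param elevated Logical: incidental immunoglobulin elevation present?
#' @param elevated_rule_enabled Logical: is the internist-consult branch
#'   configured on?
#' @return One of `"refer_immunology"`, `"no_referral"`,
#'   `"consult_internist_elevated"`.
#' @export
referral_advice <- function(flags, v_score, spad_cutoff = NULL,
                            population_scores = NULL, elevated = FALSE,
                            elevated_rule_enabled = FALSE) {
  stopifnot(inherits(flags, "reduction_flags"))
  if (flags$any_reduced_excluding_igg4) return("refer_immunology")
  if (is.null(spad_cutoff) && is.null(population_scores)) {
    stop("referral_advice: supply spad_cutoff or population_scores ",
         "(the SpAD rule needs a score context when no immunoglobulin ",
         "is reduced)")
  }
  if (is.null(spad_cutoff)) {
    spad_cutoff <- unname(quantile(population_scores, 0.9, type = 7))
  }
  if (!is.na(v_score) && v_score >= spad_cutoff) return("refer_immunology")
  if (elevated_rule_enabled && isTRUE(elevated)) {
    return("consult_internist_elevated")
  }
  "no_referral"
}

#' Final outcome label for one included patient
#'
#' @param advice Advice from [referral_advice()].
#' @param referred Was the patient actually referred?
#' @param nonreferral_valid For advised-but-not-referred patients: was the
#'   GP's reason adjudicated valid (e.g. a sufficient alternative
#'   explanation) or invalid (PAD not excluded)?
#' @param diagnosis For referred patients: `"PAD_confirmed"`,
#'   `"PAD_excluded"` or `"indeterminate"`.
#' @return One of `"PAD"`, `"unlikely_PAD"`, `"inconclusive"`.
#' @export
classify_outcome <- function(advice, referred, nonreferral_valid = NULL,
                             diagnosis = NULL) {
  advice <- match.arg(advice, c("refer_immunology", "no_referral",
                                "consult_internist_elevated"))
  if (referred) {
    if (is.null(diagnosis)) {
      stop("classify_outcome: referred patients need a diagnosis outcome")
    }
    diagnosis <- match.arg(diagnosis,
                           c("PAD_confirmed", "PAD_excluded", "indeterminate"))
    return(switch(diagnosis,
                  PAD_confirmed = "PAD",
                  PAD_excluded = "unlikely_PAD",
                  indeterminate = "inconclusive"))
  }
  if (advice != "refer_immunology") return("unlikely_PAD")
  if (is.null(nonreferral_valid)) {
    stop("classify_outcome: advised but not referred needs a validity ",
         "adjudication")
  }
  if (isTRUE(nonreferral_valid)) "unlikely_PAD" else "inconclusive"
}
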