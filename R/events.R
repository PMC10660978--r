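EVENT_KINDS <- c("diagnosis", "antibiotic_prescription", "lab_result", "gp_visit")
SEX_LEVELS <- c("F", "M", "U")

CATEGORIES <- c(
  "antibiotics", "rti", "gi", "other_infections", "autoimmune",
  "malignancy_lymphoproliferative_other", "laboratory", "gp_visits"
)

#' Construct a coded EHR event
#'
#' A coded event is one line of a patient's primary-care record: an ICPC-coded
#' diagnosis, an antibiotic prescription, a laboratory result (in g/L) or a GP
#' visit.
#'
#' @param code Character code (ICPC-1 dialect for diagnoses, e.g. "B90.01";
#'   an analyte code such as "IGG" for laboratory results). May be empty only
#'   for GP visits.
#' @param kind One of `"diagnosis"`, `"antibiotic_prescription"`,
#'   `"lab_result"`, `"gp_visit"`.
#' @param date Event date (`Date` or ISO-8601 string).
#' @param value Numeric measurement in g/L; required for (and only allowed
#'   with) `kind = "lab_result"`.
#' @return A one-row `data.frame` with columns `code`, `kind`, `date`, `value`.
#' @export
coded_event <- function(code, kind, date, value = NA_real_) {
  kind <- match.arg(kind, EVENT_KINDS)
  date <- as.Date(date)
  if (is.na(date)) stop("coded_event: invalid date")
  code <- as.character(code)
  if (kind != "gp_visit" && (is.na(code) || !nzchar(code))) {
    stop("coded_event: code must be non-empty for kind '", kind, "'")
  }
  if (kind == "lab_result" && is.na(value)) {
    stop("coded_event: lab_result requires a numeric value")
  }
  if (kind != "lab_result" && !is.na(value)) {
    stop("coded_event: value only allowed for lab_result events")
  }
  data.frame(code = code, kind = kind, date = date, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(code = character(), kind = character(),
             date = as.Date(character()), value = numeric(),
             stringsAsFactors = FALSE)
}

sort_events <- function(events) {
  if (nrow(events) == 0) return(events)
  # stable sort: (date, insertion index) is a total order
  events[order(events$date), , drop = FALSE]
}

#' Construct a patient record
#'
#' @param patient_id Opaque identifier, unique within a population.
#' @param birth_date Birth date (`Date` or ISO string).
#' @param sex `"F"`, `"M"` or `"U"` (unknown/other).
#' @param events `data.frame` of events as produced by [coded_event()] (rows
#'   are bound together); sorted by date on construction.
#' @param manual_exclusion_flags Character vector of manually applied
#'   exclusion-rule names (e.g. `"current_pregnancy"`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, birth_date, sex = "U",
                           events = empty_events(),
                           manual_exclusion_flags = character()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  sex <- match.arg(sex, SEX_LEVELS)
  birth_date <- as.Date(birth_date)
  if (is.na(birth_date)) stop("patient_record: invalid birth_date")
  if (!all(c("code", "kind", "date", "value") %in% names(events))) {
    stop("patient_record: events must have columns code, kind, date, value")
  }
  events$date <- as.Date(events$date)
  rec <- list(
    patient_id = patient_id,
    birth_date = birth_date,
    sex = sex,
    events = sort_events(events),
    manual_exclusion_flags = as.character(manual_exclusion_flags)
  )
  class(rec) <- "patient_record"
  rec
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: born %s, sex %s, %d events>\n",
              x$patient_id, format(x$birth_date), x$sex, nrow(x$events)))
  invisible(x)
}

#' Construct a population of patient records
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @param extraction_date Database extraction date; every event must fall on
#'   or before it.
#' @return An object of class `population`.
#' @export
population <- function(patients, extraction_date) {
  extraction_date <- as.Date(extraction_date)
  if (is.na(extraction_date)) stop("population: invalid extraction_date")
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("population: duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (p in patients) {
    if (nrow(p$events) > 0 && any(p$events$date > extraction_date)) {
      stop("population: patient ", p$patient_id,
           " has events after the extraction date")
    }
  }
  names(patients) <- ids
  pop <- list(patients = patients, extraction_date = extraction_date)
  class(pop) <- "population"
  pop
}

#' @export
print.population <- function(x, ...) {
  n_ev <- sum(vapply(x$patients, function(p) nrow(p$events), integer(1)))
  cat(sprintf("<population: %d patients, %d events, extracted %s>\n",
              length(x$patients), n_ev, format(x$extraction_date)))
  invisible(x)
}

#' @export
length.population <- function(x) length(x$patients)

#' Age in completed years at a reference date
#'
#' @param birth_date,at `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, at) {
  birth_date <- as.Date(birth_date)
  at <- as.Date(at)
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - before_birthday)
}
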