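GEN_EVENT_CATEGORIES <- c("antibiotics", "rti", "gi", "other_infections",
                          "autoimmune", "malignancy", "gp_visits")

# mini ICPC/ATC vocabulary matching the default item catalog
GEN_CODE_POOLS <- list(
  antibiotics = c("J01CA04", "J01FA09", "J01AA02", "J01CE02"),
  rti = c("R78", "R75", "R74", "R81", "H71", "R76", "R80"),
  rti_weights = c(0.3, 0.22, 0.22, 0.08, 0.08, 0.07, 0.03),
  gi = c("D73", "D70", "D11"),
  gi_weights = c(0.5, 0.2, 0.3),
  other_infections = c("S76", "S70", "N71", "L70.01", "A78"),
  other_weights = c(0.45, 0.40, 0.05, 0.05, 0.05),
  autoimmune = c("L88", "D94", "T86", "B83", "B81"),
  malignancy = c("B02", "B87", "R95.01", "A79"),
  exclusion = c("B73", "B90", "T06", "P15.01", "T99.10"),
  ambiguous = c("B72", "B74.02")
)

# generation window (years) per event category; wide enough to cover the
# default catalog's lookbacks
GEN_WINDOW_YEARS <- c(antibiotics = 4, rti = 4, gi = 4, other_infections = 4,
                      autoimmune = 10, malignancy = 10, gp_visits = 2)

#' Specification for a synthetic primary-care population
#'
#' Defaults emulate the validated study conditions: a PAD prevalence
#' within the reported 1:1,700-1:25,000 range (default 1:5,000), cases
#' with elevated antibiotic-prescription and respiratory-infection rates
#' (about 5 prescriptions and 5 RTI codes per 4 years, versus about 1-1.5
#' in controls), frequent GP attendance in cases, a code-based exclusion
#' fraction of 8.6%, and immunoglobulin levels drawn log-normally around
#' the reported group medians (e.g. total IgG median ~7.3 g/L in cases vs
#' ~9.9 g/L in controls, putting ~50% vs ~4% of patients below the 7 g/L
#' threshold).
#'
#' @param n_patients Number of records to generate.
#' @param prevalence PAD prevalence as a fraction (e.g. `1/5000`).
#' @param seed Integer seed; generation is deterministic per seed.
#' @param case_rates,control_rates Named yearly event rates per category
#'   (`antibiotics`, `rti`, `gi`, `other_infections`, `autoimmune`,
#'   `malignancy`, `gp_visits`).
#' @param dispersion Negative-binomial size parameter for event counts
#'   (smaller = more overdispersed).
#' @param exclusion_code_rate Fraction of patients carrying a code-based
#'   exclusion diagnosis.
#' @param ambiguous_code_rate Fraction carrying an ambiguous
#'   (censoring-date) diagnosis.
#' @param ig_params Named list per group (`case`, `control`) of data.frames
#'   with columns `analyte`, `meanlog`, `sdlog`; defaults from
#'   `default_ig_params()`.
#' @param age_range Target age range (completed years) of generated
#'   patients.
#' @param force_min_cases Logical: plant exactly
#'   `round(n_patients * prevalence)` cases instead of drawing the case
#'   count binomially.
#' @param extraction_date Extraction date of the generated database.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_patients,
                           prevalence = 1 / 5000,
                           seed = 1,
                           case_rates = c(antibiotics = 1.25, rti = 1.4,
                                          gi = 0.3, other_infections = 0.02,
                                          autoimmune = 0.06, malignancy = 0.25,
                                          gp_visits = 9),
                           control_rates = c(antibiotics = 0.3, rti = 0.35,
                                             gi = 0.15,
                                             other_infections = 0.005,
                                             autoimmune = 0.03,
                                             malignancy = 0.05,
                                             gp_visits = 3),
                           dispersion = 1.5,
                           exclusion_code_rate = 0.086,
                           ambiguous_code_rate = 0.002,
                           ig_params = default_ig_params(),
                           age_range = c(13, 69),
                           force_min_cases = FALSE,
                           extraction_date = as.Date("2022-02-08")) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("generator_spec: prevalence must be in (0, 1)")
  }
  for (r in list(case_rates, control_rates)) {
    if (!all(GEN_EVENT_CATEGORIES %in% names(r))) {
      stop("generator_spec: rates must name all of: ",
           paste(GEN_EVENT_CATEGORIES, collapse = ", "))
    }
    if (any(r < 0)) stop("generator_spec: rates must be non-negative")
  }
  if (case_rates[["rti"]] < control_rates[["rti"]] ||
        case_rates[["antibiotics"]] < control_rates[["antibiotics"]]) {
    stop("generator_spec: case RTI/antibiotic rates must be >= control rates")
  }
  if (force_min_cases && round_half_up(n_patients * prevalence) < 1) {
    stop("generator_spec: infeasible spec, prevalence x n < 1 case with ",
         "force_min_cases")
  }
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 seed = seed, case_rates = case_rates,
                 control_rates = control_rates, dispersion = dispersion,
                 exclusion_code_rate = exclusion_code_rate,
                 ambiguous_code_rate = ambiguous_code_rate,
                 ig_params = ig_params, age_range = age_range,
                 force_min_cases = force_min_cases,
                 extraction_date = as.Date(extraction_date)),
            class = "generator_spec")
}

#' Default immunoglobulin generating parameters
#'
#' Log-normal location (log of the group median) and scale per analyte,
#' per group.
#'
#' @return Named list with `case` and `control` data.frames.
#' @export
default_ig_params <- function() {
  analytes <- IG_ANALYTES
  case <- data.frame(
    analyte = analytes,
    meanlog = log(c(0.52, 2.07, 7.28, 5.00, 1.61, 0.22, 0.24, 27.0)),
    sdlog = c(0.55, 0.40, 0.30, 0.30, 0.45, 0.38, 0.55, 0.08),
    stringsAsFactors = FALSE
  )
  control <- data.frame(
    analyte = analytes,
    meanlog = log(c(0.98, 2.09, 9.89, 6.80, 2.60, 0.22, 0.33, 30.0)),
    sdlog = c(0.46, 0.50, 0.195, 0.25, 0.35, 0.15, 0.65, 0.10),
    stringsAsFactors = FALSE
  )
  list(case = case, control = control)
}

sample_codes <- function(category, n) {
  pools <- GEN_CODE_POOLS
  switch(category,
    antibiotics = sample(pools$antibiotics, n, replace = TRUE),
    rti = sample(pools$rti, n, replace = TRUE, prob = pools$rti_weights),
    gi = sample(pools$gi, n, replace = TRUE, prob = pools$gi_weights),
    other_infections = sample(pools$other_infections, n, replace = TRUE,
                              prob = pools$other_weights),
    autoimmune = sample(pools$autoimmune, n, replace = TRUE),
    malignancy = sample(pools$malignancy, n, replace = TRUE),
    gp_visits = rep("", n)
  )
}

#' Generate a synthetic population with planted PAD cases
#'
#' Event counts per category are drawn from a negative-binomial process
#' (overdispersed relative to Poisson, matching the wide interquartile
#' ranges seen in real prescription counts) over category-specific
#' observation windows ending at the extraction date; event dates are
#' uniform within the window. Cases use elevated rates. A configurable
#' fraction of patients receives a code-based exclusion diagnosis or an
#' ambiguous (censoring) diagnosis. Immunoglobulin panels are drawn
#' log-normally per group. Everything is deterministic given the spec's
#' seed.
#'
#' @param spec A [generator_spec()].
#' @return List with `population` (a [population()]), `ground_truth`
#'   (named vector patient_id -> `"case"`/`"control"`) and `panels`
#'   (named list of [ig_panel()]s).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  if (spec$force_min_cases) {
    n_cases <- round_half_up(n * spec$prevalence)
    is_case <- seq_len(n) %in% sample(n, n_cases)
  } else {
    is_case <- runif(n) < spec$prevalence
  }
  extraction <- spec$extraction_date

  patients <- vector("list", n)
  panels <- vector("list", n)
  for (i in seq_len(n)) {
    rates <- if (is_case[i]) spec$case_rates else spec$control_rates
    ev_list <- list()
    for (cat_ in GEN_EVENT_CATEGORIES) {
      win <- GEN_WINDOW_YEARS[[cat_]]
      mu <- rates[[cat_]] * win
      k <- if (mu == 0) 0L else rnbinom(1, size = spec$dispersion, mu = mu)
      if (k == 0) next
      days <- sort(sample.int(round(win * 365.25), k, replace = TRUE))
      kind <- switch(cat_, antibiotics = "antibiotic_prescription",
                     gp_visits = "gp_visit", "diagnosis")
      ev_list[[cat_]] <- data.frame(
        code = sample_codes(cat_, k), kind = kind,
        date = extraction - days, value = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (runif(1) < spec$exclusion_code_rate) {
      ev_list$exclusion <- data.frame(
        code = sample(GEN_CODE_POOLS$exclusion, 1), kind = "diagnosis",
        date = extraction - sample.int(3652, 1), value = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (runif(1) < spec$ambiguous_code_rate) {
      ev_list$ambiguous <- data.frame(
        code = sample(GEN_CODE_POOLS$ambiguous, 1), kind = "diagnosis",
        date = extraction - sample.int(2500, 1), value = NA_real_,
        stringsAsFactors = FALSE)
    }
    events <- if (length(ev_list)) do.call(rbind, ev_list) else empty_events()
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1)
    birth <- extraction - round((age + runif(1, 0.05, 0.9)) * 365.25)
    patients[[i]] <- patient_record(
      patient_id = ids[i], birth_date = birth,
      sex = sample(c("F", "M"), 1), events = events)

    grp <- if (is_case[i]) "case" else "control"
    par <- spec$ig_params[[grp]]
    vals <- setNames(rlnorm(nrow(par), par$meanlog, par$sdlog), par$analyte)
    ews_p <- if (is_case[i]) 0.35 else 0.2
    panels[[i]] <- ig_panel(
      patient_id = ids[i], age_years = age,
      igm = vals[["igm"]], iga = vals[["iga"]],
      igg_total = vals[["igg_total"]], igg1 = vals[["igg1"]],
      igg2 = vals[["igg2"]], igg3 = vals[["igg3"]], igg4 = vals[["igg4"]],
      calculated_globulin = vals[["calculated_globulin"]],
      ews_score = rbinom(1, 10, ews_p))
  }
  names(panels) <- ids
  list(population = population(patients, extraction),
       ground_truth = setNames(ifelse(is_case, "case", "control"), ids),
       panels = panels)
}

#' A hand-written 12-patient worked fixture
#'
#' Small deterministic population whose version-1 scores under the shipped
#' default config are known by hand; the independently computed score
#' table ships at
#' `system.file("extdata", "worked-fixture-scores.csv", package = "padscreen")`.
#' Used as the documentation example and as an oracle anchor in tests.
#'
#' @return List with `population`, `labels` (named expected totals) and
#'   `expected` (the committed score table as a data.frame).
#' @export
make_worked_fixture <- function() {
  x <- as.Date  # brevity
  ev <- function(...) rbind(...)
  gp <- function(dates) do.call(rbind, lapply(dates, function(d)
    coded_event("", "gp_visit", d)))
  dx <- function(code, dates) do.call(rbind, lapply(dates, function(d)
    coded_event(code, "diagnosis", d)))
  rx <- function(dates) do.call(rbind, lapply(dates, function(d)
    coded_event("J01CA04", "antibiotic_prescription", d)))

  extraction <- x("2022-02-08")
  pts <- list(
    # A: empty record -> 0
    patient_record("FIX-A", x("1980-05-01"), "F"),
    # B: 8 GP visits in the last year -> frequent_gp_visits fires -> 3
    patient_record("FIX-B", x("1975-03-10"), "M",
      gp(paste0("2021-", sprintf("%02d", 3:10), "-15"))),
    # C: 5 antibiotic prescriptions in 4 years -> 5 x 1.5 = 7.5
    patient_record("FIX-C", x("1990-11-20"), "F",
      rx(c("2019-01-10", "2019-08-02", "2020-03-15", "2021-02-01",
           "2021-11-11"))),
    # D: 2 pneumonia + 1 sinusitis -> 2 x 2.5 + 1.5 = 6.5
    patient_record("FIX-D", x("1968-07-07"), "M",
      ev(dx("R81", c("2020-01-05", "2021-06-20")),
         dx("R75", "2020-10-10"))),
    # E: HIV code -> excluded; 3 prescriptions still score 4.5
    patient_record("FIX-E", x("1985-01-01"), "M",
      ev(dx("B90.01", "2015-06-01"),
         rx(c("2020-01-01", "2020-06-01", "2021-01-01")))),
    # F: lymphoma 2019-05-01 censors; only the 2 earlier prescriptions
    # count -> 3.0
    patient_record("FIX-F", x("1972-09-09"), "F",
      ev(dx("B72", "2019-05-01"),
         rx(c("2018-01-10", "2018-06-10", "2020-02-01", "2020-09-01",
              "2021-05-01")))),
    # G: 6 rx (9) + 4 bronchitis (6) + 1 GI infection (2) + RA (1.5)
    #    + lymphadenopathy (1) + 7 GP visits (3) = 22.5
    patient_record("FIX-G", x("1960-12-01"), "F",
      ev(rx(c("2019-03-01", "2019-09-01", "2020-03-01", "2020-09-01",
              "2021-03-01", "2021-09-01")),
         dx("R78", c("2019-04-01", "2020-04-01", "2020-11-01", "2021-04-01")),
         dx("D73", "2021-01-15"),
         dx("L88", "2015-05-05"),
         dx("B02", "2014-03-01"),
         gp(c("2021-03-05", "2021-04-05", "2021-06-05", "2021-08-05",
              "2021-10-05", "2021-12-05", "2022-01-05")))),
    # H: recorded low IgM (0.30 g/L) -> 5; one URI -> 1; total 6.0
    patient_record("FIX-H", x("1995-02-14"), "M",
      ev(coded_event("IGM", "lab_result", "2020-03-15", 0.30),
         dx("R74", "2021-01-01"))),
    # I: everything outside its lookback window -> 0
    patient_record("FIX-I", x("1979-04-04"), "F",
      ev(rx("2017-06-01"),
         dx("L88", "2011-06-01"))),
    # J: exactly 6 GP visits in the last year -> threshold met -> 3
    patient_record("FIX-J", x("1988-08-08"), "M",
      gp(c("2021-03-01", "2021-05-01", "2021-07-01", "2021-09-01",
           "2021-11-01", "2022-01-10"))),
    # K: age 10 -> excluded by age window; no events -> 0
    patient_record("FIX-K", x("2011-06-15"), "F"),
    # L: once-counted items: 3 x IBD (1.5 once) + splenomegaly (1.5) = 3.0
    patient_record("FIX-L", x("1955-10-30"), "M",
      ev(dx("D94", c("2016-01-01", "2018-01-01", "2020-01-01")),
         dx("B87", "2019-07-01")))
  )
  expected <- utils::read.csv(system.file("extdata",
                                          "worked-fixture-scores.csv",
                                          package = "padscreen",
                                          mustWork = TRUE),
                              stringsAsFactors = FALSE)
  list(population = population(pts, extraction),
       labels = setNames(expected$total, expected$patient_id),
       expected = expected)
}
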