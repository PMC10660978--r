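cfg <- default_scoring_config()
extraction <- as.Date("2022-02-08")

test_that("censoring date is the extraction date without ambiguous codes", {
  rec <- patient_record("P", "1980-01-01", "F",
                        coded_event("R74", "diagnosis", "2020-05-01"))
  expect_equal(compute_censoring_date(rec, cfg, extraction), extraction)
})

test_that("an ambiguous diagnosis moves the censoring date; earliest wins", {
  rec <- patient_record("P", "1970-01-01", "M",
                        coded_event("B72", "diagnosis", "2019-05-01"))
  expect_equal(compute_censoring_date(rec, cfg, extraction),
               as.Date("2019-05-01"))
  rec2 <- patient_record("P", "1970-01-01", "M", rbind(
    coded_event("B72", "diagnosis", "2020-01-01"),
    coded_event("B74.02", "diagnosis", "2018-01-01")))
  expect_equal(compute_censoring_date(rec2, cfg, extraction),
               as.Date("2018-01-01"))
})

test_that("score_item implements the three counting rules and the cap", {
  empty <- patient_record("P", "1980-01-01", "F")
  for (it in cfg$items) expect_equal(score_item(empty, it, extraction), 0)

  # >= 6 GP visits per year, weight 3: 8 visits in the window score 3
  visits <- do.call(rbind, lapply(sprintf("2021-%02d-15", 3:10), function(d)
    coded_event("", "gp_visit", d)))
  rec <- patient_record("P", "1980-01-01", "F", visits)
  expect_equal(score_item(rec, cfg$items$frequent_gp_visits, extraction), 3)

  # per-occurrence with a cap: weight 2, 5 events, cap 8 -> 8
  it <- scoring_item("capped", "rti", "R78", lookback_years = 4,
                     weight = 2, counting = "per_occurrence", cap = 8)
  rec5 <- patient_record("P", "1980-01-01", "F", do.call(rbind,
    lapply(sprintf("2021-%02d-01", 1:5), function(d)
      coded_event("R78", "diagnosis", d))))
  expect_equal(score_item(rec5, it, extraction), 8)
  expect_equal(score_item(rec5, scoring_item("u", "rti", "R78",
                                             lookback_years = 4, weight = 2),
                          extraction), 10)
})

test_that("lookback windows are half-open and censor-bounded", {
  it <- scoring_item("w", "rti", "R78", lookback_years = 1, weight = 1)
  boundary <- extraction - 365  # exactly at the window start: excluded
  inside <- extraction - 364
  rec <- patient_record("P", "1980-01-01", "F", rbind(
    coded_event("R78", "diagnosis", boundary),
    coded_event("R78", "diagnosis", inside),
    coded_event("R78", "diagnosis", extraction)))
  expect_equal(score_item(rec, it, extraction), 2)
})

test_that("code prefix matching covers sub-codes and dot-free systems", {
  it <- scoring_item("hiv_like", "rti", "B90", lookback_years = 4, weight = 1)
  rec <- patient_record("P", "1980-01-01", "F", rbind(
    coded_event("B90", "diagnosis", "2021-01-01"),
    coded_event("B90.01", "diagnosis", "2021-02-01"),
    coded_event("B900", "diagnosis", "2021-03-01"),  # dot-free extension
    coded_event("B9", "diagnosis", "2021-04-01")))   # shorter: no match
  expect_equal(score_item(rec, it, extraction), 3)
})

test_that("empty record scores zero; GP-visit-only record scores 3 under v1", {
  empty <- patient_record("P", "1980-01-01", "F")
  bd <- score_patient(empty, cfg, extraction)
  expect_equal(bd$total, 0)
  expect_true(all(bd$category_score == 0))
  fx <- make_worked_fixture()
  bd_b <- score_patient(fx$population$patients[["FIX-B"]], cfg, extraction)
  expect_equal(bd_b$total, 3)
  expect_equal(unname(bd_b$category_score[["gp_visits"]]), 3)
})

test_that("totals equal the independent double-loop oracle on random records", {
  for (s in 1:30) {
    rec <- random_record(sprintf("R%02d", s), seed = 1000 + s)
    bd <- score_patient(rec, cfg, extraction)
    expect_equal(bd$total, bf_total_score(rec, cfg, extraction),
                 info = paste("seed", s))
    # conservation: total is the sum of the category scores
    expect_equal(bd$total, sum(bd$category_score))
    expect_equal(unname(bd$category_score),
                 unname(bd$category_raw * cfg$category_weights[names(bd$category_raw)]))
  }
})

test_that("scores are invariant to event-list permutation", {
  for (s in 1:5) {
    rec <- random_record("P", seed = 2000 + s)
    set.seed(s)
    perm <- rec$events[sample(nrow(rec$events)), , drop = FALSE]
    rec2 <- patient_record("P", rec$birth_date, rec$sex, perm)
    expect_equal(score_patient(rec2, cfg, extraction)$total,
                 score_patient(rec, cfg, extraction)$total)
  }
})

test_that("adding a scoring event never decreases the total (monotonicity)", {
  for (s in 1:10) {
    rec <- random_record("P", seed = 3000 + s)
    base <- score_patient(rec, cfg, extraction)$total
    extra <- coded_event("R81", "diagnosis", "2021-12-01")
    rec2 <- patient_record("P", rec$birth_date, rec$sex,
                           rbind(rec$events, extra))
    expect_gte(score_patient(rec2, cfg, extraction)$total, base)
  }
})

test_that("exclusion rules fire on codes, flags and age", {
  rules <- default_exclusion_rules()
  hiv <- patient_record("P", "1980-01-01", "M",
                        coded_event("B90", "diagnosis", "2015-01-01"))
  res <- apply_exclusions(hiv, rules, cfg, extraction)
  expect_false(res$eligible)
  expect_true("HIV" %in% res$reasons)

  clean <- patient_record("P", "1981-06-01", "F")  # age 40
  expect_true(apply_exclusions(clean, rules, cfg, extraction)$eligible)

  old <- patient_record("P", "1946-06-01", "F")  # age 75
  res_old <- apply_exclusions(old, rules, cfg, extraction)
  expect_false(res_old$eligible)
  expect_match(res_old$reasons, "age outside 12-70", all = FALSE)

  preg <- patient_record("P", "1990-01-01", "F",
                         manual_exclusion_flags = "current_pregnancy")
  res_p <- apply_exclusions(preg, rules, cfg, extraction)
  expect_false(res_p$eligible)
  expect_true("current_pregnancy" %in% res_p$reasons)
})

test_that("ranking orders by total, breaks ties by patient id", {
  mk <- function(id, total) {
    bd <- score_patient(patient_record(id, "1980-01-01", "F"), cfg, extraction)
    bd$total <- total
    bd
  }
  r <- rank_population(list(mk("a", 30), mk("b", 10), mk("c", 20)))
  expect_equal(vapply(r, `[[`, character(1), "patient_id"), c("a", "c", "b"))
  expect_equal(vapply(r, `[[`, integer(1), "rank"), 1:3)

  # ties: adjacent ranks in id order under every input permutation
  tied <- list(mk("zz", 5), mk("aa", 5), mk("mm", 5))
  for (p in list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- rank_population(tied[p])
    expect_equal(vapply(r, `[[`, character(1), "patient_id"),
                 c("aa", "mm", "zz"))
    expect_equal(vapply(r, `[[`, integer(1), "rank"), 1:3)
  }

  expect_error(rank_population(list(mk("a", 1), mk("a", 2))), "duplicate")
})

test_that("rank permutation equals an independent sort on 1,000 totals", {
  set.seed(9)
  totals <- sample(0:60, 1000, replace = TRUE) + sample(c(0, 0.5), 1000, TRUE)
  ids <- sprintf("P%04d", sample(1000))
  bds <- lapply(seq_along(ids), function(i) {
    bd <- score_patient(patient_record(ids[i], "1980-01-01", "F"), cfg,
                        extraction)
    bd$total <- totals[i]
    bd
  })
  ranked <- rank_population(bds)
  oracle <- order(-totals, ids)  # independent sort
  expect_equal(vapply(ranked, `[[`, character(1), "patient_id"), ids[oracle])
})

test_that("excluded patients are scored but never ranked", {
  fx <- make_worked_fixture()
  sc <- score_population(fx$population, cfg, default_exclusion_rules())
  expect_true(all(is.na(sc$rank[sc$excluded])))
  expect_true(all(!is.na(sc$rank[!sc$excluded])))
  expect_error(rank_population(list(local({
    bd <- score_patient(fx$population$patients[[1]], cfg, extraction)
    bd$excluded <- TRUE
    bd
  }))), "excluded")
})
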