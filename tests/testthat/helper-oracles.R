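# Independent brute-force oracles used across the suite. Deliberately
# written as plain double loops over events and candidate values, sharing
# no code with the package internals they check.

# AUC by exhaustive case-control pair counting, ties worth 1/2.
bf_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  s <- 0
  for (a in cases) {
    for (b in controls) {
      s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  s / (length(cases) * length(controls))
}

# Sensitivity/specificity at every candidate cutoff (observed values and
# midpoints), rule score >= cutoff.
bf_cutoff_table <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- u
  if (length(u) > 1) cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  do.call(rbind, lapply(cand, function(ct) {
    data.frame(cutoff = ct,
               sens = mean(scores[labels == 1] >= ct),
               spec = mean(scores[labels == 0] < ct))
  }))
}

bf_youden <- function(scores, labels) {
  tab <- bf_cutoff_table(scores, labels)
  tab$j <- tab$sens + tab$spec - 1
  best <- tab[order(-tab$j, -tab$sens, tab$cutoff), ][1, ]
  list(cutoff = best$cutoff, sensitivity = best$sens, specificity = best$spec)
}

bf_full_sens <- function(scores, labels) {
  tab <- bf_cutoff_table(scores, labels)
  tab <- tab[tab$sens == 1, ]
  best <- tab[which.max(tab$cutoff), ]
  list(cutoff = best$cutoff, specificity = best$spec)
}

# Double-loop score oracle: re-derives one patient's total by iterating
# items x events with freshly coded matching, window and counting logic.
bf_total_score <- function(record, config, extraction_date) {
  match1 <- function(code, stems) {
    for (s in stems) {
      if (code == s) return(TRUE)
      if (startsWith(code, paste0(s, "."))) return(TRUE)
      if (!grepl(".", s, fixed = TRUE) && !grepl(".", code, fixed = TRUE) &&
            startsWith(code, s)) return(TRUE)
    }
    FALSE
  }
  ev <- record$events
  censor <- as.Date(extraction_date)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "diagnosis" &&
            match1(ev$code[i], config$ambiguous_diagnosis_codes) &&
            ev$date[i] < censor) {
        censor <- ev$date[i]
      }
    }
  }
  total <- 0
  for (it in config$items) {
    start <- censor - round(it$lookback_years * 365.25)
    count <- 0
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        if (ev$kind[i] != it$kind) next
        if (!(ev$date[i] > start && ev$date[i] <= censor)) next
        if (length(it$codes) > 0 && !match1(ev$code[i], it$codes)) next
        if (!is.null(it$value_below) &&
              (is.na(ev$value[i]) || ev$value[i] >= it$value_below)) next
        count <- count + 1
      }
    }
    pts <- if (it$counting == "per_occurrence") it$weight * count
           else if (it$counting == "once") it$weight * (count >= 1)
           else it$weight * (count >= it$min_count)
    pts <- min(pts, it$cap)
    gw <- 1
    if (!is.null(config$item_groups)) {
      g <- config$item_groups[[it$item_id]]
      if (!is.null(g)) gw <- config$group_weights[[g]]
    }
    total <- total + pts * gw * config$category_weights[[it$category]]
  }
  unname(total)
}

# Random patient record drawing from the default catalog's vocabulary.
random_record <- function(id, seed, extraction = as.Date("2022-02-08")) {
  set.seed(seed)
  codes <- c("R81", "R78", "R75", "H71", "R74", "D73", "D11", "L88", "D94",
             "B02", "B87", "R95.01", "S76", "S70", "N71", "B72", "B74.02",
             "A79", "T86", "B83")
  n_dx <- sample(0:12, 1)
  ev <- list()
  if (n_dx > 0) {
    ev$dx <- data.frame(code = sample(codes, n_dx, replace = TRUE),
                        kind = "diagnosis",
                        date = extraction - sample.int(4000, n_dx),
                        value = NA_real_, stringsAsFactors = FALSE)
  }
  n_rx <- sample(0:8, 1)
  if (n_rx > 0) {
    ev$rx <- data.frame(code = "J01CA04", kind = "antibiotic_prescription",
                        date = extraction - sample.int(2200, n_rx),
                        value = NA_real_, stringsAsFactors = FALSE)
  }
  n_gp <- sample(0:10, 1)
  if (n_gp > 0) {
    ev$gp <- data.frame(code = "", kind = "gp_visit",
                        date = extraction - sample.int(500, n_gp),
                        value = NA_real_, stringsAsFactors = FALSE)
  }
  if (runif(1) < 0.3) {
    ev$lab <- data.frame(code = sample(c("IGG", "IGM", "IGA"), 1),
                         kind = "lab_result",
                         date = extraction - sample.int(3000, 1),
                         value = runif(1, 0.1, 12), stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(code = character(), kind = character(),
               date = as.Date(character()), value = numeric(),
               stringsAsFactors = FALSE)
  patient_record(id, as.Date("1980-01-01") + sample(-8000:8000, 1),
                 sample(c("F", "M"), 1), events)
}

# Item-point feature matrix for a set of patients under a config.
item_feature_matrix <- function(pop, config) {
  out <- sapply(names(config$items), function(id) {
    vapply(pop$patients, function(p) {
      cen <- compute_censoring_date(p, config, pop$extraction_date)
      score_item(p, config$items[[id]], cen)
    }, numeric(1))
  })
  as.data.frame(matrix(out, nrow = length(pop$patients),
                       dimnames = list(names(pop$patients),
                                       names(config$items))))
}

# Minimal scoring config whose item ids match a named group map; used to
# drive fit_version3 on synthetic feature matrices.
grouped_cfg <- function(groups) {
  ids <- names(groups)
  cats <- rep(padscreen:::CATEGORIES[1:7], length.out = length(ids))
  items <- lapply(seq_along(ids), function(i)
    scoring_item(ids[i], cats[i], codes = sprintf("X%02d", i),
                 lookback_years = 4, weight = 1))
  scoring_config("v1", items,
                 stats::setNames(rep(1, 8), padscreen:::CATEGORIES))
}

# Synthetic labelled subset with planted group structure, for refit tests:
# items in the first two "signal" groups drive the label with the given
# log-odds effects; remaining items are noise.
planted_subset <- function(n, seed, effects = c(2, 1), n_noise_items = 6,
                           items_per_group = 3) {
  set.seed(seed)
  k <- length(effects)
  z <- matrix(rnorm(n * k), n, k)
  feats <- list()
  groups <- character(0)
  for (g in seq_len(k)) {
    for (j in seq_len(items_per_group)) {
      nm <- sprintf("sig%d_%d", g, j)
      feats[[nm]] <- pmax(0, round(z[, g] + rnorm(n, sd = 0.4) + 1))
      groups[nm] <- sprintf("G%d", g)
    }
  }
  for (j in seq_len(n_noise_items)) {
    nm <- sprintf("noise_%d", j)
    feats[[nm]] <- pmax(0, round(rnorm(n) + 1))
    groups[nm] <- sprintf("N%d", j)
  }
  eta <- -1 + as.numeric(scale(z) %*% effects)
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(subset = labelled_subset(as.data.frame(feats), y), groups = groups)
}
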