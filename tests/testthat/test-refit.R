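base_cfg <- default_scoring_config()

# small category-score subset where one category cleanly separates labels
separating_subset <- function(n = 120, seed = 5) {
  set.seed(seed)
  feats <- as.data.frame(matrix(rnorm(n * 8, mean = 2, sd = 0.5), n, 8,
                                dimnames = list(NULL, padscreen:::CATEGORIES)))
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  feats$autoimmune <- feats$autoimmune + 2.5 * y
  labelled_subset(feats, y)
}

test_that("ridge-refit weights live on the grid and reward the separating category", {
  sub <- separating_subset()
  fit <- fit_version2(sub, base_cfg, seed = 3)
  w <- fit$details$mapped_weights
  expect_true(all(w %in% c(0.5, 1, 2)))
  expect_equal(unname(w[["autoimmune"]]), 2)
  expect_equal(fit$fitted_config$version, "v2")
  expect_equal(fit$fitted_config$category_weights, w[names(fit$fitted_config$category_weights)])
})

test_that("refits are deterministic given the seed", {
  sub <- separating_subset()
  a <- fit_version2(sub, base_cfg, seed = 11)
  b <- fit_version2(sub, base_cfg, seed = 11)
  expect_identical(a$coefficient_table, b$coefficient_table)
  expect_identical(a$details$mapped_weights, b$details$mapped_weights)
})

test_that("uninformative (constant) categories keep their base weight", {
  set.seed(8)
  n <- 80
  feats <- as.data.frame(matrix(1, n, 8,
                                dimnames = list(NULL, padscreen:::CATEGORIES)))
  feats$rti <- rnorm(n)
  feats$antibiotics <- rnorm(n)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  expect_warning(fit <- fit_version2(labelled_subset(feats, y), base_cfg,
                                     seed = 1),
                 "constant categories")
  w <- fit$details$mapped_weights
  const <- setdiff(padscreen:::CATEGORIES, c("rti", "antibiotics"))
  expect_true(all(w[const] == 1))
})

test_that("grid mapping reproduces the published weight pattern and is monotone", {
  # coefficient ordering: GI lowest; antibiotics/RTI/malignancy typical;
  # autoimmune/GP-visits/other-infections clearly stronger
  coefs <- c(gi = 0.1, antibiotics = 0.8, rti = 0.9,
             malignancy_lymphoproliferative_other = 1.0,
             autoimmune = 1.7, gp_visits = 1.8, other_infections = 1.9)
  w <- map_weights_to_grid(coefs)
  expect_equal(unname(w[["gi"]]), 0.5)
  expect_equal(unname(w[c("antibiotics", "rti",
                          "malignancy_lymphoproliferative_other")]),
               c(1, 1, 1))
  expect_equal(unname(w[c("autoimmune", "gp_visits", "other_infections")]),
               c(2, 2, 2))

  # monotone: larger coefficients never get smaller weights
  for (s in 1:20) {
    set.seed(s)
    cf <- setNames(rnorm(8, 1, 0.8), paste0("c", 1:8))
    ww <- map_weights_to_grid(cf)
    o <- order(cf)
    expect_true(all(diff(ww[o]) >= 0), info = paste("seed", s))
    expect_true(all(ww %in% c(0.5, 1, 2)))
  }
})

test_that("PCA grouping recovers block structure", {
  # a single varying item forms its own group
  m1 <- cbind(solo = c(0, 1, 0, 1, 1, 0))
  expect_equal(unname(group_items_pca(m1)), "PC1")

  # two independent blocks of perfectly correlated items -> two groups
  # (5 binary items per block put each block eigenvalue ~5 x 0.25 >= 1)
  set.seed(13)
  a <- rbinom(400, 1, 0.5)
  b <- rbinom(400, 1, 0.5)
  m <- cbind(a1 = a, a2 = a, a3 = a, a4 = a, a5 = a,
             b1 = b, b2 = b, b3 = b, b4 = b, b5 = b)
  g <- group_items_pca(m)
  # brute-force oracle: group by perfect pairwise correlation
  expect_length(unique(g), 2)
  expect_length(unique(g[paste0("a", 1:5)]), 1)
  expect_length(unique(g[paste0("b", 1:5)]), 1)
  expect_false(g[["a1"]] == g[["b1"]])

  # absent items fall back to the clinical grouping, or error without one
  m2 <- cbind(m, absent = 0)
  expect_error(group_items_pca(m2), "absent")
  g2 <- group_items_pca(m2, clinical_fallback = list(absent = "G_clinical"))
  expect_equal(unname(g2[["absent"]]), "G_clinical")

  expect_error(group_items_pca(cbind(z = rep(0, 10))), "all-zero")
})

test_that("eigenvalue >= 1 retains the planted number of components", {
  set.seed(21)
  n <- 500
  k <- 3
  latent <- matrix(rnorm(n * k), n, k)
  strength <- c(1.3, 0.9, 0.6)  # separated eigenvalues keep loadings clean
  items <- do.call(cbind, lapply(seq_len(k), function(j) {
    sapply(1:4, function(i) strength[j] * latent[, j] + rnorm(n, sd = 0.2))
  }))
  colnames(items) <- sprintf("it%d_%d", rep(seq_len(k), each = 4), 1:4)
  # plus low-variance independent items (population eigenvalues < 1)
  noise <- matrix(rnorm(n * 3, sd = 0.3), n, 3,
                  dimnames = list(NULL, paste0("nz", 1:3)))
  g <- group_items_pca(cbind(items, noise))
  got_k <- length(unique(g[colnames(items)]))
  expect_equal(got_k, k)
  for (j in seq_len(k)) {
    expect_length(unique(g[sprintf("it%d_%d", j, 1:4)]), 1)
  }
})

test_that("version 3 collapses to version 2 when groups equal categories", {
  # one item per category, so group scores == category scores
  set.seed(17)
  n <- 100
  items <- lapply(padscreen:::CATEGORIES, function(cat_) {
    scoring_item(paste0("only_", cat_), cat_,
                 codes = if (cat_ == "gp_visits") character() else "X00",
                 kind = if (cat_ == "gp_visits") "gp_visit" else "diagnosis",
                 lookback_years = 4, weight = 1,
                 counting = if (cat_ == "gp_visits") "threshold" else "per_occurrence")
  })
  cfg1 <- scoring_config("v1", items,
                         setNames(rep(1, 8), padscreen:::CATEGORIES))
  feats <- as.data.frame(matrix(abs(rnorm(n * 8, 2)), n, 8,
                                dimnames = list(NULL, names(cfg1$items))))
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  feats$only_rti <- feats$only_rti + 1.5 * y
  sub <- labelled_subset(feats, y)
  groups <- setNames(padscreen:::CATEGORIES, names(cfg1$items))
  v3 <- fit_version3(sub, groups, cfg1, seed = 4)
  v2 <- fit_version2(sub, cfg1, seed = 4)
  stage1 <- v3$coefficient_table[paste0("group:", padscreen:::CATEGORIES)]
  expect_equal(unname(stage1), unname(v2$coefficient_table[padscreen:::CATEGORIES]),
               tolerance = 1e-4)
})

test_that("version 3 recovers the planted group-weight ordering", {
  hits <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    p <- planted_subset(400, seed = 5000 + s, effects = c(2, 1))
    fit <- fit_version3(p$subset, p$groups, grouped_cfg(p$groups), seed = s)
    gw <- fit$details$group_weights
    hits <- hits + (gw[["G1"]] > gw[["G2"]])
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("version 3 on pure-noise features stays at chance AUC", {
  aucs <- numeric(50)
  for (s in seq_len(50)) {
    set.seed(7000 + s)
    n <- 120
    feats <- as.data.frame(matrix(pmax(0, round(rnorm(n * 6, 1))), n, 6,
                                  dimnames = list(NULL, paste0("nz", 1:6))))
    y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
    groups <- setNames(paste0("G", rep(1:2, each = 3)), names(feats))
    train <- seq_len(n) %% 2 == 0
    if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2) next
    sub_tr <- labelled_subset(feats[train, ], y[train])
    fit <- suppressWarnings(
      fit_version3(sub_tr, groups, grouped_cfg(groups), seed = s))
    sc <- padscreen:::total_score_from_items(feats[!train, ], fit$fitted_config)
    aucs[s] <- if (sd(sc) == 0) 0.5 else bf_auc(sc, y[!train])
  }
  aucs <- aucs[aucs > 0]
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("lasso selection keeps the informative score and drops noise", {
  kept_v3 <- 0; kept_noise <- 0; n_rep <- 50
  for (s in seq_len(n_rep)) {
    set.seed(8000 + s)
    n <- 150
    v3s <- rnorm(n, 10, 4)
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * scale(v3s)[, 1] * 4))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    extra <- data.frame(immunosuppressant_4y = rbinom(n, 1, 0.2),
                        copd_or_malignancy = rbinom(n, 1, 0.15),
                        gp_visits_6plus = rbinom(n, 1, 0.4),
                        ews_score = sample(0:10, n, TRUE))
    sub <- labelled_subset(data.frame(x = v3s), y)
    fit <- fit_version4(sub, v3s, extra, seed = s)
    kept_v3 <- kept_v3 + ("v3_score" %in% fit$retained)
    kept_noise <- kept_noise + any(names(extra) %in% fit$retained)
  }
  expect_gte(kept_v3 / n_rep, 0.9)
  expect_lte(kept_noise / n_rep, 0.5)
})

test_that("lasso retains score and EWS when both carry signal", {
  set.seed(31)
  n <- 250
  v3s <- rnorm(n, 10, 4)
  ews <- sample(0:10, n, TRUE)
  eta <- -1 + 1.6 * scale(v3s)[, 1] + 1.4 * scale(ews)[, 1]
  y <- rbinom(n, 1, plogis(eta)); y[1:2] <- c(0L, 1L)
  extra <- data.frame(immunosuppressant_4y = rbinom(n, 1, 0.2),
                      copd_or_malignancy = rbinom(n, 1, 0.15),
                      gp_visits_6plus = rbinom(n, 1, 0.4),
                      ews_score = ews)
  fit <- fit_version4(labelled_subset(data.frame(x = v3s), y), v3s, extra,
                      seed = 2)
  expect_true(all(c("v3_score", "ews_score") %in% fit$retained))
})

test_that("degenerate refit inputs fail loudly", {
  n <- 40
  y <- rep(c(0, 1), 20)
  const <- data.frame(a = rep(1, n), b = rep(2, n))
  expect_error(fit_version4(labelled_subset(data.frame(x = rep(1, n)), y),
                            rep(1, n), const, seed = 1),
               "constant")
  expect_error(labelled_subset(data.frame(x = rnorm(4)), c(1, 1, 1, 1)),
               "one row per label")
})

test_that("one-SE lasso falls back to the minimal penalty when empty", {
  set.seed(55)
  n <- 60
  # weak signal: the 1SE model is typically empty, triggering the fallback
  v3s <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 * v3s)); y[1:2] <- c(0L, 1L)
  extra <- data.frame(z1 = rnorm(n), z2 = rnorm(n))
  fit <- fit_version4(labelled_subset(data.frame(x = v3s), y), v3s, extra,
                      seed = 9)
  expect_true(fit$lambda_rule %in% c("one_SE", "minimal"))
  if (all(fit$coefficient_table == 0)) {
    expect_equal(fit$lambda_rule, "minimal")
  }
})
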