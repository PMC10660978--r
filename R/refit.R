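#' Construct a labelled high-risk subset for refitting
#'
#' Rows are patients from the high-risk screening stage with a confirmed
#' PAD / unlikely-PAD label; columns are numeric features -- item points
#' (named by `item_id`), category scores (named by category) and/or extra
#' covariates.
#'
#' @param features Numeric `data.frame` with unique column names.
#' @param label Binary vector (1 = PAD), one per row.
#' @return A `labelled_subset`.
#' @export
labelled_subset <- function(features, label) {
  features <- as.data.frame(features)
  if (anyDuplicated(names(features))) stop("labelled_subset: duplicate feature names")
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("labelled_subset: all features must be numeric")
  }
  if (nrow(features) != length(label)) {
    stop("labelled_subset: label length must match rows")
  }
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labelled_subset: label must be 0/1")
  if (length(unique(label)) < 2) {
    stop("labelled_subset: at least one row per label is required")
  }
  structure(list(features = features, label = label),
            class = "labelled_subset")
}

# Stratified fold assignment, deterministic per seed.
stratified_folds <- function(y, nfolds = 10, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(nfolds), length.out = length(idx)))
  }
  fold
}

# Penalized logistic fit with cross-validated penalty.
# Features are standardized (mean 0, SD 1) here; coefficients are reported
# on the standardized scale. Returns coefficients at the requested rule and
# the rule actually used ("one_SE" falls back to "minimal" when the 1SE
# model is empty and allow_fallback is TRUE).
penalized_logistic <- function(x, y, alpha, seed, rule = "one_SE",
                               allow_fallback = FALSE, nfolds = 10) {
  x <- as.matrix(x)
  keep <- apply(x, 2, function(col) sd(col) > 0)
  if (!any(keep)) stop("penalized fit: all features are constant (no information)")
  dropped <- colnames(x)[!keep]
  xs <- scale(x[, keep, drop = FALSE])
  foldid <- stratified_folds(y, nfolds = min(nfolds, max(3, min(table(y)))),
                             seed = seed)
  if (ncol(xs) >= 2) {
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = alpha,
                            foldid = foldid, standardize = FALSE,
                            nlambda = 100)
    lam <- if (rule == "one_SE") cv$lambda.1se else cv$lambda.min
    b <- as.numeric(coef(cv, s = lam))[-1]
    used_rule <- rule
    if (rule == "one_SE" && allow_fallback && all(b == 0)) {
      lam <- cv$lambda.min
      b <- as.numeric(coef(cv, s = lam))[-1]
      used_rule <- "minimal"
    }
  } else {
    # a single informative feature: plain logistic fit, no penalty path
    fit <- stats::glm(y ~ xs, family = stats::binomial())
    b <- unname(coef(fit)[-1])
    lam <- 0
    used_rule <- rule
  }
  coefs <- setNames(b, colnames(xs))
  list(coefficients = coefs, lambda = lam, rule = used_rule,
       dropped = dropped)
}

refit_result <- function(version, fitted_config, coefficient_table,
                         lambda_rule, retained = NULL, details = list()) {
  structure(list(version = version, fitted_config = fitted_config,
                 coefficient_table = coefficient_table,
                 lambda_rule = lambda_rule, retained = retained,
                 details = details),
            class = "refit_result")
}

#' @export
print.refit_result <- function(x, ...) {
  cat(sprintf("<refit_result %s (lambda rule: %s)>\n", x$version, x$lambda_rule))
  ct <- x$coefficient_table
  cat("  coefficients (standardized scale):\n")
  for (nm in names(ct)) cat(sprintf("    %-38s %8.4f\n", nm, ct[[nm]]))
  if (!is.null(x$retained)) {
    cat("  retained: ", paste(x$retained, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Category scores from an item-level feature matrix, applying the config's
# group weights when present.
category_scores_from_items <- function(features, config) {
  out <- matrix(0, nrow(features), length(CATEGORIES),
                dimnames = list(NULL, CATEGORIES))
  for (it in config$items) {
    if (!it$item_id %in% names(features)) next
    v <- features[[it$item_id]]
    if (!is.null(config$item_groups)) {
      g <- config$item_groups[[it$item_id]]
      if (!is.null(g)) v <- v * config$group_weights[[g]]
    }
    out[, it$category] <- out[, it$category] + v
  }
  out
}

# Total algorithm score from an item-level feature matrix.
total_score_from_items <- function(features, config) {
  cs <- category_scores_from_items(features, config)
  as.numeric(cs %*% config$category_weights[CATEGORIES])
}

#' Map fitted coefficients onto a discrete weight grid
#'
#' Coefficients are expressed relative to the median coefficient and each
#' ratio is snapped to the nearest grid value (ties toward the lower
#' value), so categories of typical importance keep weight 1 while clearly
#' weaker/stronger ones move down/up the grid. Non-positive ratios take
#' the smallest grid weight. The mapping is monotone: a larger coefficient
#' never receives a smaller weight.
#'
#' @param coefs Named numeric coefficients (standardized scale).
#' @param grid Ordered candidate weights, default `c(0.5, 1, 2)`.
#' @return Named numeric weights drawn from `grid`.
#' @export
map_weights_to_grid <- function(coefs, grid = c(0.5, 1, 2)) {
  grid <- sort(grid)
  ref <- median(coefs)
  if (ref <= 0) ref <- if (any(coefs > 0)) mean(coefs[coefs > 0]) else NA
  if (is.na(ref) || ref <= 0) {
    warning("map_weights_to_grid: no positive reference coefficient; ",
            "weights left at 1")
    return(setNames(rep(1, length(coefs)), names(coefs)))
  }
  ratio <- coefs / ref
  w <- vapply(ratio, function(r) {
    d <- abs(r - grid)
    grid[which(d == min(d))[1]]
  }, numeric(1))
  setNames(w, names(coefs))
}

#' Refit category weights by ridge regression (algorithm version 2)
#'
#' Fits an L2-penalized logistic model of PAD status on the eight category
#' scores, with the penalty chosen by seeded stratified cross-validation at
#' the one-standard-error rule, then snaps each category's coefficient to
#' a discrete weight grid (default \{0.5, 1, 2\}) via
#' [map_weights_to_grid()]. Categories that are constant in the subset
#' cannot inform the fit and keep their base weight (with a warning).
#'
#' @param subset A [labelled_subset()] whose features contain either the
#'   eight category scores (columns named by category) or item points from
#'   which they can be derived via `base`.
#' @param base The base (version 1) `scoring_config`.
#' @param weight_grid Candidate weights, default `c(0.5, 1, 2)`.
#' @param seed Integer seed for fold assignment.
#' @return A `refit_result` with a `v2` fitted config.
#' @export
fit_version2 <- function(subset, base, weight_grid = c(0.5, 1, 2), seed = 1) {
  stopifnot(inherits(subset, "labelled_subset"))
  feats <- subset$features
  if (all(CATEGORIES %in% names(feats))) {
    x <- as.matrix(feats[, CATEGORIES])
  } else {
    x <- category_scores_from_items(feats, base)
  }
  fit <- penalized_logistic(x, subset$label, alpha = 0, seed = seed,
                            rule = "one_SE")
  if (length(fit$dropped) > 0) {
    warning("fit_version2: constant categories keep their base weight: ",
            paste(fit$dropped, collapse = ", "))
  }
  w <- base$category_weights
  if (length(fit$coefficients) > 0) {
    mapped <- map_weights_to_grid(fit$coefficients, weight_grid)
    w[names(mapped)] <- mapped
  }
  cfg <- scoring_config(version = "v2", items = unname(base$items),
                        category_weights = w,
                        ambiguous_diagnosis_codes = base$ambiguous_diagnosis_codes,
                        age_window = base$age_window, cutoffs = base$cutoffs)
  refit_result("v2", cfg, fit$coefficients, fit$rule,
               details = list(lambda = fit$lambda, weight_grid = weight_grid,
                              mapped_weights = w))
}

#' Group scoring items by principal component analysis
#'
#' To avoid overfitting a many-item score to a small labelled subset,
#' items are grouped before refitting: a PCA runs on the centered (not
#' scaled) patient x item matrix, components with eigenvalue >= 1 are
#' retained (at least one is always kept), and each item joins the
#' component where it has the largest absolute loading. Items with no
#' variation in the data (e.g. all-zero columns) cannot be placed by the
#' PCA and are assigned from `clinical_fallback`.
#'
#' @param item_matrix Numeric patients x items matrix (column names are
#'   item ids), typically 0/1 indicators or item points.
#' @param clinical_fallback Named map item id -> group id for items absent
#'   from the data.
#' @return Named character vector: item id -> group id (`"PC1"`, ...).
#' @export
group_items_pca <- function(item_matrix, clinical_fallback = NULL) {
  item_matrix <- as.matrix(item_matrix)
  if (is.null(colnames(item_matrix))) stop("group_items_pca: items must be named")
  if (all(item_matrix == 0)) stop("group_items_pca: all-zero item matrix")
  variances <- apply(item_matrix, 2, function(col) sd(col) > 0)
  if (sum(variances) == 0) {
    stop("group_items_pca: no item with nonzero variance")
  }
  absent <- colnames(item_matrix)[!variances]
  groups <- character(0)
  if (length(absent) > 0) {
    missing_fb <- absent[!absent %in% names(clinical_fallback)]
    if (length(missing_fb) > 0) {
      stop("group_items_pca: no clinical fallback group for item(s): ",
           paste(missing_fb, collapse = ", "))
    }
    groups <- setNames(unlist(clinical_fallback[absent]), absent)
  }
  pca <- prcomp(item_matrix[, variances, drop = FALSE],
                center = TRUE, scale. = FALSE)
  eig <- pca$sdev^2
  k <- max(1L, sum(eig >= 1))
  load <- abs(pca$rotation[, seq_len(k), drop = FALSE])
  assign <- apply(load, 1, which.max)
  groups <- c(setNames(paste0("PC", assign), rownames(load)), groups)
  groups[colnames(item_matrix)]
}

#' Two-stage ridge refit over item groups and categories (version 3)
#'
#' Stage 1 fits a ridge logistic model of PAD status on per-group scores
#' (sums of each group's item points) and takes the coefficients as group
#' weights. Stage 2 recomputes category scores with the group-weighted
#' items and fits a second ridge model to obtain category weights. The
#' resulting config scores patients as "algorithm version 3". Negative
#' fitted weights are clamped to zero in the config (a score weight cannot
#' be negative); the raw coefficients are kept in the coefficient table.
#'
#' @param subset A [labelled_subset()] whose features are item points named
#'   by `item_id`.
#' @param groups Named map item id -> group id, e.g. from
#'   [group_items_pca()].
#' @param base The base `scoring_config` (supplies the item catalog).
#' @param seed Integer seed.
#' @return A `refit_result` with a `v3` fitted config.
#' @export
fit_version3 <- function(subset, groups, base, seed = 1) {
  stopifnot(inherits(subset, "labelled_subset"))
  feats <- subset$features
  item_ids <- intersect(names(base$items), names(feats))
  if (length(item_ids) == 0) stop("fit_version3: no item features found")
  ungrouped <- item_ids[!item_ids %in% names(groups)]
  if (length(ungrouped) > 0) {
    stop("fit_version3: item(s) without a group: ",
         paste(ungrouped, collapse = ", "))
  }
  gids <- sort(unique(unlist(groups[item_ids])))
  gx <- sapply(gids, function(g) {
    members <- item_ids[unlist(groups[item_ids]) == g]
    rowSums(feats[, members, drop = FALSE])
  })
  gx <- matrix(gx, nrow = nrow(feats), dimnames = list(NULL, gids))

  stage1 <- penalized_logistic(gx, subset$label, alpha = 0, seed = seed,
                               rule = "one_SE")
  group_w <- setNames(rep(0, length(gids)), gids)
  group_w[names(stage1$coefficients)] <- pmax(stage1$coefficients, 0)
  # groups seen only through constant columns carry no information: weight 0

  cfg_groups <- as.list(groups[item_ids])
  interim <- scoring_config(version = "v3", items = unname(base$items[item_ids]),
                            category_weights = setNames(rep(1, 8), CATEGORIES) ,
                            ambiguous_diagnosis_codes = base$ambiguous_diagnosis_codes,
                            age_window = base$age_window, cutoffs = base$cutoffs,
                            item_groups = cfg_groups, group_weights = group_w)
  cx <- category_scores_from_items(feats, interim)
  if (all(apply(cx, 2, sd) == 0)) {
    # stage 1 found no informative group: nothing left for stage 2 to fit,
    # category weights stay at their base values
    warning("fit_version3: no informative item group; category weights ",
            "kept at base values")
    stage2 <- list(coefficients = setNames(rep(0, length(CATEGORIES)),
                                           CATEGORIES),
                   lambda = NA_real_, rule = "one_SE", dropped = CATEGORIES)
    cat_w <- base$category_weights
  } else {
    stage2 <- penalized_logistic(cx, subset$label, alpha = 0, seed = seed,
                                 rule = "one_SE")
    cat_w <- setNames(rep(0, length(CATEGORIES)), CATEGORIES)
    cat_w[names(stage2$coefficients)] <- pmax(stage2$coefficients, 0)
    cat_w[stage2$dropped] <- base$category_weights[stage2$dropped]
  }

  cfg <- scoring_config(version = "v3", items = unname(base$items[item_ids]),
                        category_weights = cat_w,
                        ambiguous_diagnosis_codes = base$ambiguous_diagnosis_codes,
                        age_window = base$age_window, cutoffs = base$cutoffs,
                        item_groups = cfg_groups, group_weights = group_w)
  refit_result("v3", cfg,
               c(setNames(stage1$coefficients,
                          paste0("group:", names(stage1$coefficients))),
                 setNames(stage2$coefficients,
                          paste0("category:", names(stage2$coefficients)))),
               "one_SE",
               details = list(group_weights = group_w,
                              category_weights = cat_w,
                              lambda_stage1 = stage1$lambda,
                              lambda_stage2 = stage2$lambda))
}

#' Lasso selection over the refined score and new covariates (version 4)
#'
#' Combines the version-3 total score with candidate covariates that were
#' unavailable or ambiguous at development time (canonically:
#' immunosuppressant use in the past 4 years, an ICPC code for COPD or
#' malignancy, >= 6 GP visits per year in the past 2-4 years, and the
#' Early Warning Signs questionnaire score) in an L1-penalized logistic
#' model. The penalty follows the one-standard-error rule, falling back to
#' the minimum-deviance penalty when the 1SE model retains nothing.
#'
#' @param subset A [labelled_subset()] (supplies the labels).
#' @param v3_scores Numeric version-3 total scores aligned to the subset
#'   rows.
#' @param extra `data.frame` of candidate covariates aligned to the subset
#'   rows.
#' @param seed Integer seed.
#' @param base Optional base `scoring_config`; when supplied the fitted
#'   config is a `v4` config carrying the retained coefficients as
#'   `extra_covariates`.
#' @return A `refit_result` with `retained` feature names.
#' @export
fit_version4 <- function(subset, v3_scores, extra, seed = 1, base = NULL) {
  stopifnot(inherits(subset, "labelled_subset"))
  extra <- as.data.frame(extra)
  if (nrow(extra) != length(subset$label) ||
        length(v3_scores) != length(subset$label)) {
    stop("fit_version4: v3_scores and extra must align with the subset rows")
  }
  x <- cbind(v3_score = v3_scores, extra)
  fit <- penalized_logistic(x, subset$label, alpha = 1, seed = seed,
                            rule = "one_SE", allow_fallback = TRUE)
  retained <- names(fit$coefficients)[fit$coefficients != 0]
  cfg <- NULL
  if (!is.null(base)) {
    cfg <- scoring_config(version = "v4", items = unname(base$items),
                          category_weights = base$category_weights,
                          ambiguous_diagnosis_codes = base$ambiguous_diagnosis_codes,
                          age_window = base$age_window, cutoffs = base$cutoffs,
                          item_groups = base$item_groups,
                          group_weights = base$group_weights,
                          extra_covariates = as.list(fit$coefficients[retained]))
  }
  refit_result("v4", cfg, fit$coefficients, fit$rule, retained = retained,
               details = list(lambda = fit$lambda))
}
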