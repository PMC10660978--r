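check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
  labels
}

auc_point <- function(scores, labels) {
  # Mann-Whitney formulation; ties count 1/2
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve with confidence interval
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation, counting
#' tied case-control pairs as one half. The default confidence interval is
#' a seeded stratified percentile bootstrap (resampling cases and controls
#' separately); `ci_method = "delong"` delegates to
#' \pkg{pROC}'s DeLong variance estimate.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels Binary labels (1 = case).
#' @param ci_method `"bootstrap"` (default) or `"delong"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, and `cutpoints` (a data.frame of candidate cutoffs with
#'   sensitivity and specificity under the rule score >= cutoff).
#' @export
auc_roc <- function(scores, labels, ci_method = c("bootstrap", "delong"),
                    n_boot = 2000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- check_two_classes(labels)
  if (any(!is.finite(scores))) stop("auc_roc: scores must be finite")
  auc <- auc_point(scores, labels)
  alpha <- (1 - conf_level) / 2
  if (ci_method == "bootstrap") {
    idx1 <- which(labels == 1)
    idx0 <- which(labels == 0)
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      i1 <- sample(idx1, length(idx1), replace = TRUE)
      i0 <- sample(idx0, length(idx0), replace = TRUE)
      auc_point(c(scores[i1], scores[i0]),
                c(rep(1L, length(i1)), rep(0L, length(i0))))
    }, numeric(1))
    ci <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
  } else {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      stop("auc_roc: ci_method = 'delong' requires the pROC package")
    }
    r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    ci <- as.numeric(pROC::ci.auc(r, method = "delong",
                                  conf.level = conf_level))[c(1, 3)]
  }
  cuts <- candidate_cutoffs(scores)
  cp <- data.frame(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(ct) mean(scores[labels == 1] >= ct),
                         numeric(1)),
    specificity = vapply(cuts, function(ct) mean(scores[labels == 0] < ct),
                         numeric(1))
  )
  structure(list(auc = auc,
                 ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
                 conf_level = conf_level, ci_method = ci_method,
                 cutpoints = cp[order(cp$cutoff), , drop = FALSE]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (%d%% CI %.3f-%.3f, %s)>\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method))
  invisible(x)
}

# Candidate cutoffs: the observed score values plus midpoints between
# consecutive distinct values. Midpoints are what make half-point cutoffs
# like 15.5 appear from integer-ish score distributions.
candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
}

#' Optimal cutoff by Youden's index
#'
#' Maximizes sensitivity + specificity - 1 over the candidate cutoffs
#' (observed values and midpoints) under the classification rule
#' score >= cutoff. Ties are broken toward higher sensitivity, then the
#' lower cutoff. With constant scores the single degenerate candidate is
#' returned with a warning.
#'
#' @inheritParams auc_roc
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_two_classes(labels)
  cuts <- candidate_cutoffs(scores)
  if (length(cuts) == 1) {
    warning("youden_cutoff: constant scores, cutoff is degenerate")
  }
  sens <- vapply(cuts, function(ct) mean(scores[labels == 1] >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(scores[labels == 0] < ct), numeric(1))
  j <- sens + spec - 1
  ord <- order(-j, -sens, cuts)
  i <- ord[1]
  list(cutoff = cuts[i], sensitivity = sens[i], specificity = spec[i],
       youden = j[i])
}

#' Cutoff retaining 100% sensitivity
#'
#' The largest cutoff classifying every case positive under the rule
#' score >= cutoff; this is the minimum case score. Reports the resulting
#' specificity.
#'
#' @inheritParams auc_roc
#' @return List with `cutoff`, `sensitivity` (always 1), `specificity`.
#' @export
full_sensitivity_cutoff <- function(scores, labels) {
  labels <- check_two_classes(labels)
  ct <- min(scores[labels == 1])
  list(cutoff = ct, sensitivity = 1,
       specificity = mean(scores[labels == 0] < ct))
}

round_half_up <- function(x) floor(x + 0.5)

#' Screening yield: numbers needed to screen, test, refer
#'
#' Stage counts per detected case, rounded to the nearest integer with
#' halves away from zero.
#'
#' @param n_screened,n_tested,n_referred Stage counts.
#' @param n_cases Detected cases (must be >= 1).
#' @return List with the four counts and `nns`, `nnt`, `nnr`.
#' @export
screening_yield <- function(n_screened, n_tested, n_referred, n_cases) {
  counts <- c(n_screened, n_tested, n_referred, n_cases)
  if (any(counts < 0) || any(counts != round_half_up(counts))) {
    stop("screening_yield: counts must be non-negative integers")
  }
  if (n_cases == 0) stop("screening_yield: undefined yield (n_cases = 0)")
  if (!(n_cases <= n_referred && n_referred <= n_tested &&
          n_tested <= n_screened)) {
    stop("screening_yield: counts must be non-increasing along the funnel")
  }
  list(n_screened = n_screened, n_tested = n_tested,
       n_referred = n_referred, n_cases = n_cases,
       nns = round_half_up(n_screened / n_cases),
       nnt = round_half_up(n_tested / n_cases),
       nnr = round_half_up(n_referred / n_cases))
}

#' A-priori expected case count range from prevalence bounds
#'
#' @param population_size Number of records.
#' @param prevalence_low,prevalence_high Prevalence bounds as 1:k ratios,
#'   given as the denominators `k` (low prevalence = larger k).
#' @return List with `low` and `high` expected case counts (rounded).
#' @export
expected_case_range <- function(population_size, prevalence_low, prevalence_high) {
  if (population_size <= 0 || prevalence_low <= 0 || prevalence_high <= 0) {
    stop("expected_case_range: inputs must be positive")
  }
  if (prevalence_high > prevalence_low) {
    stop("expected_case_range: prevalence_low must be the larger denominator (rarer)")
  }
  list(low = round_half_up(population_size / prevalence_low),
       high = round_half_up(population_size / prevalence_high))
}
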