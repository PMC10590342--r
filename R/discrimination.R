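# ROC discrimination of dose-limiting toxicity (DLT) from a continuous
# measurement: empirical ROC curve, AUC with DeLong confidence interval,
# Youden optimal cut-point, and confusion-matrix performance.
#
# Direction convention: `direction = "lower"` (the default) means a LOWER
# measurement predicts DLT — i.e. cases are expected below controls, as with
# skeletal muscle volume. The direction is fixed per analysis, never
# auto-flipped, so a poorly discriminating variable can legitimately report
# an AUC below 0.5.

# orient so that larger score = more case-like
.orient <- function(x, direction) if (direction == "lower") -x else x

# midrank placements: P(score of each case > random control score), ties 1/2
.placements <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  r_all <- rank(c(cases, controls))
  v10 <- (r_all[seq_len(n1)] - rank(cases)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(controls)) / n1
  list(v10 = v10, v01 = v01)
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' The AUC is the probability a random case-control pair is ordered per
#' `direction`, ties counting one half — identical to the trapezoidal area
#' under the empirical curve and to `U / (n1 * n0)` of the Mann-Whitney
#' statistic. The confidence interval uses DeLong's nonparametric variance
#' (normal interval on placements, truncated to [0, 1]).
#'
#' Candidate thresholds are the midpoints between adjacent distinct observed
#' values plus -Inf and +Inf; sensitivity/specificity at a threshold t follow
#' the boundary rule "value >= t is classified into the 'higher' class".
#'
#' @param cases measurement values of DLT patients.
#' @param controls measurement values of non-DLT patients.
#' @param direction `"lower"` if a lower value predicts DLT (default),
#'   `"higher"` otherwise; `"auto"` orients from the group medians (the
#'   returned object records the direction chosen). The default is fixed,
#'   not auto-flipped, so a non-discriminating variable can report an AUC
#'   below one half.
#' @param conf_level confidence level for the AUC interval.
#' @return object of class `roc_curve`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `ci_low`, `ci_high`,
#'   `direction`, `n_cases`, `n_controls`, `degenerate`.
#' @export
roc_auc <- function(cases, controls, direction = c("lower", "higher", "auto"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  cases <- as.numeric(cases); controls <- as.numeric(controls)
  if (length(cases) == 0L || length(controls) == 0L) {
    stop("both the case and control group must be nonempty")
  }
  if (direction == "auto") {
    direction <- if (stats::median(cases) <= stats::median(controls))
      "lower" else "higher"
  }
  sc <- .orient(cases, direction); sk <- .orient(controls, direction)
  pl <- .placements(sc, sk)
  auc <- mean(pl$v10)
  degenerate <- length(unique(c(cases, controls))) == 1L
  if (degenerate || length(cases) < 2L || length(controls) < 2L) {
    se <- NA_real_
  } else {
    se <- sqrt(stats::var(pl$v10) / length(cases) +
               stats::var(pl$v01) / length(controls))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    pmin(1, pmax(0, auc + c(-1, 1) * zq * se))

  vals <- sort(unique(c(cases, controls)))
  thresholds <- c(-Inf, if (length(vals) > 1L)
    (vals[-length(vals)] + vals[-1L]) / 2, Inf)
  pred_case <- function(x, t) if (direction == "lower") x < t else x >= t
  sens <- vapply(thresholds, function(t) mean(pred_case(cases, t)), numeric(1))
  spec <- vapply(thresholds, function(t) mean(!pred_case(controls, t)), numeric(1))

  structure(
    list(curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                                specificity = spec),
         auc = auc, ci_low = ci[1], ci_high = ci[2],
         conf_level = conf_level, direction = direction,
         n_cases = length(cases), n_controls = length(controls),
         degenerate = degenerate),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d controls, direction '%s'\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$n_cases, x$n_controls, x$direction))
  invisible(x)
}

#' Optimal cut-point from a ROC curve
#'
#' Maximises Youden's J = sensitivity + specificity - 1 (default), or
#' accuracy when `criterion = "accuracy"`. Ties are broken deterministically:
#' highest specificity first, then lowest threshold. On a fully degenerate
#' curve (all values tied) the lowest candidate threshold is returned with
#' `degenerate = TRUE`.
#'
#' @param curve a [roc_auc()] result.
#' @param criterion `"youden"` or `"accuracy"`.
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`,
#'   `criterion`, `degenerate`.
#' @export
optimal_cutpoint <- function(curve, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_curve"))
  cv <- curve$curve
  score <- if (criterion == "youden") {
    cv$sensitivity + cv$specificity - 1
  } else {
    (cv$sensitivity * curve$n_cases + cv$specificity * curve$n_controls) /
      (curve$n_cases + curve$n_controls)
  }
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  cand <- cand[order(-cv$specificity[cand], cv$threshold[cand])][1]
  list(threshold = cv$threshold[cand],
       sensitivity = cv$sensitivity[cand],
       specificity = cv$specificity[cand],
       j = cv$sensitivity[cand] + cv$specificity[cand] - 1,
       criterion = criterion,
       degenerate = curve$degenerate)
}

#' Confusion-matrix metrics from raw counts
#'
#' Accuracy = correctly classified / total; sensitivity = correctly
#' identified DLT / all DLT; specificity = correctly identified non-DLT /
#' all non-DLT.
#'
#' @param tp,fn,tn,fp confusion-matrix counts (DLT = positive class).
#' @param threshold optional threshold to record alongside the counts.
#' @return one-row tibble of class `cutpoint_evaluation`.
#' @export
cutpoint_metrics <- function(tp, fn, tn, fp, threshold = NA_real_) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  out <- tibble::tibble(
    threshold = threshold, tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
  class(out) <- c("cutpoint_evaluation", class(out))
  out
}

#' Evaluate a dichotomising threshold on case/control data
#'
#' Classification rule at the boundary: `value >= threshold` goes to the
#' "higher" class (non-DLT under `direction = "lower"`, DLT under
#' `direction = "higher"`).
#'
#' @param cases,controls measurement values for DLT / non-DLT patients.
#' @param threshold finite dichotomisation threshold, measurement units.
#' @param direction as in [roc_auc()].
#' @return one-row tibble of class `cutpoint_evaluation` with counts and
#'   accuracy / sensitivity / specificity.
#' @export
evaluate_cutpoint <- function(cases, controls, threshold,
                              direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  pred_case <- function(x) if (direction == "lower") x < threshold else x >= threshold
  cutpoint_metrics(
    tp = sum(pred_case(cases)), fn = sum(!pred_case(cases)),
    tn = sum(!pred_case(controls)), fp = sum(pred_case(controls)),
    threshold = threshold
  )
}

#' Classify a cohort at published (fixed, not fitted) cut-offs
#'
#' Dichotomises `variable` at the supplied per-sex thresholds — e.g.
#' published sarcopenia SMI cut-offs — and evaluates the resulting DLT
#' prediction per sex.
#'
#' @param cohort validated cohort table.
#' @param variable measurement column to threshold.
#' @param cutoffs named numeric vector, one threshold per sex present
#'   (names in `F`, `M`).
#' @param direction as in [roc_auc()]; `"lower"` means a value below the
#'   cut-off predicts DLT (the sarcopenia convention).
#' @return tibble with one `cutpoint_evaluation` row per sex.
#' @export
threshold_classifier <- function(cohort, variable, cutoffs,
                                 direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  cohort <- validate_cohort(cohort)
  rows <- list()
  for (sex in sort(unique(cohort$sex))) {
    if (!sex %in% names(cutoffs)) {
      stop("no cut-off supplied for sex '", sex, "'")
    }
    block <- cohort[cohort$sex == sex, ]
    ev <- evaluate_cutpoint(block[[variable]][block$dlt == 1L],
                            block[[variable]][block$dlt == 0L],
                            threshold = cutoffs[[sex]], direction = direction)
    rows[[sex]] <- tibble::add_column(ev, sex = sex, variable = variable,
                                      .before = 1)
  }
  dplyr::bind_rows(rows)
}

#' Per-sex, per-measurement ROC report (Tables-2/3 style)
#'
#' For each sex and each variable (BSA plus the nine 2D and six 3D
#' measurements by default): AUC with confidence interval, Youden optimal
#' cut-point, and in-sample confusion-matrix performance at that cut-point.
#' `exceeds_bsa` flags variables whose AUC is greater than BSA's in the same
#' sex (the report's highlighting rule).
#'
#' @param cohort validated cohort table.
#' @param variables measurement columns to analyse.
#' @param direction as in [roc_auc()]; fixed for all variables.
#' @param criterion cut-point criterion, see [optimal_cutpoint()].
#' @param conf_level AUC confidence level.
#' @return tibble with columns `sex`, `variable`, `auc`, `ci_low`,
#'   `ci_high`, `cutpoint`, `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`, `degenerate`, `exceeds_bsa`.
#' @export
evaluate_all <- function(cohort, variables = c("bsa", measurement_columns()),
                         direction = c("lower", "higher", "auto"),
                         criterion = c("youden", "accuracy"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  cohort <- validate_cohort(cohort)
  rows <- list()
  for (sex in sort(unique(cohort$sex))) {
    block <- cohort[cohort$sex == sex, ]
    cases <- block[block$dlt == 1L, ]; controls <- block[block$dlt == 0L, ]
    for (v in variables) {
      curve <- roc_auc(cases[[v]], controls[[v]], direction = direction,
                       conf_level = conf_level)
      cut <- optimal_cutpoint(curve, criterion = criterion)
      dir_v <- curve$direction  # resolved orientation under "auto"
      ev <- if (is.finite(cut$threshold)) {
        evaluate_cutpoint(cases[[v]], controls[[v]], cut$threshold, dir_v)
      } else {
        # infinite cut-point: the classifier assigns everyone to one class
        all_case <- (dir_v == "lower" && cut$threshold == Inf) ||
          (dir_v == "higher" && cut$threshold == -Inf)
        cutpoint_metrics(tp = if (all_case) nrow(cases) else 0,
                         fn = if (all_case) 0 else nrow(cases),
                         tn = if (all_case) 0 else nrow(controls),
                         fp = if (all_case) nrow(controls) else 0,
                         threshold = cut$threshold)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sex, variable = v, n_dlt = nrow(cases),
        n_no_dlt = nrow(controls), direction = curve$direction,
        auc = curve$auc, ci_low = curve$ci_low, ci_high = curve$ci_high,
        cutpoint = cut$threshold,
        tp = ev$tp, fn = ev$fn, tn = ev$tn, fp = ev$fp,
        accuracy = ev$accuracy, sensitivity = ev$sensitivity,
        specificity = ev$specificity, degenerate = cut$degenerate
      )
    }
  }
  report <- dplyr::bind_rows(rows)
  bsa_auc <- report$auc[report$variable == "bsa"]
  names(bsa_auc) <- report$sex[report$variable == "bsa"]
  report$exceeds_bsa <- if ("bsa" %in% variables) {
    report$auc > bsa_auc[report$sex] & report$variable != "bsa"
  } else NA
  report
}
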