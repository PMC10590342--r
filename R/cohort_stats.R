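# Group-comparison statistics and Table-1-style cohort summaries.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two independent samples. Uses exact enumeration
#' when both groups have at most 25 observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#' The returned U statistic counts (a, b) pairs with a > b, ties counting
#' one half, so `U / (n_a * n_b)` is the AUC of group A against group B.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact override the exact/approximate choice (`NULL` = automatic).
#' @return list with `u`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    # fully tied data carry no ordering information
    return(list(u = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate (all ties)"))
  }
  if (is.null(exact)) exact <- length(a) <= 25L && length(b) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(u = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact && !ties) "exact" else "normal approximation")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Yates continuity correction is applied by default (df = 1).
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Validate a cohort table
#'
#' Checks the column contract of the analysis substrate: `patient_id`
#' (unique), `sex` in {F, M}, `dlt` in {0, 1}, plus `age`, `height_m`, `bsa`
#' and the 15 measurement columns ([measurement_columns()]).
#'
#' @param cohort data frame.
#' @return the cohort as a tibble, invisibly validated.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("patient_id", "sex", "age", "height_m", "bsa", "dlt",
                measurement_columns())
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(cohort$patient_id[duplicated(cohort$patient_id)]),
               collapse = ", "))
  }
  if (!all(cohort$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(cohort$dlt %in% c(0L, 1L))) stop("dlt must be 0 or 1")
  cohort
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with the [validate_cohort()] column contract.
#' @return validated tibble.
#' @export
read_cohort <- function(path) {
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Table-1-style group summaries: DLT vs no DLT, stratified by sex
#'
#' Per sex stratum and per variable: median and interquartile range
#' (linear-interpolation quartiles, `stats::quantile` type 7) within the DLT
#' and no-DLT groups, and the two-sided Mann-Whitney p-value.
#'
#' @param cohort validated cohort table.
#' @param variables continuous variables to summarise; defaults to age, BSA
#'   and all 15 measurements.
#' @param stratify_by_sex summarise each sex separately (the default); when
#'   `FALSE` a single pooled block labelled `"all"` is produced.
#' @return tibble with columns `sex`, `variable`, and per group (`dlt`,
#'   `no_dlt`) `n`, `median`, `q1`, `q3`, plus `p_value`.
#' @export
summarize_groups <- function(cohort,
                             variables = c("age", "bsa", measurement_columns()),
                             stratify_by_sex = TRUE) {
  cohort <- validate_cohort(cohort)
  strata <- if (stratify_by_sex) split(cohort, cohort$sex) else list(all = cohort)
  rows <- list()
  for (sex in names(strata)) {
    block <- strata[[sex]]
    g1 <- block[block$dlt == 1L, , drop = FALSE]
    g0 <- block[block$dlt == 0L, , drop = FALSE]
    if (nrow(g1) == 0L || nrow(g0) == 0L) {
      stop("stratum '", sex, "' has an empty DLT or no-DLT group")
    }
    for (v in variables) {
      x1 <- g1[[v]]; x0 <- g0[[v]]
      q1v <- stats::quantile(x1, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
      q0v <- stats::quantile(x0, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sex, variable = v,
        n_dlt = nrow(g1), median_dlt = q1v[[2]], q1_dlt = q1v[[1]], q3_dlt = q1v[[3]],
        n_no_dlt = nrow(g0), median_no_dlt = q0v[[2]], q1_no_dlt = q0v[[1]],
        q3_no_dlt = q0v[[3]],
        p_value = mann_whitney(x1, x0)$p_value
      )
    }
  }
  dplyr::bind_rows(rows)
}
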