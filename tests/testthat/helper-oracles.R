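# Independent brute-force oracles and shared small fixtures.

# AUC by explicit pair counting (ties count one half)
auc_pairs <- function(cases, controls, direction = "lower") {
  s <- 0
  for (a in cases) {
    for (b in controls) {
      s <- s + if (a == b) 0.5
      else if ((direction == "lower" && a < b) ||
               (direction == "higher" && a > b)) 1 else 0
    }
  }
  s / (length(cases) * length(controls))
}

# trapezoidal area under the empirical ROC curve in (1 - spec, sens) space
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$curve$specificity
  sens <- curve$curve$sensitivity
  ord <- order(fpr, sens)
  fpr <- fpr[ord]; sens <- sens[ord]
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# exhaustive search over every candidate dichotomisation for the best Youden J
best_j_exhaustive <- function(cases, controls, direction = "lower") {
  vals <- sort(unique(c(cases, controls)))
  cand <- c(-Inf, if (length(vals) > 1) (vals[-length(vals)] + vals[-1]) / 2, Inf)
  pred <- function(x, t) if (direction == "lower") x < t else x >= t
  max(vapply(cand, function(t) {
    mean(pred(cases, t)) + mean(!pred(controls, t)) - 1
  }, numeric(1)))
}

# exact two-sided permutation p for the rank-sum test (small n, no ties)
mw_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    auc_pairs(x, y, direction = "higher") * n1 * length(y)
  }
  obs <- abs(u_of(seq_len(n1)) - n1 * length(b) / 2)
  all_idx <- utils::combn(length(pooled), n1)
  us <- apply(all_idx, 2, u_of)
  mean(abs(us - n1 * length(b) / 2) >= obs - 1e-9)
}

# compact phantom used across tests: 96 mm field of view at 1 mm spacing
small_phantom_spec <- function(seed = 7, ...) {
  args <- list(size = 96L, row_spacing_mm = 1, n_slices = 5L, thickness_mm = 4,
               vat_radius_mm = 15, sm_outer_mm = 25, sat_outer_mm = 35,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# pixelation bound for a rasterised region: 2 x perimeter x pixel area
pixelation_bound_cm2 <- function(perimeter_mm, spacing_mm) {
  2 * perimeter_mm * spacing_mm / 100
}
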