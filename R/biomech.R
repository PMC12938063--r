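#' Spatially averaged wall stress (SAWS)
#'
#' Area-weighted mean of per-element first principal stress:
#' `sum(sigma_e * A_e) / sum(A_e)`.
#'
#' @param principal_1 Per-element first principal stress (N/cm^2).
#' @param areas Per-element areas (cm^2), all positive.
#' @return SAWS in N/cm^2.
#' @export
saws <- function(principal_1, areas) {
  if (length(principal_1) != length(areas))
    stop_aaawall("stress and area vectors differ in length")
  if (any(areas <= 0)) stop_aaawall("element areas must be positive")
  sum(principal_1 * areas) / sum(areas)
}

#' Percentile wall stress
#'
#' Linear-interpolation percentile (R's type-7 quantile) of the
#' per-element first principal stress; `q = 99` gives the 99th-percentile
#' wall stress, `q = 100` the maximum.
#'
#' @param principal_1 Non-empty numeric vector.
#' @param q Percentile in \[0, 100\] (default 99).
#' @return Stress value in N/cm^2.
#' @export
percentile_ws <- function(principal_1, q = 99) {
  if (length(principal_1) == 0) stop_aaawall("empty stress field")
  unname(quantile(principal_1, q / 100, type = 7))
}

#' Mean arterial pressure
#'
#' One-third pulse-pressure rule `(SBP + 2 DBP) / 3`, reported to
#' 0.1 mmHg; 120/80 mmHg gives 93.3 mmHg.
#'
#' @param sbp Systolic pressure (mmHg).
#' @param dbp Diastolic pressure (mmHg), `0 < dbp <= sbp`.
#' @return MAP in mmHg, rounded to one decimal.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop_aaawall("diastolic pressure must be positive")
  if (any(sbp < dbp)) stop_aaawall("systolic pressure below diastolic")
  round((sbp + 2 * dbp) / 3, 1)
}

#' Coefficient of determination between predicted and reference values
#'
#' Default is the squared Pearson correlation of the paired values;
#' `mode = "identity"` instead computes `1 - SS_res / SS_tot` about the
#' identity line `y = x`.
#'
#' @param predicted,reference Paired numeric vectors, `n >= 2`.
#' @param mode `"pearson"` (default) or `"identity"`.
#' @return R^2.
#' @export
r_squared <- function(predicted, reference, mode = c("pearson", "identity")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(reference)) stop_aaawall("length mismatch")
  if (length(predicted) < 2) stop_aaawall("need at least 2 pairs")
  if (sd(predicted) == 0 || sd(reference) == 0)
    stop_aaawall("zero variance: R^2 undefined")
  if (mode == "pearson") return(cor(predicted, reference)^2)
  1 - sum((predicted - reference)^2) / sum((reference - mean(reference))^2)
}

#' Friedman rank test across paired groups
#'
#' Non-parametric repeated-measures comparison of `k >= 3` groups paired
#' by subject, via the rank-based Friedman chi-square (mid-ranks for
#' ties). A thin wrapper around [stats::friedman.test()] returning the
#' statistic and p-value directly.
#'
#' @param groups List of `k` equal-length numeric vectors, or a matrix
#'   with subjects in rows and groups in columns.
#' @return List with `statistic` (FS), `p_value`, and `df`.
#' @export
friedman_test <- function(groups) {
  if (is.list(groups)) {
    n <- unique(lengths(groups))
    if (length(n) != 1) stop_aaawall("groups must have equal lengths")
    groups <- do.call(cbind, groups)
  }
  if (ncol(groups) < 3) stop_aaawall("need at least 3 groups")
  ft <- stats::friedman.test(as.matrix(groups))
  stat <- unname(ft$statistic); pval <- ft$p.value
  if (!is.finite(stat)) {
    # fully tied rows: no rank variation at all, so no evidence of a
    # group effect
    stat <- 0; pval <- 1
  }
  list(statistic = stat, p_value = pval, df = unname(ft$parameter))
}

#' Summarise a wall-stress field
#'
#' Computes the three biomechanical summary statistics over the element
#' centroid first principal stresses: 99th-percentile wall stress,
#' arithmetic mean wall stress, and spatially (area-)averaged wall
#' stress.
#'
#' @param field A `stress_field` from [solve_stress()].
#' @return A `stress_summary` list: `ws99`, `mean_ws`, `saws` (N/cm^2)
#'   and `n_elements`.
#' @export
stress_summary <- function(field) {
  p1 <- field$principal_1
  structure(list(ws99 = percentile_ws(p1, 99), mean_ws = mean(p1),
                 saws = saws(p1, field$areas), n_elements = length(p1)),
            class = "stress_summary")
}
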