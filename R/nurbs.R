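# Closed and open NURBS curves via the Cox-de Boor recursion.
#
# A curve of degree p over control points P_i with positive weights w_i is
#   c(t) = sum_i N_{i,p}(t) w_i P_i / sum_i N_{i,p}(t) w_i,  t in [0, 1].
# Open curves use a clamped-uniform knot vector; closed curves use a
# periodic-uniform knot vector with the first p control points wrapped, so
# the curve is C^{p-1} across the seam.  The user-facing parameter is
# always normalised to [0, 1] over the valid span.

#' Knot vector for a uniform B-spline
#'
#' For open curves this is the clamped-uniform vector: `p + 1` zeros,
#' `n_ctrl - p - 1` equally spaced interior knots, `p + 1` ones (length
#' `n_ctrl + p + 1`). For closed curves it is the periodic-uniform vector
#' for the wrapped control net (`n_ctrl + p` effective control points),
#' with knots `(i - 1 - p) / n_ctrl`, so the valid span is exactly
#' \[0, 1\].
#'
#' @param n_ctrl Number of (distinct) control points.
#' @param p Curve degree.
#' @param closed Logical.
#' @return Non-decreasing numeric knot vector.
#' @export
compute_knot_vector <- function(n_ctrl, p, closed = FALSE) {
  if (n_ctrl <= p) stop_aaawall("need more control points (%d) than degree (%d)", n_ctrl, p)
  if (closed) {
    m <- n_ctrl + p                      # wrapped control net size
    return(((seq_len(m + p + 1) - 1) - p) / n_ctrl)
  }
  n_int <- n_ctrl - p - 1
  c(rep(0, p + 1), if (n_int > 0) seq_len(n_int) / (n_int + 1), rep(1, p + 1))
}

# all basis functions N_{i,p}(t), i = 1..n_basis, for one parameter value;
# n_basis = length(knots) - p - 1.  Classic knot-span + triangular scheme.
bspline_basis <- function(t, p, knots) {
  n_basis <- length(knots) - p - 1
  lo <- knots[p + 1]; hi <- knots[n_basis + 1]
  if (t < lo - 1e-12 || t > hi + 1e-12)
    stop_aaawall("parameter %g outside valid span [%g, %g]", t, lo, hi)
  t <- min(max(t, lo), hi)
  # knot span k such that knots[k] <= t < knots[k+1] (right end maps to last span)
  if (t >= hi) k <- max(which(knots < hi))
  else k <- max(which(knots <= t + 1e-15))
  k <- min(max(k, p + 1), n_basis)
  N <- numeric(p + 1); N[1] <- 1
  left <- numeric(p); right <- numeric(p)
  for (j in seq_len(p)) {
    left[j] <- t - knots[k + 1 - j]
    right[j] <- knots[k + j] - t
    saved <- 0
    for (r in seq_len(j)) {
      denom <- right[r] + left[j - r + 1]
      tmp <- if (denom > 0) N[r] / denom else 0
      N[r] <- saved + right[r] * tmp
      saved <- left[j - r + 1] * tmp
    }
    N[j + 1] <- saved
  }
  out <- numeric(n_basis)
  out[(k - p):k] <- N
  out
}

#' Construct a NURBS curve
#'
#' @param control Numeric matrix `n x 2` of control points.
#' @param weights Positive weights, one per control point (default all 1).
#' @param degree Curve degree `p >= 1` (default 3).
#' @param closed Logical; closed curves wrap the control net periodically.
#' @param knots Optional knot vector; defaults to [compute_knot_vector()].
#' @return A `nurbs_curve` object.
#' @export
nurbs_curve <- function(control, weights = rep(1, nrow(control)), degree = 3L,
                        closed = TRUE, knots = NULL) {
  control <- as.matrix(control)
  if (ncol(control) != 2) stop_aaawall("control points must be n x 2")
  n <- nrow(control)
  if (n <= degree) stop_aaawall("need more control points (%d) than degree (%d)", n, degree)
  if (length(weights) != n || any(weights <= 0))
    stop_aaawall("weights must be positive, one per control point")
  if (is.null(knots)) knots <- compute_knot_vector(n, degree, closed)
  if (is.unsorted(knots)) stop_aaawall("knot vector must be non-decreasing")
  expected <- if (closed) n + 2 * degree + 1 else n + degree + 1
  if (length(knots) != expected)
    stop_aaawall("knot vector length %d, expected %d", length(knots), expected)
  structure(list(control = control, weights = weights, degree = as.integer(degree),
                 closed = closed, knots = knots), class = "nurbs_curve")
}

# wrapped control net / weights used for evaluation
curve_net <- function(curve) {
  if (!curve$closed) return(list(P = curve$control, w = curve$weights))
  p <- curve$degree
  list(P = rbind(curve$control, curve$control[seq_len(p), , drop = FALSE]),
       w = c(curve$weights, curve$weights[seq_len(p)]))
}

#' Evaluate basis functions of a curve at one parameter
#'
#' Returns the full vector of B-spline basis values `N_{i,p}(t)` over the
#' (wrapped, for closed curves) control net; these sum to 1 for any valid
#' `t`.
#'
#' @param curve A `nurbs_curve`.
#' @param t Parameter in \[0, 1\].
#' @return Numeric vector of basis values.
#' @export
curve_basis <- function(curve, t) {
  bspline_basis(t, curve$degree, curve$knots)
}

#' Evaluate a NURBS curve
#'
#' @param curve A `nurbs_curve`.
#' @param t Numeric vector of parameters in \[0, 1\].
#' @return Matrix `length(t) x 2` of curve points.
#' @export
evaluate_curve <- function(curve, t) {
  if (any(t < 0 | t > 1)) stop_aaawall("parameter t must lie in [0, 1]")
  net <- curve_net(curve)
  out <- matrix(0, length(t), 2)
  for (i in seq_along(t)) {
    N <- bspline_basis(t[i], curve$degree, curve$knots)
    nw <- N * net$w
    out[i, ] <- colSums(nw * net$P) / sum(nw)
  }
  colnames(out) <- c("x", "y")
  out
}

#' Move one control point
#'
#' Editing is local: only the portion of the curve within the basis
#' support of the moved point changes; samples outside that support are
#' bit-identical.
#'
#' @param curve A `nurbs_curve`.
#' @param index Control point index (1-based).
#' @param new_point Length-2 numeric.
#' @return The edited `nurbs_curve`.
#' @export
move_control_point <- function(curve, index, new_point) {
  if (index < 1 || index > nrow(curve$control)) stop_aaawall("control point index out of range")
  curve$control[index, ] <- new_point
  curve
}

#' Set the weight of one control point
#'
#' Increasing a weight pulls the curve toward that control point within
#' its basis support.
#'
#' @param curve A `nurbs_curve`.
#' @param index Control point index.
#' @param weight New positive weight.
#' @return The edited `nurbs_curve`.
#' @export
set_control_weight <- function(curve, index, weight) {
  if (index < 1 || index > nrow(curve$control)) stop_aaawall("control point index out of range")
  if (weight <= 0) stop_aaawall("weight must be positive")
  curve$weights[index] <- weight
  curve
}
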