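#' Sampled parametric plane curve
#'
#' Holds samples of a plane curve `(x(t), y(t))` for numerical curvature
#' analysis. At least 5 samples are required so that interior points have
#' the two neighbours on each side needed by the second-order central
#' difference stencils.
#'
#' @param t strictly increasing parameter values.
#' @param x,y coordinates (mm), same length as `t`.
#' @return An object of class `parametric_curve`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)
#' circ <- parametric_curve(th, 10 * cos(th), 10 * sin(th))
#' curvature_at(circ, 180)  # ~ 0.1 = 1/r
#' @export
parametric_curve <- function(t, x, y) {
  if (length(t) < 5L) stop("need at least 5 samples", call. = FALSE)
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("t, x, y must have equal length", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
            class = "parametric_curve")
}

# first/second derivatives of f(t) at interior index i by 3-point
# non-uniform central differences (exact for quadratics)
central_derivs <- function(t, f, i) {
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  d1 <- (f[i + 1] * h1^2 - f[i - 1] * h2^2 + f[i] * (h2^2 - h1^2)) /
    (h1 * h2 * (h1 + h2))
  d2 <- 2 * (f[i - 1] * h2 + f[i + 1] * h1 - f[i] * (h1 + h2)) /
    (h1 * h2 * (h1 + h2))
  c(d1, d2)
}

#' Curvature of a sampled curve at an interior point
#'
#' Signed-magnitude curvature of a parametric plane curve,
#' `kappa = |y'' x' - x'' y'| / (x'^2 + y'^2)^(3/2)`,
#' with derivatives taken by central finite differences. The curvature is
#' the reciprocal of the osculating-circle radius, so a sampled circle of
#' radius `r` returns `1/r` up to discretization error.
#'
#' @param curve a [parametric_curve()].
#' @param index interior sample index; must be at least 2 samples away from
#'   either endpoint.
#' @return Non-negative curvature in 1/mm.
#' @seealso [osculating_circle()]
#' @export
curvature_at <- function(curve, index) {
  stopifnot(inherits(curve, "parametric_curve"))
  n <- length(curve$t)
  if (index < 3L || index > n - 2L) {
    stop("index must be >= 2 samples away from the endpoints", call. = FALSE)
  }
  dx <- central_derivs(curve$t, curve$x, index)
  dy <- central_derivs(curve$t, curve$y, index)
  speed2 <- dx[1]^2 + dy[1]^2
  if (speed2 == 0) {
    stop("degenerate curve: zero tangent at index", call. = FALSE)
  }
  abs(dy[2] * dx[1] - dx[2] * dy[1]) / speed2^1.5
}

#' Osculating circle at an interior point of a sampled curve
#'
#' The circle tangent to the curve with matching curvature: radius
#' `1/kappa`, centre offset from the point along the unit normal on the
#' concave side. Skin nodules are modelled as osculating circles of the
#' body-surface profile, so this is the geometric object the static mode
#' reports.
#'
#' @inheritParams curvature_at
#' @return List of class `osculating_circle` with `center` (x, y) and
#'   `radius` (mm).
#' @export
osculating_circle <- function(curve, index) {
  kappa <- curvature_at(curve, index)
  if (kappa <= 0) stop("flat curve: zero curvature has no osculating circle",
                       call. = FALSE)
  dx <- central_derivs(curve$t, curve$x, index)
  dy <- central_derivs(curve$t, curve$y, index)
  cross <- dx[1] * dy[2] - dy[1] * dx[2]
  speed <- sqrt(dx[1]^2 + dy[1]^2)
  # unit normal pointing toward the concave side
  nvec <- sign(cross) * c(-dy[1], dx[1]) / speed
  r <- 1 / kappa
  structure(
    list(center = c(curve$x[index], curve$y[index]) + r * nvec, radius = r),
    class = "osculating_circle"
  )
}
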