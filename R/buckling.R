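#' Timoshenko beam-on-foundation buckling model
#'
#' Parameters of the linear buckling equation used to rationalize wrist
#' wrinkle (multi-layer skin) shapes:
#' `(P - k_p*EI - k_w*ks*GA) * v'' + k_w*ks*GA * v = 0`,
#' a Timoshenko beam on an elastic foundation reduced to second order.
#' The shear correction factor is named `kappa_shear` to keep it distinct
#' from geometric curvature (the two share a symbol in the mechanics
#' literature).
#'
#' @param P axial load (used when evaluating residuals; the critical load is
#'   solved for, so the constructor default is 0).
#' @param k_p shear constant of the foundation.
#' @param k_w spring constant of the foundation (>= 0).
#' @param kappa_shear Timoshenko shear correction factor.
#' @param GA shear stiffness (> 0).
#' @param EI flexural rigidity (> 0).
#' @param L beam length (> 0).
#' @return An object of class `buckling_model`.
#' @export
buckling_model <- function(P = 0, k_p = 0, k_w = 0, kappa_shear = 1,
                           GA = 1, EI = 1, L = 1) {
  if (EI <= 0 || GA <= 0) stop("EI and GA must be > 0", call. = FALSE)
  if (k_w < 0) stop("k_w must be >= 0", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  structure(list(P = P, k_p = k_p, k_w = k_w, kappa_shear = kappa_shear,
                 GA = GA, EI = EI, L = L),
            class = "buckling_model")
}

# foundation groupings a = k_p*EI, b = k_w*kappa_shear*GA
buckling_ab <- function(model) {
  c(a = model$k_p * model$EI, b = model$k_w * model$kappa_shear * model$GA)
}

#' Buckling solution with pinned ends
#'
#' With pinned-pinned boundary conditions `v(0) = v(L) = 0` the nontrivial
#' solutions of the buckling equation are sinusoids `v = A sin(n pi x / L)`.
#' Substituting `v'' = -(n pi / L)^2 v` gives the critical load of mode `n`:
#' `P_n = k_p*EI + k_w*ks*GA * (1 + (L / (n pi))^2)`.
#' When the foundation term `k_w*ks*GA` is zero the reduced equation admits
#' no sinusoidal bifurcation and an explicit no-buckling result is returned.
#'
#' @param model a [buckling_model()].
#' @param mode_n positive integer mode number.
#' @param n_grid number of grid points for the returned deflection profile.
#' @return List of class `buckling_solution` with `critical_load`, `buckles`
#'   (logical), and a profile (`x`, `deflection`) normalized to unit maximum
#'   deflection.
#' @seealso [buckling_critical_load_fd()] for an independent
#'   finite-difference eigenvalue solution of the same problem.
#' @examples
#' m <- buckling_model(EI = 1, GA = 1, kappa_shear = 1, k_p = 0.1, k_w = 1,
#'                     L = pi)
#' buckling_solution(m, 1)$critical_load  # 2.1
#' @export
buckling_solution <- function(model, mode_n, n_grid = 201L) {
  stopifnot(inherits(model, "buckling_model"))
  mode_n <- as.integer(mode_n)
  if (mode_n < 1L) stop("mode_n must be a positive integer", call. = FALSE)
  ab <- buckling_ab(model)
  x <- seq(0, model$L, length.out = n_grid)
  if (ab["b"] == 0) {
    return(structure(list(buckles = FALSE, critical_load = NA_real_,
                          mode_n = mode_n, x = x,
                          deflection = rep(0, n_grid)),
                     class = "buckling_solution"))
  }
  mu2 <- (mode_n * pi / model$L)^2
  p_cr <- unname(ab["a"] + ab["b"] + ab["b"] / mu2)
  if (!is.finite(p_cr) || p_cr <= 0) {
    return(structure(list(buckles = FALSE, critical_load = NA_real_,
                          mode_n = mode_n, x = x,
                          deflection = rep(0, n_grid)),
                     class = "buckling_solution"))
  }
  v <- sin(mode_n * pi * x / model$L)
  structure(list(buckles = TRUE, critical_load = p_cr, mode_n = mode_n,
                 x = x, deflection = v / max(abs(v))),
            class = "buckling_solution")
}

#' Finite-difference eigenvalue solution of the buckling critical load
#'
#' Discretizes `v''` on a uniform interior grid with the standard 3-point
#' stencil, solves the resulting symmetric eigenproblem for the curvature
#' eigenvalues `lambda_n ~ -(n pi / L)^2`, and recovers the critical load
#' `P_n = a + b - b / lambda_n` with `a = k_p*EI`, `b = k_w*ks*GA`.
#' Optional Richardson extrapolation (grids `n` and `2n`) removes the
#' leading `h^2` discretization error. This numerical route is independent
#' of the closed form in [buckling_solution()] and serves as its
#' cross-check.
#'
#' @inheritParams buckling_solution
#' @param n_interior interior grid points of the coarse grid.
#' @param richardson extrapolate over grids `n` and `2n + 1` (default TRUE).
#' @return Critical load of mode `mode_n` (numeric scalar).
#' @export
buckling_critical_load_fd <- function(model, mode_n, n_interior = 400L,
                                      richardson = TRUE) {
  stopifnot(inherits(model, "buckling_model"))
  ab <- buckling_ab(model)
  if (ab["b"] == 0) return(NA_real_)
  lam_n <- function(n) {
    h <- model$L / (n + 1)
    d2 <- diag(-2, n)
    idx <- seq_len(n - 1)
    d2[cbind(idx, idx + 1)] <- 1
    d2[cbind(idx + 1, idx)] <- 1
    ev <- eigen(d2 / h^2, symmetric = TRUE, only.values = TRUE)$values
    # eigen returns descending (all negative); mode n is the n-th closest to 0
    ev[mode_n]
  }
  lam <- lam_n(n_interior)
  if (richardson) {
    lam_fine <- lam_n(2L * n_interior + 1L)
    lam <- (4 * lam_fine - lam) / 3
  }
  unname(ab["a"] + ab["b"] - ab["b"] / lam)
}

#' Residual of a deflection profile in the buckling equation
#'
#' Evaluates `(P - a - b) v'' + b v` on the interior of a uniform grid,
#' with `v''` from 5-point fourth-order central differences, to verify that
#' a candidate profile satisfies the equation at a candidate load.
#'
#' @inheritParams buckling_solution
#' @param P axial load at which to evaluate.
#' @param x uniform grid.
#' @param v deflection samples on `x`.
#' @return Maximum absolute residual over the interior grid.
#' @export
buckling_residual <- function(model, P, x, v) {
  ab <- buckling_ab(model)
  h <- x[2] - x[1]
  i <- 3:(length(x) - 2)
  d2 <- (-v[i + 2] + 16 * v[i + 1] - 30 * v[i] + 16 * v[i - 1] - v[i - 2]) /
    (12 * h^2)
  max(abs((P - ab["a"] - ab["b"]) * d2 + ab["b"] * v[i]))
}
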