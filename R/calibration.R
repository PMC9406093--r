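#' Per-node calibration factors
#'
#' Fabrication non-uniformity (screen-printing thickness, film sagging,
#' nanoparticle dispersion) biases each node's gain. On a surface of uniform
#' curvature every node should read the same, so the correction factor of a
#' node is the grand mean divided by that node's mean:
#' multiplying each node by its factor equalizes all node means. A node that
#' reads 25% high gets factor 0.80; one reading at `mean/1.49` gets 1.49.
#'
#' @param node_means per-node mean ADC counts from a uniform-curvature
#'   recording (all > 0).
#' @return Object of class `node_calibration` with `factors` and
#'   `reference_mean`.
#' @examples
#' node_factors(c(100, 100, 125, 75))
#' @export
node_factors <- function(node_means) {
  if (any(!is.finite(node_means))) stop("node means must be finite", call. = FALSE)
  dead <- which(node_means == 0)
  if (length(dead) > 0) {
    stop(sprintf("dead node(s) with zero mean: %s",
                 paste(dead, collapse = ", ")), call. = FALSE)
  }
  if (any(node_means < 0)) stop("node means must be > 0", call. = FALSE)
  m <- mean(node_means)
  structure(list(factors = m / node_means, reference_mean = m),
            class = "node_calibration")
}

#' @rdname node_factors
#' @param cal a `node_calibration`.
#' @param values ADC matrix (frames x nodes) or vector of node values.
#' @return `apply_factors()`: the calibrated values.
#' @export
apply_factors <- function(cal, values) {
  stopifnot(inherits(cal, "node_calibration"))
  if (is.matrix(values)) {
    sweep(values, 2, cal$factors, `*`)
  } else {
    values * cal$factors
  }
}

#' Empirical ADC-to-curvature calibration
#'
#' The per-node ADC signal grows linearly with surface curvature; the
#' empirical law is `kappa = (S_I + C1) / C2` with device constants
#' `C1 = 82.6` (ADC offset) and `C2 = 6927.6` (ADC per 1/mm). The defaults
#' are the fitted constants of the characterized device.
#'
#' @param c1 ADC offset constant.
#' @param c2 ADC counts per unit curvature (1/mm); must be > 0.
#' @param r_squared goodness of fit of the source regression (optional).
#' @return Object of class `curvature_calibration`.
#' @export
curvature_calibration <- function(c1 = 82.6, c2 = 6927.6, r_squared = NA_real_) {
  if (c2 <= 0) stop("c2 must be > 0", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]", call. = FALSE)
  }
  structure(list(c1 = c1, c2 = c2, r_squared = r_squared),
            class = "curvature_calibration")
}

#' Convert an ADC signal to curvature
#'
#' Applies `kappa = (S_I + C1) / C2`. Signals below `-C1` (which would give
#' negative curvature, i.e. flatter than flat) clip to zero with a warning.
#' The per-count curvature resolution of the device is `1 / C2`.
#'
#' @param signal ADC count(s).
#' @param cal a [curvature_calibration()].
#' @return Curvature(s) in 1/mm. `curvature_resolution()` returns the
#'   curvature change per single ADC count; `curvature_radius()` the
#'   osculating radius `1/kappa` in mm.
#' @examples
#' adc_to_curvature(184.7)            # ~0.0386 1/mm (neck nodule reading)
#' signif(curvature_resolution(), 2)  # 0.00014 1/mm per count
#' @export
adc_to_curvature <- function(signal, cal = curvature_calibration()) {
  stopifnot(inherits(cal, "curvature_calibration"))
  kappa <- (signal + cal$c1) / cal$c2
  if (any(kappa < 0)) {
    warning("signal below -C1; curvature clipped to 0", call. = FALSE)
    kappa <- pmax(kappa, 0)
  }
  kappa
}

#' @rdname adc_to_curvature
#' @export
curvature_resolution <- function(cal = curvature_calibration()) {
  1 / cal$c2
}

#' @rdname adc_to_curvature
#' @param kappa curvature(s) in 1/mm, > 0.
#' @export
curvature_radius <- function(kappa) {
  if (any(kappa <= 0)) stop("radius undefined for non-positive curvature",
                            call. = FALSE)
  1 / kappa
}

#' Fit the linear ADC-curvature law
#'
#' Ordinary least squares of mean ADC on curvature over reference objects of
#' known curvature (calibration cylinders use `kappa = 2 / diameter`). The
#' empirical calibration constants follow as `c2 = slope`,
#' `c1 = -intercept`.
#'
#' @param curvatures curvature values (1/mm), at least 3 distinct.
#' @param mean_adc mean ADC per object, same length.
#' @return List of class `curvature_fit` with `slope`, `intercept`,
#'   `r_squared`, and `calibration` (a [curvature_calibration()]).
#' @examples
#' k <- 2 / c(53, 65, 82, 90, 100)
#' fit_curvature_line(k, 6927.6 * k - 82.6)
#' @export
fit_curvature_line <- function(curvatures, mean_adc) {
  if (length(curvatures) != length(mean_adc)) {
    stop("curvatures and mean_adc must have equal length", call. = FALSE)
  }
  if (length(unique(curvatures)) < 3L) {
    stop("need at least 3 distinct curvature values", call. = FALSE)
  }
  fit <- stats::lm(mean_adc ~ curvatures)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((mean_adc - mean(mean_adc))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  cal <- if (slope > 0) {
    curvature_calibration(c1 = -intercept, c2 = slope,
                          r_squared = min(max(r2, 0), 1))
  } else NULL  # a non-increasing line cannot serve as a forward law
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 calibration = cal),
            class = "curvature_fit")
}

#' @export
print.curvature_fit <- function(x, ...) {
  cat(sprintf("<curvature_fit> ADC = %.1f * kappa %+.1f   (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Subtract the attachment baseline from a trace
#'
#' The per-node baseline is the mean over the initial idle window after
#' attachment; deformation is the (optionally factor-calibrated) ADC minus
#' that baseline. Negative values mean concave (dented) skin, positive
#' convex.
#'
#' @param trace an [adc_trace()] covering at least `idle_window` seconds
#'   from its start.
#' @param idle_window idle duration in seconds used for the baseline
#'   (default 2 s, 60 frames at 30 Hz).
#' @param factors optional [node_factors()] calibration applied before
#'   baseline subtraction.
#' @return A `deformation_map` (see [build_map()]).
#' @export
subtract_baseline <- function(trace, idle_window = 2, factors = NULL) {
  stopifnot(inherits(trace, "adc_trace"))
  vals <- trace_values(trace)
  if (!is.null(factors)) vals <- apply_factors(factors, vals)
  t <- trace$t_s
  # half-open window [t0, t0 + idle_window): the first post-idle frame is
  # not part of the baseline
  idle <- t < t[1] + idle_window
  if (sum(idle) < 1L || (t[length(t)] - t[1]) < idle_window) {
    stop("trace shorter than the idle window; cannot take a baseline",
         call. = FALSE)
  }
  baseline <- colMeans(vals[idle, , drop = FALSE])
  new_deformation_map(sweep(vals, 2, baseline), times = t,
                      nodes = seq_len(ncol(vals)))
}

#' Segment a static-mode trace into event stages
#'
#' Static-mode recordings pass through three stages: attachment/idle (I),
#' curvature change (II) while the baseline-relative signal is at or above
#' the onset level, and detachment (III). Detachment is recognized by its
#' signature collapse: every node losing at least 90% of its level within
#' one frame (peeling breaks all contacts at once). If the signal returns
#' below the onset level after an onset, the alleviation flag is set — the
#' degree of nodule alleviation is measurable within stage II.
#'
#' @param trace an [adc_trace()].
#' @param onset_level ADC threshold on the mean baseline-subtracted signal.
#' @param idle_window seconds used for the baseline (see
#'   [subtract_baseline()]).
#' @return List of class `stage_segmentation`: per-frame `labels` (factor
#'   with levels `attach_idle`, `curvature_change`, `detach`), `onset_level`,
#'   `alleviation` flag, and the onset/detach frame indices (NA if absent).
#' @export
detect_stages <- function(trace, onset_level, idle_window = 2) {
  stopifnot(inherits(trace, "adc_trace"))
  vals <- trace_values(trace)
  n <- nrow(vals)
  lv <- c("attach_idle", "curvature_change", "detach")
  labels <- rep("attach_idle", n)
  t <- trace$t_s
  idle <- t < t[1] + idle_window
  baseline <- colMeans(vals[idle, , drop = FALSE])
  rel <- rowMeans(sweep(vals, 2, baseline))

  # detachment: all nodes drop >= 90% of their current level in one frame
  detach_at <- NA_integer_
  if (n >= 2L) {
    prev <- vals[-n, , drop = FALSE]
    cur <- vals[-1, , drop = FALSE]
    collapse <- rowSums(prev > 0 & cur <= 0.1 * prev) == ncol(vals) &
      apply(prev > 0, 1, all)
    if (any(collapse)) detach_at <- which(collapse)[1] + 1L
  }
  active <- if (is.na(detach_at)) seq_len(n) else seq_len(detach_at - 1L)
  in_change <- rel >= onset_level
  in_change[!idle] <- in_change[!idle]
  labels[active][in_change[active]] <- "curvature_change"
  if (!is.na(detach_at)) labels[detach_at:n] <- "detach"

  onset_at <- if (any(labels == "curvature_change")) {
    which(labels == "curvature_change")[1]
  } else NA_integer_
  alleviation <- FALSE
  if (!is.na(onset_at)) {
    after <- labels[seq(onset_at, if (is.na(detach_at)) n else detach_at - 1L)]
    alleviation <- any(after == "attach_idle")
  }
  structure(list(labels = factor(labels, levels = lv),
                 onset_level = onset_level, onset_frame = onset_at,
                 detach_frame = detach_at, alleviation = alleviation),
            class = "stage_segmentation")
}
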