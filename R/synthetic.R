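# Synthetic-data generators: per-finger wrist deformation templates,
# gesture maps with superposition/interference, cylinder-phantom traces and
# the post-attachment drift trace. These define the study conditions every
# test and evaluation runs under.

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Noise model for synthetic patch signals
#'
#' Additive Gaussian frame noise plus fixed per-node multiplicative gain
#' deviations (the fabrication non-uniformity that calibration factors
#' remove). The default deviation vector for the 6-node static sticker has
#' node 5 reading 25% high and node 2 reading low (1/1.49), matching the
#' characterized device; its mean is exactly 1 so calibration factors are
#' clean reciprocals.
#'
#' @param sigma ADC noise standard deviation (counts), >= 0. Default 10, a
#'   realistic frame noise for ~200-count signals.
#' @param node_deviation per-node multiplicative factors (> 0), or `NULL`
#'   for the context default (static default below for 6 nodes, all-ones
#'   otherwise).
#' @param seed integer RNG seed; all generator randomness flows through it.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma = 10, node_deviation = NULL, seed = 0L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.null(node_deviation) && any(node_deviation <= 0)) {
    stop("node deviations must be > 0", call. = FALSE)
  }
  structure(list(sigma = sigma, node_deviation = node_deviation,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# default per-node gain deviations of the 6-node static sticker (mean 1;
# node 5 reads 25% high -> factor 0.80, node 2 low -> factor 1.49)
static_node_deviation <- function() c(0.96, 0.671, 1.03, 1.10, 1.25, 0.989)

#' Per-finger wrist deformation templates
#'
#' Phenomenological per-node signal-change profiles of the 10-node wrist
#' bandage when one finger folds (palm up, node 1 nearest the little
#' finger, node 10 nearest the thumb). Each template has a negative core
#' at the finger's characteristic nodes — thumb at node 9 (node 8 weakly
#' indented), index at node 8 with valleys to 7 and 9, middle at node 6
#' reaching 5 and 4, ring at node 5 flanked by 4 and 6, little with two
#' comparable peaks at nodes 3 and 4 — and positive side lobes where the
#' periphery skin rises (e.g. thumb at nodes 7 and 10, index at 6 and 10).
#'
#' Template magnitudes are free parameters of the generator. The default
#' `lobe_gain` is calibrated once so that the mean total negative
#' deformation of four-finger folds is 3.49 times that of single folds,
#' with near-linear growth in the number of folded fingers.
#'
#' @param scale depth of a primary single-finger core in ADC counts
#'   (default 100; all template values scale with it).
#' @param lobe_gain gain on the positive side lobes (default 1.563, the
#'   calibrated value).
#' @return Named list of class `finger_templates` with one 10-vector per
#'   finger (`thumb`, `index`, `middle`, `ring`, `little`).
#' @export
finger_templates <- function(scale = 100, lobe_gain = 1.563) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  g <- lobe_gain
  tpl <- list(
    thumb  = c(0, 0, 0, 0, 0, 0, 25 * g, -35, -100, 20 * g),
    index  = c(0, 0, 0, 0, 0, 40 * g, -45, -100, -45, 15 * g),
    middle = c(0, 0, 20 * g, -25, -75, -100, 30 * g, 0, 0, 0),
    ring   = c(0, 0, 25 * g, -55, -100, -55, 30 * g, 0, 0, 0),
    little = c(0, 15 * g, -85, -80, 25 * g, 0, 0, 0, 0, 0)
  )
  structure(lapply(tpl, function(v) v * scale / 100),
            class = "finger_templates", scale = scale, lobe_gain = g)
}

#' Finger-binary codes and naturalness
#'
#' A finger binary is a 5-character string over `{0,1}` ordered thumb to
#' little, 1 = folded. There are 32 codes; `00000` (all unfolded) is the
#' no-signal default. Codes where the little finger folds while the ring
#' finger stays up are anatomically awkward: the ring finger co-folds
#' involuntarily, so the map is not the linear sum of the coded fingers.
#'
#' @return `gesture_codes()`: the 32 codes; `finger_names()`: the five
#'   finger labels in code order; `single_finger_codes()`: named codes for
#'   single folds.
#' @export
gesture_codes <- function() {
  vapply(0:31, function(i) {
    paste(rev(as.integer(intToBits(i))[1:5]), collapse = "")
  }, character(1))
}

#' @rdname gesture_codes
#' @export
finger_names <- function() c("thumb", "index", "middle", "ring", "little")

#' @rdname gesture_codes
#' @export
single_finger_codes <- function() {
  stats::setNames(c("10000", "01000", "00100", "00010", "00001"),
                  finger_names())
}

#' @rdname gesture_codes
#' @param binary a 5-character finger binary.
#' @param unnatural_set codes treated as unnatural (default the awkward
#'   ring-up/little-down set).
#' @export
is_natural_gesture <- function(binary,
                               unnatural_set = c("01001", "00101", "01101",
                                                 "10101", "11101")) {
  check_binary(binary)
  !(binary %in% unnatural_set)
}

check_binary <- function(binary) {
  if (!is.character(binary) || length(binary) != 1L ||
      !grepl("^[01]{5}$", binary)) {
    stop("finger binary must be a 5-character string over {0,1}",
         call. = FALSE)
  }
  invisible(binary)
}

#' Noiseless composite node profile of a finger binary
#'
#' Natural gestures superpose linearly: the profile is the sum of the
#' folded fingers' templates. Unnatural gestures additionally fold the ring
#' finger involuntarily and acquire an interference bump at its peak node
#' (node 5), so they are *not* the linear sum. A closed fist (`11111`)
#' experiences mutual interference that partially relieves the crowded
#' negative region (nodes 3 and 6), so its total negative deformation drops
#' below the four-finger level.
#'
#' @inheritParams is_natural_gesture
#' @param templates a [finger_templates()] set.
#' @param interference depth of the unnatural-gesture bump at node 5
#'   (default 160 ADC counts; scaled with the template scale).
#' @param fist_relief positive relief at nodes 3 and 6 for `11111`
#'   (default 70, scaled likewise).
#' @return Numeric 10-vector of expected signal change per node.
#' @export
gesture_profile <- function(binary, templates = finger_templates(),
                            interference = 160, fist_relief = 70,
                            unnatural_set = c("01001", "00101", "01101",
                                              "10101", "11101")) {
  check_binary(binary)
  s <- attr(templates, "scale") / 100
  bits <- as.integer(strsplit(binary, "")[[1]])
  p <- rep(0, length(templates[[1]]))
  for (f in finger_names()[bits == 1]) p <- p + templates[[f]]
  if (binary %in% unnatural_set) {
    p <- p + templates$ring
    p[5] <- p[5] - interference * s
  }
  if (binary == "11111") {
    p[3] <- p[3] + fist_relief * s
    p[6] <- p[6] + fist_relief * s
  }
  p
}

#' Simulate one gesture epoch as a deformation map
#'
#' Builds the composite node profile of the gesture (see
#' [gesture_profile()]), applies a fold-and-hold temporal envelope (linear
#' ramp over `ramp_s`, then hold), and adds i.i.d. Gaussian frame noise.
#' `00000` with zero noise gives an all-zero map.
#'
#' @inheritParams gesture_profile
#' @param noise a [noise_model()]; `noise$seed` makes the map reproducible.
#' @param n_frames epoch length in frames (default 60 = 2 s at 30 Hz).
#' @param sampling_hz frame rate.
#' @param ramp_s fold ramp duration in seconds.
#' @return A `deformation_map` (frames x 10 nodes).
#' @examples
#' m <- simulate_gesture("00111", finger_templates(), noise_model(sigma = 0))
#' @export
simulate_gesture <- function(binary, templates = finger_templates(),
                             noise = noise_model(), n_frames = 60L,
                             sampling_hz = 30, ramp_s = 0.5,
                             interference = 160, fist_relief = 70,
                             unnatural_set = c("01001", "00101", "01101",
                                               "10101", "11101")) {
  profile <- gesture_profile(binary, templates, interference, fist_relief,
                             unnatural_set)
  t <- (seq_len(n_frames) - 1L) / sampling_hz
  env <- pmin(t / ramp_s, 1)
  vals <- outer(env, profile)
  if (noise$sigma > 0) {
    vals <- vals + with_seed(noise$seed, {
      matrix(stats::rnorm(length(vals), 0, noise$sigma), nrow = n_frames)
    })
  }
  new_deformation_map(vals, times = t, nodes = seq_along(profile))
}

#' Simulate a cylinder-phantom recording
#'
#' Static-mode calibration input: the sticker wrapped on a cylinder of
#' known diameter reads, at every node, the ADC implied by the linear
#' curvature law (`kappa = 2 / diameter`), scaled by that node's gain
#' deviation, plus frame noise. Smaller cylinders give stronger signals.
#'
#' @param diameter cylinder diameter in mm (> 0).
#' @param cal a [curvature_calibration()] defining the forward law.
#' @param noise a [noise_model()]; `node_deviation = NULL` uses the static
#'   6-node default deviations.
#' @param n_frames number of frames (default 100).
#' @param config a [patch_config()]; default 6-node static sticker.
#' @return An [adc_trace()].
#' @export
simulate_cylinder <- function(diameter, cal = curvature_calibration(),
                              noise = noise_model(sigma = 5),
                              n_frames = 100L,
                              config = patch_config(node_count = 6L)) {
  if (diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  dev <- noise$node_deviation
  if (is.null(dev)) {
    dev <- if (config$node_count == 6L) static_node_deviation()
           else rep(1, config$node_count)
  }
  if (length(dev) != config$node_count) {
    stop("node_deviation length must match node_count", call. = FALSE)
  }
  kappa <- 2 / diameter
  ideal <- (cal$c2 * kappa - cal$c1) * dev
  vals <- matrix(rep(ideal, each = n_frames), nrow = n_frames)
  if (noise$sigma > 0) {
    vals <- vals + with_seed(noise$seed, {
      matrix(stats::rnorm(length(vals), 0, noise$sigma), nrow = n_frames)
    })
  }
  vals <- pmin(pmax(vals, 0), config$adc_full_scale)
  adc_trace((seq_len(n_frames) - 1L) / config$sampling_hz, vals, config)
}

#' Simulate a labeled set of single-finger trials
#'
#' Generates `n_per_finger` noisy gesture maps for each of the five
#' single-finger codes, with ground-truth labels — the synthetic stand-in
#' for the single-finger classification experiment (150 trials per finger
#' gives the 750-trial total of the reference evaluation).
#'
#' @param n_per_finger trials per finger (>= 1).
#' @inheritParams simulate_gesture
#' @param seed master seed; each trial derives its own sub-seed, so the
#'   whole set is reproducible.
#' @param ... further arguments passed to [simulate_gesture()].
#' @return List of class `trial_set`; each element has `map`, `finger`,
#'   `binary`.
#' @export
simulate_trial_set <- function(n_per_finger, templates = finger_templates(),
                               noise = noise_model(), seed = 1L, ...) {
  n_per_finger <- as.integer(n_per_finger)
  if (n_per_finger < 1L) stop("n_per_finger must be >= 1", call. = FALSE)
  codes <- single_finger_codes()
  trials <- vector("list", 5L * n_per_finger)
  k <- 0L
  for (f in names(codes)) {
    for (i in seq_len(n_per_finger)) {
      k <- k + 1L
      nm <- noise_model(sigma = noise$sigma,
                        node_deviation = noise$node_deviation,
                        seed = as.integer(seed) * 100003L + k)
      trials[[k]] <- list(map = simulate_gesture(codes[[f]], templates,
                                                 nm, ...),
                          finger = f, binary = codes[[f]])
    }
  }
  structure(trials, class = "trial_set", seed = as.integer(seed))
}

#' Post-attachment drift specification and trace
#'
#' After attachment the contact resistance settles, so the signal decays
#' for a while. The settling trace is recorded for 60 s at 2 s intervals
#' (31 samples); the first 26 samples form the training set and the last 5
#' the test set of the drift predictor. The generator emits
#' `y(t) = baseline + amplitude * exp(-t / tau)` plus Gaussian noise, on a
#' normalized signal scale.
#'
#' @param duration_s recording length (default 60 s).
#' @param interval_s sampling interval (default 2 s).
#' @param amplitude decay amplitude on the normalized scale (default 0.3).
#' @param tau_s decay time constant (default 15 s).
#' @param baseline settled signal level (default 0.7).
#' @param sigma noise standard deviation on the normalized scale
#'   (default 0.02).
#' @return `drift_spec()`: an object of class `drift_spec`.
#' @export
drift_spec <- function(duration_s = 60, interval_s = 2, amplitude = 0.3,
                       tau_s = 15, baseline = 0.7, sigma = 0.02) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (tau_s <= 0) stop("tau_s must be > 0", call. = FALSE)
  structure(list(duration_s = duration_s, interval_s = interval_s,
                 amplitude = amplitude, tau_s = tau_s, baseline = baseline,
                 sigma = sigma),
            class = "drift_spec")
}

#' @rdname drift_spec
#' @param spec a `drift_spec`.
#' @param seed integer RNG seed.
#' @return `simulate_attachment_drift()`: a [drift_trace()] with the
#'   chronological train/test split (26/5 under the defaults).
#' @export
simulate_attachment_drift <- function(spec = drift_spec(), seed = 7L) {
  t <- seq(0, spec$duration_s, by = spec$interval_s)
  y <- spec$baseline + spec$amplitude * exp(-t / spec$tau_s)
  if (spec$sigma > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(t), 0, spec$sigma))
  }
  drift_trace(t, y)
}
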