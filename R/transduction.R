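#' Voltage-divider transduction of the patch resistance
#'
#' The patch node and a reference resistor form a divider:
#' `V_out = V_in * R_ref / (R_patch + R_ref)`. Full contact (`r_patch = 0`)
#' returns the input voltage; an open circuit (no skin contact,
#' `r_patch = Inf`) returns exactly zero. Open circuit is represented by the
#' `Inf` sentinel rather than a large finite resistance so the zero is exact.
#'
#' @param r_patch patch node resistance in ohm; `Inf` for open circuit.
#'   Vectorized.
#' @param v_in divider input voltage (V), > 0.
#' @param r_ref reference resistance (ohm), > 0.
#' @return Output voltage(s) in volts, strictly decreasing in `r_patch`.
#' @examples
#' transduce(0, 3.3, 10e3)    # 3.3  (full contact)
#' transduce(Inf, 3.3, 10e3)  # 0    (no contact)
#' transduce(10e3, 3.3, 10e3) # 1.65 (symmetric divider)
#' @export
transduce <- function(r_patch, v_in, r_ref) {
  stopifnot_scalar_number(v_in, "v_in")
  stopifnot_scalar_number(r_ref, "r_ref")
  if (v_in <= 0) stop("v_in must be > 0", call. = FALSE)
  if (r_ref <= 0) stop("r_ref must be > 0", call. = FALSE)
  if (any(is.na(r_patch)) || any(r_patch < 0)) {
    stop("r_patch must be >= 0 (Inf for open circuit)", call. = FALSE)
  }
  out <- v_in * r_ref / (r_patch + r_ref)
  out[is.infinite(r_patch)] <- 0
  out
}

#' Quantize a divider output voltage to an ADC count
#'
#' Linear quantization of `v_out` against the `v_in` reference:
#' `round(v_out / v_in * adc_full_scale)`, clipped to the ADC range.
#' Voltages above `v_in` are clipped to full scale with a warning.
#'
#' @param v_out output voltage(s) from [transduce()].
#' @param v_in ADC reference voltage (the divider input).
#' @param config a [patch_config()] supplying `adc_full_scale`.
#' @return Integer ADC count(s) in `[0, adc_full_scale]`.
#' @examples
#' quantize_adc(1.65, 3.3, patch_config())  # 512 at 10 bit
#' @export
quantize_adc <- function(v_out, v_in, config = patch_config()) {
  stopifnot_scalar_number(v_in, "v_in")
  if (any(v_out < 0)) stop("v_out must be >= 0", call. = FALSE)
  if (any(v_out > v_in)) {
    warning("v_out above v_in; clipping to full scale", call. = FALSE)
  }
  fs <- config$adc_full_scale
  as.integer(pmin(pmax(round(v_out / v_in * fs), 0), fs))
}

#' Per-node resistance state and resistance change
#'
#' The patch signal derives from the total per-node resistance change
#' `delta_R = R_initial - R_final` between the unfolded (initial) and folded
#' (final) state. Concave skin under a node lifts the substrates apart and
#' raises the resistance, so `delta_R` is negative there; raised (convex)
#' skin increases contact and gives positive `delta_R`.
#'
#' @param r_initial,r_final per-node resistances in ohm (equal length, > 0;
#'   `Inf` marks open circuit).
#' @return `resistance_state()`: an object of class `resistance_state`.
#' @examples
#' st <- resistance_state(c(10e3, 10e3), c(4e3, 12e3))
#' delta_resistance(st)  # 6000, -2000
#' @export
resistance_state <- function(r_initial, r_final) {
  if (length(r_initial) != length(r_final)) {
    stop("r_initial and r_final must have the same length", call. = FALSE)
  }
  if (any(r_initial <= 0) || any(r_final <= 0)) {
    stop("resistances must be > 0 (Inf for open circuit)", call. = FALSE)
  }
  structure(list(r_initial = r_initial, r_final = r_final),
            class = "resistance_state")
}

#' @rdname resistance_state
#' @param state a `resistance_state`.
#' @return `delta_resistance()`: numeric vector of per-node resistance
#'   changes (ohm).
#' @export
delta_resistance <- function(state) {
  stopifnot(inherits(state, "resistance_state"))
  state$r_initial - state$r_final
}
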