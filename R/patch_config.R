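#' Patch configuration
#'
#' Geometry and electrical constants of the sensor patch. Defaults follow the
#' fabricated device: 7.45 mm node pitch, 76 um total thickness, 30 Hz
#' sampling. The wrist bandage uses 10 nodes; the static curvature sticker
#' uses 6. The patch is size-cuttable, so `node_count` is free.
#'
#' `v_in` and `r_ref` set the voltage divider; only their ratio to the patch
#' resistance matters downstream. ADC bit depth defaults to 10 bits
#' (`adc_full_scale = 1023`).
#'
#' @param node_count number of sensor nodes (default 10, the wrist bandage).
#' @param pitch_mm centre-to-centre node pitch in mm.
#' @param thickness_um total sticker thickness in micrometres.
#' @param sampling_hz frame rate in Hz.
#' @param v_in divider input voltage (V).
#' @param r_ref divider reference resistance (ohm).
#' @param adc_bits ADC resolution in bits.
#'
#' @return An object of class `patch_config`.
#' @examples
#' cfg <- patch_config()
#' cfg$adc_full_scale  # 1023
#' @export
patch_config <- function(node_count = 10L, pitch_mm = 7.45, thickness_um = 76,
                         sampling_hz = 30, v_in = 3.3, r_ref = 10e3,
                         adc_bits = 10L) {
  node_count <- as.integer(node_count)
  adc_bits <- as.integer(adc_bits)
  if (node_count < 1L) stop("node_count must be >= 1", call. = FALSE)
  if (pitch_mm <= 0) stop("pitch_mm must be > 0", call. = FALSE)
  if (sampling_hz <= 0) stop("sampling_hz must be > 0", call. = FALSE)
  if (adc_bits < 1L) stop("adc_bits must be >= 1", call. = FALSE)
  if (v_in <= 0 || r_ref <= 0) stop("v_in and r_ref must be > 0", call. = FALSE)
  structure(
    list(node_count = node_count, pitch_mm = pitch_mm,
         thickness_um = thickness_um, sampling_hz = sampling_hz,
         v_in = v_in, r_ref = r_ref, adc_bits = adc_bits,
         adc_full_scale = as.integer(2^adc_bits - 1)),
    class = "patch_config"
  )
}

#' @export
print.patch_config <- function(x, ...) {
  cat(sprintf(
    "<patch_config> %d nodes, pitch %.2f mm, %g Hz, %d-bit ADC (full scale %d)\n",
    x$node_count, x$pitch_mm, x$sampling_hz, x$adc_bits, x$adc_full_scale))
  invisible(x)
}

#' ADC trace constructor and CSV input/output
#'
#' A trace is one patch recording: a data frame with a time column `t_s`
#' (seconds) followed by `node_1 .. node_N` ADC columns, one row per frame.
#'
#' @param t numeric vector of frame times (s), strictly increasing.
#' @param values numeric matrix of ADC counts, one row per frame, one column
#'   per node.
#' @param config a [patch_config()]; used to check value ranges.
#' @return A data frame of class `adc_trace`.
#' @examples
#' tr <- adc_trace(c(0, 1/30), rbind(c(100, 120), c(101, 119)),
#'                 patch_config(node_count = 2))
#' @export
adc_trace <- function(t, values, config = patch_config()) {
  values <- as.matrix(values)
  if (length(t) != nrow(values)) {
    stop("length(t) must equal nrow(values)", call. = FALSE)
  }
  if (ncol(values) != config$node_count) {
    stop(sprintf("trace has %d node columns but config expects %d",
                 ncol(values), config$node_count), call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (any(values < 0 | values > config$adc_full_scale)) {
    stop("ADC values outside [0, adc_full_scale]", call. = FALSE)
  }
  out <- data.frame(t_s = t, values)
  names(out) <- c("t_s", paste0("node_", seq_len(config$node_count)))
  class(out) <- c("adc_trace", "data.frame")
  attr(out, "config") <- config
  out
}

#' @rdname adc_trace
#' @param file path of a trace CSV (`t_s, node_1..node_N`).
#' @export
read_trace <- function(file, config = NULL) {
  df <- utils::read.csv(file, comment.char = "#")
  if (names(df)[1] != "t_s") stop("first trace column must be t_s", call. = FALSE)
  n <- ncol(df) - 1L
  if (is.null(config)) config <- patch_config(node_count = n)
  adc_trace(df$t_s, as.matrix(df[, -1, drop = FALSE]), config)
}

#' @rdname adc_trace
#' @param trace an `adc_trace`.
#' @param seed optional integer written as a header comment so outputs record
#'   their generator seed.
#' @export
write_trace <- function(trace, file, seed = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(as.data.frame(unclass(trace)), con, row.names = FALSE)
  invisible(file)
}

# node value matrix of a trace (frames x nodes)
trace_values <- function(trace) {
  as.matrix(as.data.frame(unclass(trace))[, -1, drop = FALSE])
}
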