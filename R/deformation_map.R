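# deformation_map: rectangular node x time grid of baseline-subtracted
# signal change. Stored as a frames x nodes matrix with time/node axes in
# attributes; negative values = concave skin.

new_deformation_map <- function(values, times, nodes, interpolated = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times), ncol(values) == length(nodes))
  structure(values, times = as.numeric(times), nodes = as.numeric(nodes),
            interpolated = interpolated,
            class = c("deformation_map", "matrix", "array"))
}

#' Deformation map accessors
#'
#' @param map a `deformation_map` (frames x nodes grid of baseline-subtracted
#'   ADC change; negative = concave skin).
#' @return `map_times()` / `map_nodes()` return the grid axes;
#'   `map_values()` the bare matrix.
#' @export
map_times <- function(map) attr(map, "times")

#' @rdname map_times
#' @export
map_nodes <- function(map) attr(map, "nodes")

#' @rdname map_times
#' @export
map_values <- function(map) {
  out <- unclass(map)
  attr(out, "times") <- NULL
  attr(out, "nodes") <- NULL
  attr(out, "interpolated") <- NULL
  out
}

#' @export
print.deformation_map <- function(x, ...) {
  v <- map_values(x)
  cat(sprintf(
    "<deformation_map> %d frames x %d nodes%s; range [%.1f, %.1f]\n",
    nrow(v), ncol(v), if (isTRUE(attr(x, "interpolated"))) " (interpolated)" else "",
    min(v), max(v)))
  invisible(x)
}

#' Build a deformation map from raw frames
#'
#' Subtracts a per-node baseline from a trace and optionally refines the
#' node axis by linear interpolation (for smooth rendered maps). With
#' `upsample = u` the node axis gains `u - 1` interpolated columns between
#' each pair of nodes, preserving the original node values at the original
#' positions; interpolated maps are flagged and not accepted by the decoder.
#'
#' @param trace an [adc_trace()].
#' @param baseline per-node baseline vector, or `NULL` to use the mean over
#'   the initial `idle_window` seconds.
#' @param upsample integer node-axis refinement factor (default 1 = off).
#' @param idle_window seconds of idle used when `baseline` is `NULL`.
#' @param factors optional [node_factors()] calibration.
#' @return A `deformation_map`.
#' @export
build_map <- function(trace, baseline = NULL, upsample = 1L, idle_window = 2,
                      factors = NULL) {
  stopifnot(inherits(trace, "adc_trace"))
  if (nrow(trace) < 1L) stop("empty trace", call. = FALSE)
  if (is.null(baseline)) {
    map <- subtract_baseline(trace, idle_window = idle_window,
                             factors = factors)
  } else {
    vals <- trace_values(trace)
    if (!is.null(factors)) vals <- apply_factors(factors, vals)
    if (length(baseline) != ncol(vals)) {
      stop("baseline length must match node count", call. = FALSE)
    }
    map <- new_deformation_map(sweep(vals, 2, baseline), times = trace$t_s,
                               nodes = seq_len(ncol(vals)))
  }
  upsample <- as.integer(upsample)
  if (upsample > 1L) {
    nodes <- map_nodes(map)
    xout <- seq(nodes[1], nodes[length(nodes)], by = 1 / upsample)
    v <- map_values(map)
    vi <- t(apply(v, 1, function(row) {
      stats::approx(nodes, row, xout = xout)$y
    }))
    map <- new_deformation_map(vi, times = map_times(map), nodes = xout,
                               interpolated = TRUE)
  }
  map
}

#' Per-node depth profile of a deformation map
#'
#' Summarizes a gesture-epoch map as one value per node: the minimum over
#' time after light temporal smoothing (moving average). The smoothing
#' keeps frame noise from biasing the minimum while the hold phase of the
#' gesture dominates. This profile is what the decoder scores.
#'
#' @param map a `deformation_map` on the original (integer) node axis.
#' @param smooth_frames moving-average window in frames (default 5).
#' @return Numeric vector, one depth per node (negative = concave).
#' @export
node_profile <- function(map, smooth_frames = 5L) {
  v <- map_values(map)
  w <- min(as.integer(smooth_frames), nrow(v))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    v <- apply(v, 2, function(col) {
      if (length(col) < w) return(col)
      stats::filter(col, kern, sides = 2)
    })
    v <- as.matrix(v)
  }
  apply(v, 2, function(col) min(col, na.rm = TRUE))
}

#' Deformation map CSV input/output
#'
#' Maps are written with rows = time and columns `t_s, node_1..node_N`
#' (fractional node positions from upsampled maps are written as
#' `node_1.25`-style headers and read back as such).
#'
#' @param map a `deformation_map`.
#' @param file path to a CSV file.
#' @param seed optional integer recorded as a header comment.
#' @export
write_map <- function(map, file, seed = NULL) {
  df <- data.frame(t_s = map_times(map), map_values(map))
  names(df) <- c("t_s", paste0("node_", map_nodes(map)))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_map
#' @export
read_map <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  nodes <- as.numeric(sub("^node_", "", names(df)[-1]))
  interp <- any(nodes != round(nodes))
  new_deformation_map(as.matrix(df[, -1, drop = FALSE]), times = df$t_s,
                      nodes = nodes, interpolated = interp)
}
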