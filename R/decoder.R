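#' Decoder rules
#'
#' The fixed decision constants of the gesture decoder: the characteristic
#' peak node of each finger (thumb 9, index 8, middle 6, ring 5, little the
#' pair 3 and 4), the depth margins that disambiguate the four-and-five
#' finger quartet sharing core-line nodes — `11101` runs at least 107
#' deeper at node 5, `11110` at least 50 shallower at node 4, `11011` at
#' least 70 shallower at node 5 than `11111` — and the core threshold
#' (-40 ADC change).
#'
#' @param core_threshold core-line threshold (<= 0).
#' @param margin_11101_node5,margin_11110_node4,margin_11011_node5 depth
#'   margins (ADC counts, > 0).
#' @param smooth_frames temporal smoothing window used by [node_profile()].
#' @return Object of class `decoder_rules`.
#' @export
decoder_rules <- function(core_threshold = -40, margin_11101_node5 = 107,
                          margin_11110_node4 = 50, margin_11011_node5 = 70,
                          smooth_frames = 5L) {
  if (core_threshold > 0) stop("core_threshold must be <= 0", call. = FALSE)
  if (margin_11101_node5 <= 0 || margin_11110_node4 <= 0 ||
      margin_11011_node5 <= 0) {
    stop("depth margins must be > 0", call. = FALSE)
  }
  structure(list(
    peak_node = list(thumb = 9L, index = 8L, middle = 6L, ring = 5L,
                     little = c(3L, 4L)),
    core_threshold = core_threshold,
    margin_11101_node5 = margin_11101_node5,
    margin_11110_node4 = margin_11110_node4,
    margin_11011_node5 = margin_11011_node5,
    smooth_frames = as.integer(smooth_frames)),
    class = "decoder_rules")
}

#' Classify a single-finger gesture by its peak node
#'
#' The node position of the maximum negative peak decides the finger: the
#' candidate depth of each finger is the map's profile value at its peak
#' node, and the deepest candidate at or below the core threshold wins.
#' Because the little finger tends to co-fold with the ring finger, it is
#' only accepted when *both* of its peak nodes (3 and 4) are below
#' threshold, its candidate depth being the shallower of the two. Maps with
#' no sub-threshold cell classify as `"none"`.
#'
#' @param map a `deformation_map` of one gesture epoch (original node axis).
#' @param rules a [decoder_rules()].
#' @return One of `"thumb"`, `"index"`, `"middle"`, `"ring"`, `"little"`,
#'   `"none"`.
#' @export
classify_single_finger <- function(map, rules = decoder_rules()) {
  stopifnot(inherits(map, "deformation_map"))
  if (isTRUE(attr(map, "interpolated"))) {
    stop("classify on the original node axis, not an interpolated map",
         call. = FALSE)
  }
  prof <- node_profile(map, rules$smooth_frames)
  thr <- rules$core_threshold
  depth <- c(
    thumb  = prof[rules$peak_node$thumb],
    index  = prof[rules$peak_node$index],
    middle = prof[rules$peak_node$middle],
    ring   = prof[rules$peak_node$ring],
    little = max(prof[rules$peak_node$little])
  )
  eligible <- depth <= thr
  if (!any(eligible)) return("none")
  names(which.min(ifelse(eligible, depth, Inf)))
}

#' Decode a finger binary from a deformation map
#'
#' Template-matching decoder honouring the core-line position + depth
#' rules. Each of the 32 candidate codes is rendered as its composite
#' noiseless profile (linear sum of folded-finger templates,
#' interference-adjusted for unnatural codes and the closed fist, see
#' [gesture_profile()]); the candidate minimizing the L2 distance to the
#' map's node profile over the core cells (nodes where either profile is at
#' or below the core threshold) wins. A map with no core cell decodes as
#' `00000`. Distance ties break toward fewer folded fingers. When the best
#' candidate lies in the `{11110, 11101, 11011, 11111}` quartet — whose
#' core lines share nodes 4, 5 and 8 — the node-4/node-5 depth margins are
#' applied against the closed-fist reference profile to settle the code.
#'
#' Confidence is a diagnostic score, `1 - best/second-best distance`,
#' clipped to `[0, 1]` (not part of the device's published decision rule).
#'
#' @inheritParams classify_single_finger
#' @param templates a [finger_templates()] set (all five fingers).
#' @param ... passed to [gesture_profile()] (interference model knobs).
#' @return List of class `gesture_decision`: `binary`, `confidence`,
#'   `evidence` (core lines, candidate distances, margin-rule trail).
#' @export
decode_binary <- function(map, templates = finger_templates(),
                          rules = decoder_rules(), ...) {
  stopifnot(inherits(map, "deformation_map"))
  prof <- node_profile(map, rules$smooth_frames)
  if (any(is.na(prof))) stop("degenerate map: NA profile", call. = FALSE)
  thr <- rules$core_threshold
  codes <- gesture_codes()
  n_folded <- vapply(strsplit(codes, ""), function(b) sum(b == "1"),
                     numeric(1))
  cand <- vapply(codes, function(code) {
    gesture_profile(code, templates, ...)
  }, numeric(length(prof)))
  dist <- vapply(codes, function(code) {
    p <- cand[, code]
    cells <- (prof <= thr) | (p <= thr)
    if (!any(cells)) return(0)
    sqrt(sum((prof[cells] - p[cells])^2))
  }, numeric(1))
  # ties toward fewer folded fingers (order() is stable)
  ord <- order(dist, n_folded)
  best <- codes[ord[1]]
  trail <- character(0)

  quartet <- c("11110", "11101", "11011", "11111")
  if (best %in% quartet) {
    fist <- gesture_profile("11111", templates, ...)
    d4 <- prof[4] - fist[4]
    d5 <- prof[5] - fist[5]
    margin_best <-
      if (d5 <= -rules$margin_11101_node5) "11101"
      else if (d5 >= rules$margin_11011_node5) "11011"
      else if (d4 >= rules$margin_11110_node4) "11110"
      else "11111"
    trail <- sprintf(
      "quartet margins vs fist: node5 %+0.1f, node4 %+0.1f -> %s",
      d5, d4, margin_best)
    best <- margin_best
  }
  second <- dist[ord[2]]
  confidence <- if (second > 0) {
    min(max(1 - dist[[ord[1]]] / second, 0), 1)
  } else 1
  structure(list(
    binary = best, confidence = confidence,
    evidence = list(core_lines = extract_core_lines(map, thr),
                    distances = sort(dist)[1:5], rule_trail = trail)),
    class = "gesture_decision")
}

#' @export
print.gesture_decision <- function(x, ...) {
  cat(sprintf("<gesture_decision> binary %s (confidence %.2f)\n",
              x$binary, x$confidence))
  invisible(x)
}

#' Zoom action from a gesture count
#'
#' The paired user interface enlarges the image on an odd number of
#' motions and reduces it on an even number.
#'
#' @param gesture_count positive integer count of motions.
#' @return `"zoom_in"` for odd counts, `"zoom_out"` for even.
#' @examples
#' zoom_action(1)  # zoom_in
#' zoom_action(2)  # zoom_out
#' @export
zoom_action <- function(gesture_count) {
  gesture_count <- as.integer(gesture_count)
  if (any(gesture_count < 1L)) {
    stop("gesture_count must be a positive integer", call. = FALSE)
  }
  ifelse(gesture_count %% 2L == 1L, "zoom_in", "zoom_out")
}
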