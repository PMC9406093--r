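#' Vector-quantize a deformation map
#'
#' Reduces the value palette of a map to `k` centroid levels by 1-D K-means
#' on the cell values (color quantization of the rendered map is equivalent
#' for a monotone colormap). Quantization with `k = 6` for two-finger folds
#' and `k = 5` for three-finger folds makes the core lines visually and
#' algorithmically separable. Initial centroids are deterministic quantiles
#' of the sorted values, so results are reproducible without restarts; a
#' seed is recorded for provenance only.
#'
#' @param map a `deformation_map`.
#' @param k number of clusters (>= 2 and at most the number of distinct cell
#'   values).
#' @param seed integer recorded in the result (the quantile initialization
#'   is already deterministic).
#' @param centroids optional fixed centroid vector; when supplied, cells are
#'   simply assigned to the nearest centroid (no re-fitting), which makes
#'   quantization idempotent.
#' @return Object of class `quantized_map`: `labels` (grid of cluster ids
#'   `1..k`), `centroids` (ascending), `k`, `seed`, and the map axes.
#' @export
quantize_map <- function(map, k, seed = 0L, centroids = NULL) {
  stopifnot(inherits(map, "deformation_map"))
  v <- map_values(map)
  vals <- as.numeric(v)
  if (!is.null(centroids)) {
    cen <- sort(as.numeric(centroids))
    lab <- apply(outer(vals, cen, function(a, b) abs(a - b)), 1, which.min)
  } else {
    k <- as.integer(k)
    if (k < 2L) stop("k must be >= 2", call. = FALSE)
    nu <- length(unique(vals))
    if (k > nu) {
      stop(sprintf("k = %d exceeds the %d distinct cell values", k, nu),
           call. = FALSE)
    }
    init <- unname(stats::quantile(unique(vals),
                                   probs = (seq_len(k) - 0.5) / k,
                                   type = 7))
    # quantiles of distinct values can still coincide; nudge apart
    init <- sort(init)
    while (any(duplicated(init))) {
      init[duplicated(init)] <- init[duplicated(init)] +
        diff(range(vals)) * 1e-9
      init <- sort(init)
    }
    km <- stats::kmeans(vals, centers = matrix(init, ncol = 1),
                        algorithm = "Lloyd", iter.max = 200L)
    ord <- order(km$centers[, 1])
    cen <- km$centers[ord, 1]
    lab <- match(km$cluster, ord)
  }
  structure(list(labels = matrix(lab, nrow = nrow(v)),
                 centroids = unname(cen), k = length(cen),
                 seed = as.integer(seed),
                 times = map_times(map), nodes = map_nodes(map)),
            class = "quantized_map")
}

#' @export
print.quantized_map <- function(x, ...) {
  cat(sprintf("<quantized_map> k = %d; centroids: %s\n", x$k,
              paste(sprintf("%.1f", x$centroids), collapse = ", ")))
  invisible(x)
}

# label connected components of a logical grid under 4-connectivity
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(lab)
  for (p in seq_len(nrow(idx))) {
    r0 <- idx[p, 1]; c0 <- idx[p, 2]
    if (lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1L && rr <= nrow(mask) && c2 >= 1L && c2 <= ncol(mask) &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nxt
          queue <- rbind(queue, c(rr, c2))
        }
      }
    }
  }
  lab
}

#' Extract core lines from a deformation map
#'
#' A core line is a contiguous region (4-connectivity over the node x time
#' grid) of cells at or below the core threshold (default -40 ADC change).
#' Its node positions and depth (most negative member cell) carry the
#' identity of the gesture. Lines are returned deepest first; equal-depth
#' ties break toward the lower node index.
#'
#' @param map a `deformation_map`.
#' @param threshold core threshold in ADC change; must be <= 0 (concavity is
#'   negative by convention).
#' @return List of class `core_line_set`; each element has `nodes` (sorted
#'   node positions touched by the line), `depth`, and `extent` (cell
#'   count). Empty for maps with no cell at or below the threshold.
#' @examples
#' tpl <- finger_templates()
#' m <- simulate_gesture("10000", tpl, noise_model(sigma = 0))
#' extract_core_lines(m)[[1]]$nodes  # thumb core line sits at node 9
#' @export
extract_core_lines <- function(map, threshold = -40) {
  stopifnot(inherits(map, "deformation_map"))
  if (length(threshold) != 1L || is.na(threshold) || threshold > 0) {
    stop("core threshold must be a single number <= 0 (−Inf allowed)",
         call. = FALSE)
  }
  v <- map_values(map)
  nodes <- map_nodes(map)
  # threshold -Inf means "no cut": the whole grid is one line
  mask <- if (is.infinite(threshold)) {
    matrix(TRUE, nrow(v), ncol(v))
  } else {
    v <= threshold
  }
  lab <- label_components(mask)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  lines <- lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    list(nodes = sort(unique(nodes[cells[, 2]])),
         depth = min(v[lab == id]),
         extent = nrow(cells))
  })
  ord <- order(vapply(lines, `[[`, numeric(1), "depth"),
               vapply(lines, function(l) min(l$nodes), numeric(1)))
  structure(lines[ord], class = "core_line_set", threshold = threshold)
}

#' @export
print.core_line_set <- function(x, ...) {
  cat(sprintf("<core_line_set> %d line(s) at threshold %g\n", length(x),
              attr(x, "threshold")))
  for (l in x) {
    cat(sprintf("  nodes {%s}  depth %.1f  extent %d\n",
                paste(l$nodes, collapse = ","), l$depth, l$extent))
  }
  invisible(x)
}
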