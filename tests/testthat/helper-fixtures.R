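# shared fixtures, built in code

# published single-finger confusion counts (prediction rows thumb..little,
# none; actual columns thumb..little); 750 trials, 150 per finger
reference_confusion <- function() {
  as_confusion(rbind(
    c(146,   2,   0,   0,   0),
    c(  4, 139,   0,   0,   0),
    c(  0,   0, 143,   2,   0),
    c(  0,   0,   6, 140,   0),
    c(  0,   0,   0,   0, 145),
    c(  0,   9,   1,   8,   5)
  ))
}

# circle of radius r sampled at n points over the full turn, rotated by phi
# and translated by (cx, cy)
circle_curve <- function(r, n = 20001L, phi = 0, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n)
  parametric_curve(th, cx + r * cos(th + phi), cy + r * sin(th + phi))
}

# constant-resistance trace: n frames of identical node values
flat_trace <- function(value, n_frames = 90L, n_nodes = 6L) {
  cfg <- patch_config(node_count = n_nodes)
  adc_trace((seq_len(n_frames) - 1L) / cfg$sampling_hz,
            matrix(value, n_frames, n_nodes), cfg)
}

quartet_codes <- function() c("11110", "11101", "11011", "11111")

# deformation maps built directly from values (vector filled column-wise,
# or a ready frames x nodes matrix)
new_map_for_test <- function(values, nrow = 10L) {
  m <- matrix(values, nrow = nrow)
  new_deformation_map_for_test(m)
}

new_deformation_map_for_test <- function(m) {
  patchkit:::new_deformation_map(m, times = seq_len(nrow(m)) / 30,
                                 nodes = seq_len(ncol(m)))
}
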