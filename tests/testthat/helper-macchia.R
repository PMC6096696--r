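# shared fixtures for the suite

cal_default <- display_calibration()

# a small uniform point cloud that renders quickly
small_layout <- function(n = 60, width = 80, height = 40, seed = 101) {
  withr::with_seed(seed, {
    pts <- sample_points(n, width, height)
    voronoi_layout(pts, width, height)
  })
}

# noise-free observers with known idiosyncrasies injected on top of a latent
injected_panel <- function(offsets, gains, noise_sd = 0) {
  tibble::tibble(
    observer_id = sprintf("obs%02d", seq_along(offsets)),
    offset = offsets, gain = gains, noise_sd = noise_sd, step = 0
  )
}

# colour matrix with the package's column naming
as_rgb_matrix_test <- function(m) {
  colnames(m) <- c("r", "g", "b")
  m
}
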