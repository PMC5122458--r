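# Shared fixture builders. All fixtures are generated in code; geometries are
# scaled down from the device defaults so the full suite stays fast.

# quasi-1D device: channels span the full slab height, so the steady state
# equals the analytic two-layer profile exactly
geom_1d <- function(dy = 10) {
  device_geometry(chamber_width = 400, gas_width = 200, gas_gap = 200,
                  margin = 100, slab_height = 115, channel_thickness = 115,
                  dy = dy, dz = 23)
}

# small true-2D device (PDMS above the channels)
geom_2d <- function(dy = 20, dz = 23) {
  device_geometry(chamber_width = 400, gas_width = 200, gas_gap = 200,
                  margin = 100, slab_height = 230, channel_thickness = 115,
                  dy = dy, dz = dz)
}

protocol_lr <- function(left = "air", right = "nitrogen") {
  gas_protocol(data.frame(t_start = 0, left = left, right = right))
}

# constant-in-time uniform concentration profile (no gradient)
uniform_profile <- function(value = 10, ny = 41, half = 500, t_end = 1e4) {
  y <- seq(-half, half, length.out = ny)
  as_chamber_profile(y, c(0, t_end), matrix(value, ny, 2))
}

# constant-in-time exponential profile: constant relative gradient k (1/um)
expgrad_profile <- function(k = 0.002, c0 = 5, ny = 101, half = 500,
                            t_end = 1e4) {
  y <- seq(-half, half, length.out = ny)
  cexp <- c0 * exp(k * y)
  as_chamber_profile(y, c(0, t_end), cbind(cexp, cexp))
}

# straight-line track table
straight_track <- function(id = 1L, n = 20L, x0 = 0, y0 = 0, vx = 0, vy = 0,
                           dt = 0.1) {
  data.frame(track_id = id, frame = seq_len(n),
             x_um = x0 + vx * dt * (seq_len(n) - 1L),
             y_um = y0 + vy * dt * (seq_len(n) - 1L))
}

# image stack with Gaussian blobs planted at given positions
blob_stack <- function(pos, dims = c(48L, 48L), nframes = NULL, amp = 1,
                       sigma = 2, noise_sd = 0, fps = 10, px_um = 1,
                       seed = 99) {
  # pos: data.frame(frame, x, y) in pixels
  if (is.null(nframes)) nframes <- max(pos$frame, 1L)
  set.seed(seed)
  arr <- array(stats::rnorm(dims[1] * dims[2] * nframes, sd = noise_sd),
               c(dims, nframes))
  if (nrow(pos)) {
    xs <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    ys <- matrix(seq_len(dims[1]), dims[1], dims[2])
    for (i in seq_len(nrow(pos))) {
      f <- pos$frame[i]
      arr[, , f] <- arr[, , f] +
        amp * exp(-((xs - pos$x[i])^2 + (ys - pos$y[i])^2) / (2 * sigma^2))
    }
  }
  image_stack(arr, fps = fps, px_um = px_um)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
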