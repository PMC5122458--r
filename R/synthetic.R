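#' Canned gas protocols and solved oxygen fields
#'
#' Builds the gas schedules used throughout the experiments and solves the
#' device diffusion problem for them:
#' \describe{
#'   \item{flip}{air/nitrogen, swapped at half time: the lateral gradient
#'     reverses sign at the swap.}
#'   \item{air_air}{air in both channels: gradients decay to zero.}
#'   \item{n2_n2}{nitrogen in both channels from a saturated start: a
#'     residual mid-chamber oxygen maximum that decays in time.}
#'   \item{fig3_protocol}{a full cycling schedule (gradient, swap,
#'     uniform-air, nitrogen-only, gradient) exercising every regime.}
#' }
#'
#' @param name scenario name.
#' @param t_end duration (s); default 3600.
#' @param geometry a \code{device_geometry}; default
#'   \code{device_geometry()}.
#' @param dt,output_every solver stepping (s).
#' @param c_init initial uniform concentration (\%), default 20.
#' @param z_eval chamber evaluation height (um).
#' @return list with \code{protocol}, \code{field} (an
#'   \code{oxygen_field}) and \code{profile} (a \code{chamber_profile}).
#' @export
make_field_scenario <- function(name = c("flip", "air_air", "n2_n2",
                                         "fig3_protocol"),
                                t_end = 3600, geometry = device_geometry(),
                                dt = 5, output_every = 30, c_init = 20,
                                z_eval = 100) {
  name <- match.arg(name)
  seg <- switch(name,
    flip = data.frame(t_start = c(0, t_end / 2),
                      left = c("air", "nitrogen"),
                      right = c("nitrogen", "air")),
    air_air = data.frame(t_start = 0, left = "air", right = "air"),
    n2_n2 = data.frame(t_start = 0, left = "nitrogen", right = "nitrogen"),
    fig3_protocol = data.frame(
      t_start = round(t_end * c(0, 0.25, 0.45, 0.75)),
      left = c("air", "nitrogen", "air", "nitrogen"),
      right = c("nitrogen", "air", "air", "nitrogen"))
  )
  protocol <- gas_protocol(seg)
  dmap <- diffusivity_map(geometry)
  field <- solve_diffusion(geometry, dmap, protocol, t_end = t_end, dt = dt,
                           output_every = output_every, c_init = c_init)
  list(name = name, protocol = protocol, field = field,
       profile = chamber_profile(field, z_eval = z_eval))
}

#' Scenario configuration for the trajectory generator
#'
#' @param profile a \code{chamber_profile} (oxygen input for the swimmers).
#' @param strategy a \code{strategy_params} (uses \code{dr} and \code{v};
#'   the local bias is derived from the response model, see
#'   \code{\link{generate_tracks}}).
#' @param response a \code{response_model}.
#' @param n_colonies number of trajectories (default 150).
#' @param duration duration (s); default the profile's time span.
#' @param fps output frame rate (default 10).
#' @param jitter_um Gaussian position jitter (um, sd; default 0.5).
#' @param dropout per-frame detection dropout probability in [0, 1);
#'   default 0.05.
#' @param seed mandatory RNG seed.
#' @param dt_sim SDE integration step (s), default 5e-3.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(profile, strategy = strategy_params(),
                            response = response_model(),
                            n_colonies = 150, duration = NULL, fps = 10,
                            jitter_um = 0.5, dropout = 0.05, seed,
                            dt_sim = 5e-3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(profile, "chamber_profile"),
            inherits(strategy, "strategy_params"),
            inherits(response, "response_model"),
            dropout >= 0, dropout < 1, n_colonies >= 1)
  if (is.null(duration)) duration <- max(profile$t)
  structure(list(profile = profile, strategy = strategy, response = response,
                 n_colonies = n_colonies, duration = duration, fps = fps,
                 jitter_um = jitter_um, dropout = dropout, seed = seed,
                 dt_sim = dt_sim), class = "scenario_config")
}

#' Generate biased swimmer trajectories coupled to an oxygen field
#'
#' Integrates planar positions \eqn{dx = v(\cos\theta, \sin\theta)dt} with
#' the stochastic (rotational-diffusion modulation) heading dynamics, where
#' the local bias is obtained by inverting the stationary drift relation:
#' \eqn{\epsilon(y,t) = 2 v \tilde v / (v^2 + \tilde v^2)} with
#' \eqn{\tilde v = |V[c]|(y,t)} from the response model, signed by the
#' gradient direction. Walls reflect positions and headings specularly.
#' Position jitter and detection dropout emulate tracking noise.
#'
#' @param scenario a \code{scenario_config}.
#' @return list with \code{tracks} (a \code{track_set}) and \code{truth}
#'   (list: noise-free \code{x}, \code{y}, \code{theta} matrices
#'   \code{n x frames}, frame times \code{t}, the bias grid, and the seed).
#' @export
generate_tracks <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  prof <- scenario$profile
  if (scenario$duration > max(prof$t) + 1e-9) {
    stop("oxygen profile does not cover the scenario duration")
  }
  sp <- scenario$strategy
  v <- sp$v
  vt <- abs(response_velocity_matrix(scenario$response, prof))
  eps_loc <- 2 * v * vt / (v^2 + vt^2)
  bias <- eps_loc * sign(prof$dc_dy)
  y0y1 <- prof$chamber_y
  set.seed(scenario$seed)
  n <- scenario$n_colonies
  x0 <- stats::runif(n, y0y1[1], y0y1[2])
  y0 <- stats::runif(n, y0y1[1], y0y1[2])
  th0 <- stats::runif(n, -pi, pi)
  dt <- scenario$dt_sim
  frame_dt <- 1 / scenario$fps
  save_every <- max(1L, round(frame_dt / dt))
  dt <- frame_dt / save_every          # keep frames commensurate
  nsteps <- round(scenario$duration / frame_dt) * save_every
  sim <- generate_tracks_cpp(x0, y0, th0, v, sp$dr, dt, nsteps,
                             as.integer(save_every), bias, prof$y, prof$t,
                             y0y1[1], y0y1[2], y0y1[1], y0y1[2])
  nf <- ncol(sim$x)
  tframe <- (seq_len(nf) - 1L) * frame_dt
  xj <- sim$x + matrix(stats::rnorm(n * nf, sd = scenario$jitter_um), n, nf)
  yj <- sim$y + matrix(stats::rnorm(n * nf, sd = scenario$jitter_um), n, nf)
  seen <- matrix(stats::runif(n * nf) >= scenario$dropout, n, nf)
  df <- data.frame(track_id = rep(seq_len(n), nf),
                   frame = rep(seq_len(nf), each = n),
                   x_um = as.numeric(xj), y_um = as.numeric(yj))[as.vector(seen), ]
  gd <- data.frame(t = prof$t,
                   dir = sign(prof$dc_dy[which.min(abs(prof$y)), ]))
  ts <- track_set(df, frame_interval = frame_dt, chamber_y = y0y1,
                  gradient_dir = gd, tol = 6 * scenario$jitter_um + 1)
  list(tracks = ts,
       truth = list(x = sim$x, y = sim$y, theta = sim$theta, t = tframe,
                    bias = bias, y_grid = prof$y, t_grid = prof$t,
                    seed = scenario$seed))
}

# drift field V (ny x nt) on a chamber profile
response_velocity_matrix <- function(model, prof) {
  vapply(seq_along(prof$t),
         function(k) response_velocity(model, prof$c[, k], prof$dc_dy[, k]),
         numeric(length(prof$y)))
}

#' Render a toy microscopy video from tracks
#'
#' Draws Gaussian blobs at track positions on a noisy constant background
#' with a known pixel size, and returns the ground truth alongside. The
#' signal-to-noise ratio is the blob peak amplitude over the background
#' noise standard deviation.
#'
#' @param ts a \code{track_set}.
#' @param px_um pixel size (um/px).
#' @param blob_sigma_px blob width (px), default 2.
#' @param snr peak-over-noise ratio; \code{Inf} for noise-free.
#' @param seed RNG seed.
#' @param pad_px border padding (px).
#' @return list with \code{stack} (an \code{image_stack}) and \code{truth}
#'   (data.frame \code{track_id, frame, x_px, y_px}).
#' @export
render_video <- function(ts, px_um = 2, blob_sigma_px = 2, snr = 5, seed = 1,
                         pad_px = 10) {
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  set.seed(seed)
  amp <- 1
  noise_sd <- if (is.finite(snr)) amp / snr else 0
  if (nrow(tr)) {
    x_px <- tr$x_um / px_um - min(tr$x_um / px_um) + pad_px + 1
    y_px <- tr$y_um / px_um - min(tr$y_um / px_um) + pad_px + 1
    nc <- ceiling(max(x_px)) + pad_px
    nr <- ceiling(max(y_px)) + pad_px
    frames <- seq(min(tr$frame), max(tr$frame))   # gaps render as empty frames
  } else {
    x_px <- y_px <- numeric(0)
    nc <- nr <- 2 * pad_px
    frames <- 1:3
  }
  nf <- length(frames)
  if (as.double(nr) * nc * nf > 2.5e8) {
    stop("requested stack exceeds 2.5e8 pixels (", nr, " x ", nc, " x ", nf,
         "); increase px_um or render fewer/shorter tracks")
  }
  arr <- array(stats::rnorm(nr * nc * nf, mean = 0, sd = noise_sd),
               c(nr, nc, nf))
  r <- ceiling(4 * blob_sigma_px)
  truth <- data.frame(track_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0))
  if (nrow(tr)) {
    for (k in seq_len(nf)) {
      sel <- which(tr$frame == frames[k])
      if (!length(sel)) next
      for (i in sel) {
        cx <- x_px[i]; cy <- y_px[i]
        c0 <- max(1L, floor(cx) - r); c1 <- min(nc, floor(cx) + r + 1L)
        r0 <- max(1L, floor(cy) - r); r1 <- min(nr, floor(cy) + r + 1L)
        gx <- exp(-((c0:c1) - cx)^2 / (2 * blob_sigma_px^2))
        gy <- exp(-((r0:r1) - cy)^2 / (2 * blob_sigma_px^2))
        arr[r0:r1, c0:c1, k] <- arr[r0:r1, c0:c1, k] + amp * outer(gy, gx)
      }
      truth <- rbind(truth, data.frame(track_id = tr$track_id[sel], frame = k,
                                       x_px = x_px[sel], y_px = y_px[sel]))
    }
  }
  list(stack = image_stack(arr, fps = 1 / ts$frame_interval, px_um = px_um),
       truth = truth)
}
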