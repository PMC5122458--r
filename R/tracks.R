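#' Track set container
#'
#' Frame-indexed 2D trajectories at a fixed frame rate. Spurious tracks
#' shorter than \code{min_length} detections are removed on construction.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{frame},
#'   \code{x_um}, \code{y_um}; frames must be strictly increasing within a
#'   track (gaps allowed).
#' @param frame_interval seconds between frames (default 0.1, i.e. 10 fps).
#' @param chamber_y chamber extent \code{c(y0, y1)} (um); positions may
#'   exceed it by at most \code{tol}.
#' @param gradient_dir data.frame with columns \code{t} and \code{dir}
#'   (+1 gradient up, -1 down, 0 none), or NULL. Piecewise-constant in time
#'   from each \code{t} onward.
#' @param min_length minimum detections per track (default 3).
#' @param tol out-of-chamber tolerance (um).
#' @return object of class \code{track_set}.
#' @export
track_set <- function(tracks, frame_interval = 0.1, chamber_y = NULL,
                      gradient_dir = NULL, min_length = 3L, tol = 1) {
  tracks <- as.data.frame(tracks)
  need <- c("track_id", "frame", "x_um", "y_um")
  stopifnot(all(need %in% names(tracks)), frame_interval > 0)
  tracks <- tracks[order(tracks$track_id, tracks$frame), need]
  byid <- split(tracks$frame, tracks$track_id)
  if (any(vapply(byid, function(f) is.unsorted(f, strictly = TRUE), logical(1)))) {
    stop("frames must be strictly increasing within a track")
  }
  keep_ids <- names(byid)[lengths(byid) >= min_length]
  tracks <- tracks[tracks$track_id %in% keep_ids, ]
  if (is.null(chamber_y)) {
    chamber_y <- if (nrow(tracks)) range(tracks$y_um) else c(0, 0)
  } else if (nrow(tracks) &&
             (min(tracks$y_um) < chamber_y[1] - tol ||
              max(tracks$y_um) > chamber_y[2] + tol)) {
    stop("positions outside chamber bounds")
  }
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 chamber_y = chamber_y, gradient_dir = gradient_dir),
            class = "track_set")
}

#' Read / write tracks in the delimited exchange format
#' @param path CSV with header \code{track_id, frame, x_um, y_um}.
#' @param ... passed to \code{\link{track_set}}.
#' @return a \code{track_set}.
#' @export
read_tracks <- function(path, ...) track_set(utils::read.csv(path), ...)

#' @rdname read_tracks
#' @param ts a \code{track_set}.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  utils::write.csv(ts$tracks, path, row.names = FALSE)
  invisible(path)
}

gradient_dir_at <- function(ts, t) {
  gd <- ts$gradient_dir
  # no protocol supplied: treat the gradient as pointing up throughout
  if (is.null(gd)) return(rep(1, length(t)))
  i <- findInterval(t, gd$t)
  out <- rep(0, length(t))
  out[i >= 1] <- gd$dir[i[i >= 1]]
  out
}

#' Boundary-corrected kernel density profile
#'
#' Gaussian kernel density of positions on a bounded domain:
#' \deqn{\eta(y) = \sum_i \exp(-(y_i - y)^2/2\sigma^2) \Big/
#'   \int_{y_0}^{y_1} \exp(-(y' - y)^2/2\sigma^2)\, dy'}
#' where the denominator (evaluated in closed form via the Gaussian CDF)
#' compensates for kernel mass lost outside the walls, so points at a wall
#' are not under-weighted. The result is normalized to a probability
#' density: \eqn{\rho = \eta / \int \eta}.
#'
#' @param positions y positions (um), all within \code{domain}.
#' @param sigma kernel standard deviation (um), > 0. Default 25.
#' @param domain \code{c(y0, y1)} chamber extent (um).
#' @param grid evaluation grid; default 256 equispaced points spanning the
#'   domain.
#' @return list with \code{y} (grid) and \code{rho} (1/um), integrating to 1.
#' @export
density_profile <- function(positions, sigma = 25, domain, grid = NULL) {
  if (length(positions) == 0) stop("no positions supplied")
  stopifnot(sigma > 0, length(domain) == 2, domain[2] > domain[1])
  if (any(positions < domain[1] - 1e-9 | positions > domain[2] + 1e-9)) {
    stop("positions outside the domain")
  }
  if (is.null(grid)) grid <- seq(domain[1], domain[2], length.out = 256L)
  num <- vapply(grid, function(g) sum(exp(-(positions - g)^2 / (2 * sigma^2))),
                numeric(1))
  den <- sqrt(2 * pi) * sigma *
    (stats::pnorm((domain[2] - grid) / sigma) -
     stats::pnorm((domain[1] - grid) / sigma))
  eta <- num / den
  list(y = grid, rho = eta / trapz(grid, eta))
}

#' Running ensemble velocity statistics
#'
#' Central-difference velocities per track (one-frame stencil; frames
#' adjacent to gaps are skipped), ensemble-averaged per frame, optionally
#' smoothed by a centered moving average. When swap windows are supplied,
#' also returns per-colony alignment samples \eqn{\hat c\, v_y / v} with
#' the speed, restricted to those windows.
#'
#' @param ts a \code{track_set}.
#' @param smooth_window smoothing window (s); 0 disables smoothing.
#' @param swap_windows optional data.frame \code{t0, t1} of time intervals
#'   (after gas swaps) in which alignment statistics are valid.
#' @return list with \code{series} (data.frame \code{t, v, vx, vy, n}) and
#'   \code{alignment} (data.frame \code{t, align, speed} or NULL).
#' @export
velocity_series <- function(ts, smooth_window = 30, swap_windows = NULL) {
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  dtf <- ts$frame_interval
  per <- lapply(split(tr, tr$track_id), function(d) {
    n <- nrow(d)
    if (n < 3) return(NULL)     # shorter than the difference stencil
    ok <- which(d$frame[-c(1, 2)] - d$frame[-c(n - 1, n)] == 2L) + 1L
    if (!length(ok)) return(NULL)
    data.frame(frame = d$frame[ok],
               vx = (d$x_um[ok + 1L] - d$x_um[ok - 1L]) / (2 * dtf),
               vy = (d$y_um[ok + 1L] - d$y_um[ok - 1L]) / (2 * dtf))
  })
  vel <- do.call(rbind, per)
  if (is.null(vel) || !nrow(vel)) stop("no track long enough for velocities")
  vel$speed <- sqrt(vel$vx^2 + vel$vy^2)
  frames <- sort(unique(vel$frame))
  agg <- function(v) vapply(split(v, vel$frame), mean, numeric(1))
  series <- data.frame(t = frames * dtf,
                       v = agg(vel$speed), vx = agg(vel$vx), vy = agg(vel$vy),
                       n = as.integer(table(vel$frame)))
  k <- max(1L, round(smooth_window / dtf))
  if (k > 1L) for (col in c("v", "vx", "vy")) {
    series[[col]] <- moving_average(series[[col]], k)
  }
  alignment <- NULL
  if (!is.null(swap_windows)) {
    tvel <- vel$frame * dtf
    inwin <- Reduce(`|`, lapply(seq_len(nrow(swap_windows)), function(i) {
      tvel >= swap_windows$t0[i] & tvel <= swap_windows$t1[i]
    }))
    cdir <- gradient_dir_at(ts, tvel)
    sel <- inwin & cdir != 0 & vel$speed > 0
    alignment <- data.frame(t = tvel[sel],
                            align = cdir[sel] * vel$vy[sel] / vel$speed[sel],
                            speed = vel$speed[sel])
  }
  list(series = series, alignment = alignment)
}

#' Pooled heading and turn-angle samples from tracks
#'
#' Headings are taken from one-frame displacement directions,
#' \eqn{\theta = atan2(\Delta y, \Delta x)}; when the gradient points down
#' (\eqn{\hat c = -1}) the folding \eqn{\theta \to -\theta} is applied so
#' \eqn{\pi/2} always denotes up-gradient. Turn angles over a lag
#' \eqn{\Delta t} are \eqn{\Delta\phi = |\theta(t) - \pi/2| -
#' |\theta(t+\Delta t) - \pi/2|}: positive when the turn is toward the
#' gradient (the heading gets closer to \eqn{\pi/2}), which is the sign
#' convention under which the deterministic-steering turn-angle density has
#' positive mean.
#'
#' @param ts a \code{track_set}.
#' @param dt_lag lag \eqn{\Delta t} (s); must be an integer multiple of the
#'   frame interval. Default 0.65.
#' @param windows optional data.frame \code{t0, t1}; only samples within
#'   the windows (and with a nonzero gradient flag, when present) are
#'   pooled.
#' @param y_band optional \code{c(ymin, ymax)}: only samples from positions
#'   inside the band are pooled (used to exclude wall-contaminated
#'   statistics, where reflections symmetrize headings).
#' @return list with vectors \code{theta} and \code{dphi}.
#' @export
angle_samples <- function(ts, dt_lag = 0.65, windows = NULL, y_band = NULL) {
  stopifnot(inherits(ts, "track_set"))
  dtf <- ts$frame_interval
  lag <- dt_lag / dtf
  if (abs(lag - round(lag)) > 1e-6) {
    stop("dt_lag must be an integer multiple of the frame interval")
  }
  lag <- as.integer(round(lag))
  theta_all <- numeric(0)
  dphi_all <- numeric(0)
  for (d in split(ts$tracks, ts$tracks$track_id)) {
    n <- nrow(d)
    if (n < 2) next
    contig <- which(diff(d$frame) == 1L)
    th <- rep(NA_real_, n)
    th[contig] <- atan2(d$y_um[contig + 1L] - d$y_um[contig],
                        d$x_um[contig + 1L] - d$x_um[contig])
    tt <- d$frame * dtf
    cdir <- gradient_dir_at(ts, tt)
    th[cdir == -1] <- -th[cdir == -1]
    keep <- !is.na(th) & cdir != 0
    if (!is.null(y_band)) {
      keep <- keep & d$y_um >= y_band[1] & d$y_um <= y_band[2]
    }
    if (!is.null(windows)) {
      inwin <- Reduce(`|`, lapply(seq_len(nrow(windows)), function(i) {
        tt >= windows$t0[i] & tt <= windows$t1[i]
      }))
      keep <- keep & inwin
    }
    theta_all <- c(theta_all, th[keep])
    # pair samples lag frames apart (both ends valid, same gradient flag)
    if (n > lag) {
      i0 <- seq_len(n - lag)
      i1 <- i0 + lag
      ok <- keep[i0] & keep[i1] & (d$frame[i1] - d$frame[i0] == lag) &
        cdir[i0] == cdir[i1]
      # angular distance to the attractant direction, measured on the circle
      dist_up <- abs(wrap_angle(th - pi / 2))
      dphi <- (dist_up[i0] - dist_up[i1])[ok]
      dphi_all <- c(dphi_all, dphi)
    }
  }
  list(theta = theta_all, dphi = dphi_all)
}
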