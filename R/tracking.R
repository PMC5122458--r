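#' Grayscale image stack
#'
#' @param frames 3D array \code{[nrow, ncol, nframes]} (or list of equal
#'   size matrices) of intensities.
#' @param fps frame rate (frames per second), > 0. Default 10.
#' @param px_um pixel size (um per pixel).
#' @return object of class \code{image_stack}.
#' @export
image_stack <- function(frames, fps = 10, px_um = 1) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
      stop("all frames must share the same shape")
    }
    frames <- array(unlist(frames), c(d, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3, fps > 0, px_um > 0)
  structure(list(frames = frames, fps = fps, px_um = px_um),
            class = "image_stack")
}

#' Running-median background model
#'
#' Estimates a colony-free background video: each pixel of each frame is
#' the temporal median of that pixel over a centered window of about
#' \code{window} seconds (truncated at the stack ends). Moving objects that
#' occupy a pixel for less than half the window leave no trace.
#'
#' @param stack an \code{image_stack}.
#' @param window temporal window (s), default 2.5.
#' @return an \code{image_stack} of the background.
#' @export
background_model <- function(stack, window = 2.5) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$frames)[3]
  k <- round(window * stack$fps)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3) stop("window must span at least 3 frames")
  k <- min(k, if (nf %% 2 == 1) nf else nf - 1L)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  bg <- t(apply(flat, 1, function(v) stats::runmed(v, k, endrule = "keep")))
  # truncated (not shrunken) windows at the stack ends: median over the
  # available part of the full window, so brief transients still vanish
  h <- (k - 1L) %/% 2L
  for (f in c(seq_len(min(h, nf)), seq.int(max(1L, nf - h + 1L), nf))) {
    i0 <- max(1L, f - h); i1 <- min(nf, f + h)
    bg[, f] <- apply(flat[, i0:i1, drop = FALSE], 1, stats::median)
  }
  image_stack(array(bg, d), fps = stack$fps, px_um = stack$px_um)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(n, r), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(r + 1L):(r + n), ], n, ncol(m))
  }
  t(blur_cols(t(blur_cols(img))))
}

#' Detect colony positions in an image stack
#'
#' Background-subtracted frames are band-pass filtered (difference of
#' Gaussians: features near \code{lowpass} pixels are kept, structure
#' broader than \code{highpass} pixels removed), smoothed with a Gaussian
#' of width \code{sigma}, and candidate positions are strict local maxima
#' above \code{nsigma} robust (MAD) noise standard deviations, refined to
#' sub-pixel accuracy by an intensity-weighted centroid.
#'
#' @param stack an \code{image_stack}.
#' @param background background stack from \code{\link{background_model}}
#'   (or NULL to skip subtraction).
#' @param lowpass,highpass band-pass scales in pixels (defaults 2 and 20);
#'   \code{lowpass < highpass} or an error is raised.
#' @param sigma Gaussian detection scale in pixels (default 2). Blobs
#'   closer than about \code{sigma} may merge into a single detection.
#' @param nsigma detection threshold in robust noise SDs (default 3).
#' @return list (one element per frame) of data.frames \code{x, y}
#'   (pixel coordinates: x along columns, y along rows) and
#'   \code{intensity}.
#' @export
detect <- function(stack, background = NULL, lowpass = 2, highpass = 20,
                   sigma = 2, nsigma = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (lowpass >= highpass) stop("band-pass radii inverted: need lowpass < highpass")
  nf <- dim(stack$frames)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- stack$frames[, , f]
    if (!is.null(background)) img <- img - background$frames[, , f]
    bp <- gaussian_blur(img, lowpass) - gaussian_blur(img, highpass)
    sm <- gaussian_blur(bp, sigma)
    noise <- stats::mad(sm)
    thr <- nsigma * max(noise, 1e-12)
    nr <- nrow(sm); nc <- ncol(sm)
    core <- sm[2:(nr - 1), 2:(nc - 1)]
    ismax <- core > thr &
      core > sm[1:(nr - 2), 2:(nc - 1)] & core >= sm[3:nr, 2:(nc - 1)] &
      core > sm[2:(nr - 1), 1:(nc - 2)] & core >= sm[2:(nr - 1), 3:nc] &
      core > sm[1:(nr - 2), 1:(nc - 2)] & core >= sm[3:nr, 3:nc] &
      core > sm[3:nr, 1:(nc - 2)] & core >= sm[1:(nr - 2), 3:nc]
    pk <- which(ismax, arr.ind = TRUE)
    if (nrow(pk)) {
      rr <- pk[, 1] + 1L; cc <- pk[, 2] + 1L
      # parabolic fit to log intensity across the peak (exact for a
      # Gaussian blob); offset clamped to half a pixel
      paraboloid <- function(im1, i0, ip1) {
        if (im1 > 0 && i0 > 0 && ip1 > 0) {
          l1 <- log(im1); l2 <- log(i0); l3 <- log(ip1)
        } else {
          l1 <- im1; l2 <- i0; l3 <- ip1
        }
        den <- l1 - 2 * l2 + l3
        off <- if (abs(den) < 1e-12) 0 else 0.5 * (l1 - l3) / den
        max(-0.5, min(0.5, off))
      }
      ref <- vapply(seq_along(rr), function(i) {
        r <- rr[i]; cl <- cc[i]
        dy <- paraboloid(sm[r - 1L, cl], sm[r, cl], sm[r + 1L, cl])
        dx <- paraboloid(sm[r, cl - 1L], sm[r, cl], sm[r, cl + 1L])
        c(cl + dx, r + dy, sm[r, cl])
      }, numeric(3))
      out[[f]] <- data.frame(x = ref[1, ], y = ref[2, ], intensity = ref[3, ])
    } else {
      out[[f]] <- data.frame(x = numeric(0), y = numeric(0),
                             intensity = numeric(0))
    }
  }
  out
}

#' Link detections into trajectories by proximity
#'
#' Greedy nearest-neighbor linking: in each frame, candidate matches
#' between active tracks and detections within the displacement cap
#' (\code{max_disp} per elapsed frame) are assigned in order of increasing
#' distance (ties broken by lowest detection index). Tracks missing for up
#' to \code{memory} frames stay eligible (gaps are bridged by keeping a
#' running memory of the last position); unmatched detections start new
#' tracks; tracks with fewer than \code{min_length} detections are removed.
#'
#' @param detections per-frame list of data.frames \code{x, y} (any
#'   consistent length unit; see \code{px_um} to convert pixels to um).
#' @param max_disp maximum displacement per frame (same unit as x, y).
#' @param memory maximum bridgeable gap in frames (default 3).
#' @param min_length minimum detections per track (default 3).
#' @param frame_interval seconds per frame (default 0.1).
#' @param px_um scale applied to coordinates on output (um per unit).
#' @return a \code{track_set} (positions multiplied by \code{px_um}).
#' @export
link <- function(detections, max_disp, memory = 3L, min_length = 3L,
                 frame_interval = 0.1, px_um = 1) {
  stopifnot(max_disp > 0, memory >= 0)
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  rows <- list()
  next_id <- 1L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- nrow(det)
    active <- which(f - last_f <= memory + 1L)
    assigned_det <- integer(0)
    if (nd > 0 && length(active)) {
      dx <- outer(last_x[active], det$x, "-")
      dyy <- outer(last_y[active], det$y, "-")
      dist <- sqrt(dx^2 + dyy^2)
      cap <- max_disp * (f - last_f[active])
      cand <- which(dist <= cap, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(dist[cand], cand[, 2])
        used_tr <- logical(length(active)); used_dt <- logical(nd)
        for (ci in o) {
          tr <- cand[ci, 1]; dt <- cand[ci, 2]
          if (used_tr[tr] || used_dt[dt]) next
          used_tr[tr] <- TRUE; used_dt[dt] <- TRUE
          id <- active[tr]
          last_x[id] <- det$x[dt]; last_y[id] <- det$y[dt]; last_f[id] <- f
          rows[[length(rows) + 1L]] <- c(id, f, det$x[dt], det$y[dt])
        }
        assigned_det <- which(used_dt)
      }
    }
    if (nd > 0) {
      for (dt in setdiff(seq_len(nd), assigned_det)) {
        id <- next_id; next_id <- next_id + 1L
        last_x[id] <- det$x[dt]; last_y[id] <- det$y[dt]; last_f[id] <- f
        rows[[length(rows) + 1L]] <- c(id, f, det$x[dt], det$y[dt])
      }
    }
  }
  if (!length(rows)) {
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     frame_interval = frame_interval, min_length = 0L))
  }
  m <- do.call(rbind, rows)
  track_set(data.frame(track_id = m[, 1], frame = m[, 2],
                       x_um = m[, 3] * px_um, y_um = m[, 4] * px_um),
            frame_interval = frame_interval, min_length = min_length)
}

#' Full tracking pipeline on an image stack
#'
#' \code{\link{background_model}} + \code{\link{detect}} + \code{\link{link}}
#' with positions converted to um using the stack pixel size.
#'
#' @param stack an \code{image_stack}.
#' @param max_disp_um displacement cap in um per frame.
#' @param ... further arguments to \code{\link{detect}}.
#' @param window background window (s).
#' @param memory,min_length linking parameters.
#' @return a \code{track_set}.
#' @export
track_stack <- function(stack, max_disp_um, window = 2.5, memory = 3L,
                        min_length = 3L, ...) {
  bg <- background_model(stack, window = window)
  det <- detect(stack, bg, ...)
  link(det, max_disp = max_disp_um / stack$px_um, memory = memory,
       min_length = min_length, frame_interval = 1 / stack$fps,
       px_um = stack$px_um)
}
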