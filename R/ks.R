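#' Density profile container
#'
#' Per-frame-normalized colony density along the gradient axis. Each time
#' slice integrates to 1 (units 1/um).
#'
#' @param y grid centers (um).
#' @param t times (s).
#' @param rho matrix \code{ny x nt}, nonnegative; each column is normalized
#'   to unit integral on construction.
#' @return object of class \code{density_profile}.
#' @export
density_profile_obj <- function(y, t, rho) {
  stopifnot(is.matrix(rho), nrow(rho) == length(y), ncol(rho) == length(t))
  if (min(rho) < -1e-10) stop("negative densities")
  rho <- pmax(rho, 0)
  # cell-centered uniform grid: each cell carries weight dy
  w <- rep(mean(diff(y)), length(y))
  mass <- as.numeric(crossprod(rho, w))
  if (any(mass <= 0)) stop("empty density slice")
  structure(list(y = y, t = t, rho = sweep(rho, 2, mass, "/")),
            class = "density_profile")
}

#' Write / read a density profile as CSV (columns t, y, rho)
#' @param profile a \code{density_profile}.
#' @param path file path.
#' @return invisibly the data.frame written.
#' @export
write_density_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  df <- data.frame(t = rep(profile$t, each = length(profile$y)),
                   y = rep(profile$y, length(profile$t)),
                   rho = as.numeric(profile$rho))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_density_profile
#' @export
read_density_profile <- function(path) {
  df <- utils::read.csv(path)
  t <- sort(unique(df$t)); y <- sort(unique(df$y))
  o <- order(df$t, df$y)
  density_profile_obj(y, t, matrix(df$rho[o], length(y), length(t)))
}

# face velocities (ny+1) for a concentration frame: interpolate c and take
# one-sided differences across each interior face
face_velocities <- function(model, y, cvec) {
  ny <- length(y)
  dy <- y[2] - y[1]
  cf <- (cvec[-1] + cvec[-ny]) / 2
  dcf <- (cvec[-1] - cvec[-ny]) / dy
  c(0, response_velocity(model, cf, dcf), 0)
}

#' Solve the 1D Keller-Segel equation under a time-dependent oxygen profile
#'
#' Integrates \eqn{\partial\rho/\partial t = D\,\partial^2\rho/\partial y^2
#' - \partial(V[c]\rho)/\partial y} with no-flux walls (zero total flux, so
#' the population accumulates at chamber edges rather than leaking).
#' Discretisation: implicit backward Euler, first-order upwind advection
#' (positivity-preserving M-matrix), exact discrete mass conservation. The
#' drift field is derived from the supplied concentration frames via the
#' response model and interpolated linearly in time between frames.
#'
#' @param params a \code{ks_params} (uses \code{D}).
#' @param model a \code{response_model}.
#' @param c_field either a \code{chamber_profile} or a list with \code{y},
#'   \code{t}, and matrix \code{c} (\code{ny x nt}); must cover the full
#'   simulated interval.
#' @param t_end end time (s); defaults to the last field time.
#' @param dt time step (s).
#' @param output_every interval between stored slices (s).
#' @param rho0 initial density on the field's y grid (normalized
#'   internally); default uniform.
#' @param max_courant advisory cap on \code{dt * max|V| / dy}; although the
#'   implicit scheme is unconditionally stable, large advective Courant
#'   numbers degrade accuracy, so exceeding the cap is an error advising a
#'   smaller step.
#' @return a \code{density_profile}.
#' @export
solve_ks <- function(params, model, c_field, t_end = NULL, dt = 1,
                     output_every = 30, rho0 = NULL, max_courant = 20) {
  stopifnot(inherits(params, "ks_params"), inherits(model, "response_model"))
  y <- c_field$y
  tc <- c_field$t
  cm <- c_field$c
  stopifnot(is.matrix(cm), nrow(cm) == length(y), ncol(cm) == length(tc))
  if (is.null(t_end)) t_end <- max(tc)
  if (t_end > max(tc) + 1e-9) stop("c_field does not cover the simulated interval")
  ny <- length(y)
  dy <- y[2] - y[1]
  Vface <- vapply(seq_along(tc), function(k) face_velocities(model, y, cm[, k]),
                  numeric(ny + 1))
  courant <- dt * max(abs(Vface)) / dy
  if (courant > max_courant) {
    stop("advective Courant number ", signif(courant, 3),
         " too large; use a smaller dt")
  }
  if (is.null(rho0)) rho0 <- rep(1 / (ny * dy), ny)
  rho0 <- rho0 / (sum(rho0) * dy)
  nsteps <- round(t_end / dt)
  save_every <- max(1L, round(output_every / dt))
  out <- ks_solve_cpp(rho0, dy, dt, nsteps, params$D, Vface, tc,
                      as.integer(save_every))
  tout <- seq(0L, nsteps %/% save_every) * save_every * dt
  density_profile_obj(y, tout, out)
}

#' Fit Keller-Segel parameters to an observed density kymograph
#'
#' Bounded multi-start least squares over (D, alpha, vdrift) minimizing the
#' space-time sum of squared differences between the solver output and the
#' observed per-frame-normalized densities. The objective value is returned
#' so different response kinds (e.g. absolute vs logarithmic sensing) can be
#' compared on the same data.
#'
#' @param observed a \code{density_profile} (used on its own y grid; its
#'   first slice seeds the solver initial condition).
#' @param c_field concentration frames as in \code{\link{solve_ks}}, on the
#'   same y grid as \code{observed}.
#' @param kind response-model kind to fit.
#' @param n_starts number of multi-start initial points (default 8).
#' @param seed RNG seed for start dispersion.
#' @param dt,output_every solver resolution used during fitting;
#'   \code{output_every} should match the observed frame spacing.
#' @param lower,upper named bounds for \code{c(D, alpha, vdrift)}.
#' @param c_min concentration floor passed to the response model.
#' @return list with \code{par} (named \code{D}, \code{alpha},
#'   \code{vdrift}), \code{objective}, \code{kind}, and the per-start
#'   \code{trace}.
#' @export
fit_ks <- function(observed, c_field, kind = "tanh_log", n_starts = 8L,
                   seed = 1L, dt = 2, output_every = NULL,
                   lower = NULL, upper = NULL, c_min = 1e-3) {
  stopifnot(inherits(observed, "density_profile"))
  if (is.null(output_every)) {
    output_every <- if (length(observed$t) > 1) diff(observed$t[1:2]) else 30
  }
  if (is.null(lower)) {
    lower <- c(D = 50, alpha = if (kind == "tanh_log") 50 else 0.05,
               vdrift = 0.2)
  }
  if (is.null(upper)) {
    upper <- c(D = 6000, alpha = if (kind == "tanh_log") 2e4 else 500,
               vdrift = 16)
  }
  t_end <- max(observed$t)
  rho0 <- observed$rho[, 1]
  objective <- function(p) {
    sim <- solve_ks(ks_params(D = p[1]),
                    response_model(kind, vdrift = p[3], alpha = p[2],
                                   c_min = c_min),
                    c_field, t_end = t_end, dt = dt,
                    output_every = output_every, rho0 = rho0)
    k <- match(round(observed$t, 6), round(sim$t, 6))
    if (anyNA(k)) stop("observed times not commensurate with solver output")
    sum((sim$rho[, k] - observed$rho)^2)
  }
  set.seed(seed)
  # log-uniform dispersion of starts within the bounds
  starts <- t(vapply(seq_len(n_starts), function(i) {
    exp(stats::runif(3, log(lower), log(upper)))
  }, numeric(3)))
  starts[1, ] <- sqrt(lower * upper)        # deterministic central start
  trace <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 200,
                                           parscale = pmax(abs(starts[i, ]), 1))),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      trace[[i]] <- list(start = starts[i, ], error = as.character(fit))
      next
    }
    trace[[i]] <- list(start = starts[i, ], par = fit$par, value = fit$value,
                       convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed from every start")
  par <- best$par
  names(par) <- c("D", "alpha", "vdrift")
  list(par = par, objective = best$value, kind = kind, trace = trace,
       convergence = best$convergence)
}
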