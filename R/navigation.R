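#' Navigation-strategy parameters
#'
#' Parameters shared by the heading simulators and the analytic
#' (Fokker-Planck) distributions. The attractant direction is theta = pi/2.
#'
#' @param eps_d deterministic steering rate (1/s), >= 0.
#' @param eps_s stochastic bias (dimensionless, in [-1, 1]).
#' @param dr rotational diffusion constant (1/s), > 0.
#' @param v swimming speed (um/s), > 0.
#' @return object of class \code{strategy_params}; \code{kd = eps_d / 2 dr}
#'   is derived, never stored independently.
#' @export
strategy_params <- function(eps_d = 0.28, eps_s = 0.55, dr = 0.33, v = 16.5) {
  stopifnot(dr > 0, v > 0, eps_d >= 0, abs(eps_s) <= 1)
  structure(list(eps_d = eps_d, eps_s = eps_s, dr = dr, v = v),
            class = "strategy_params")
}

#' @rdname strategy_params
#' @param params a \code{strategy_params}.
#' @export
kd_of <- function(params) params$eps_d / (2 * params$dr)

new_angle_ensemble <- function(theta, dt, x = NULL, y = NULL, seed = NA) {
  structure(list(theta = theta, dt = dt, x = x, y = y, seed = seed),
            class = "angle_ensemble")
}

check_sde_dt <- function(dt, rate) {
  if (dt * rate > 0.1) {
    stop("dt too large for stable Euler-Maruyama integration; need dt << 1/",
         "max(eps_d, dr) (dt * rate = ", signif(dt * rate, 3), " > 0.1)")
  }
}

#' Simulate the deterministic-steering navigation strategy
#'
#' Euler-Maruyama integration of the Langevin heading equation
#' \eqn{d\theta = \epsilon_d \cos\theta\, dt + \sqrt{2 d_r}\, dW}, whose
#' stable fixed point (for \eqn{d_r = 0}) is the attractant direction
#' \eqn{\theta = \pi/2}.
#'
#' @param params a \code{strategy_params} (uses \code{eps_d}, \code{dr}).
#' @param n number of independent trajectories.
#' @param t_end duration (s).
#' @param dt integration step (s), default 1e-3.
#' @param seed RNG seed (mandatory; stored in the output).
#' @param save_every store the heading every this many steps (default:
#'   every step).
#' @param theta0 initial headings (radians); default uniform on the circle.
#' @return an \code{angle_ensemble} with matrix \code{theta} (n x times).
#' @export
simulate_deterministic <- function(params, n, t_end, dt = 1e-3, seed,
                                   save_every = 1L, theta0 = NULL) {
  stopifnot(inherits(params, "strategy_params"), n >= 1, t_end > 0)
  if (missing(seed)) stop("seed is mandatory")
  check_sde_dt(dt, max(params$eps_d, params$dr))
  set.seed(seed)
  if (is.null(theta0)) theta0 <- stats::runif(n, -pi, pi)
  nsteps <- round(t_end / dt)
  th <- sim_angles_cpp(0L, theta0, params$eps_d, params$dr, dt, nsteps,
                       as.integer(save_every))
  new_angle_ensemble(th, dt * save_every, seed = seed)
}

#' Simulate the stochastic (rotational-diffusion modulation) strategy
#'
#' Ito Euler-Maruyama integration of
#' \eqn{d\theta = \sqrt{2 d_r (1 - \epsilon_s \sin\theta)}\, dW}: no drift
#' term is added (Ito convention); the heading decorrelates more slowly when
#' pointing up-gradient, producing a net bias without steering.
#'
#' @inheritParams simulate_deterministic
#' @return an \code{angle_ensemble}.
#' @export
simulate_stochastic <- function(params, n, t_end, dt = 1e-3, seed,
                                save_every = 1L, theta0 = NULL) {
  stopifnot(inherits(params, "strategy_params"), n >= 1, t_end > 0)
  if (missing(seed)) stop("seed is mandatory")
  if (abs(params$eps_s) >= 1) stop("|eps_s| must be < 1 for nondegenerate noise")
  check_sde_dt(dt, params$dr)
  set.seed(seed)
  if (is.null(theta0)) theta0 <- stats::runif(n, -pi, pi)
  nsteps <- round(t_end / dt)
  th <- sim_angles_cpp(1L, theta0, params$eps_s, params$dr, dt, nsteps,
                       as.integer(save_every))
  new_angle_ensemble(th, dt * save_every, seed = seed)
}

#' Steady-state heading density, deterministic strategy (von Mises)
#'
#' The zero-flux stationary solution of the steering Langevin dynamics is a
#' von Mises distribution with mode at the attractant direction \eqn{\pi/2}
#' and concentration \eqn{\kappa = \epsilon_d / d_r} (i.e. \eqn{2 k_d} in
#' the conventional single-parameter form \eqn{k_d = \epsilon_d / 2 d_r}):
#' \eqn{p_d(\theta) = e^{\kappa \sin\theta} / (2\pi I_0(\kappa))}. The
#' concentration follows directly from integrating
#' \eqn{d_r p' = \epsilon_d \cos\theta\, p} and is confirmed by long-run
#' simulation of the Langevin equation.
#'
#' @param theta angles (radians).
#' @param eps_d steering rate (1/s).
#' @param dr rotational diffusion (1/s), > 0.
#' @return density values.
#' @export
steady_pdf_deterministic <- function(theta, eps_d, dr) {
  stopifnot(dr > 0, eps_d >= 0)
  kappa <- eps_d / dr
  exp(kappa * (sin(theta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Steady-state heading density, stochastic strategy
#'
#' \eqn{p_s(\theta) = \sqrt{1-\epsilon_s^2} / (2\pi(1 - \epsilon_s
#' \sin\theta))}; independent of \eqn{d_r}.
#'
#' @param theta angles (radians).
#' @param eps_s bias in (-1, 1).
#' @return density values.
#' @export
steady_pdf_stochastic <- function(theta, eps_s) {
  stopifnot(abs(eps_s) < 1)
  sqrt(1 - eps_s^2) / (2 * pi * (1 - eps_s * sin(theta)))
}

#' Turn-angle density, deterministic strategy
#'
#' Density of \eqn{\Delta\phi = |\delta| + \xi} over a short interval
#' \eqn{\Delta t}, where the deterministic part \eqn{\delta = \epsilon_d
#' \cos\theta\,\Delta t} has the arcsine law induced by a uniform pre-swap
#' heading and \eqn{\xi \sim N(0, 2 d_r \Delta t)}. The convolution integral
#' is evaluated by Gauss-Legendre quadrature after the substitution
#' \eqn{\delta = \epsilon_d \Delta t \sin u}, which removes the
#' inverse-square-root endpoint singularity.
#'
#' @param dphi turn angles (radians).
#' @param eps_d steering rate (1/s).
#' @param dr rotational diffusion (1/s).
#' @param dt_lag the lag \eqn{\Delta t} (s), small enough that
#'   \eqn{|\Delta\phi| < \pi}.
#' @param nodes quadrature order (default 64).
#' @return density values; nonnegative, integrating to 1 over the real line.
#' @export
delta_phi_pdf_deterministic <- function(dphi, eps_d, dr, dt_lag, nodes = 64L) {
  stopifnot(eps_d >= 0, dr > 0, dt_lag > 0)
  gl <- gauss_legendre(nodes, 0, pi / 2)
  dmax <- eps_d * dt_lag
  s2 <- 2 * dr * dt_lag
  # p(Delta phi) = (2/pi) * int_0^{pi/2} N(dphi - dmax sin u; 0, s2) du
  delt <- dmax * sin(gl$nodes)
  vapply(dphi, function(p) {
    (2 / pi) * sum(gl$weights * stats::dnorm(p - delt, sd = sqrt(s2)))
  }, numeric(1))
}

#' Turn-angle density, stochastic strategy
#'
#' Marginalizes the Gaussian increment \eqn{N(0, 2 d_r (1 - \epsilon_s
#' \sin\theta)\Delta t)} over a uniform pre-swap heading (Gauss-Legendre
#' quadrature in \eqn{\theta}). Symmetric about zero: as many turns away
#' from the gradient as toward it.
#'
#' @param dphi turn angles (radians).
#' @param eps_s bias in (-1, 1).
#' @param dr rotational diffusion (1/s).
#' @param dt_lag the lag \eqn{\Delta t} (s).
#' @param nodes quadrature order (default 64).
#' @return density values.
#' @export
delta_phi_pdf_stochastic <- function(dphi, eps_s, dr, dt_lag, nodes = 64L) {
  stopifnot(abs(eps_s) < 1, dr > 0, dt_lag > 0)
  gl <- gauss_legendre(nodes, -pi, pi)
  s2 <- 2 * dr * (1 - eps_s * sin(gl$nodes)) * dt_lag
  vapply(dphi, function(p) {
    sum(gl$weights * stats::dnorm(p, sd = sqrt(s2))) / (2 * pi)
  }, numeric(1))
}

#' Stationary-approximation drift velocity of the stochastic strategy
#'
#' Closed form \eqn{v_{drift} = v\,\langle\sin\theta\rangle =
#' v\,[1/\epsilon_s - \sqrt{1/\epsilon_s^2 - 1}]}, i.e. the mean of
#' \eqn{\sin\theta} under the stochastic steady state times the swimming
#' speed. Continuous limits: 0 as \eqn{\epsilon_s \to 0}, \eqn{v} at
#' \eqn{\epsilon_s = 1}.
#'
#' @param eps_s bias in [0, 1].
#' @param v swimming speed (um/s).
#' @return drift velocity (um/s).
#' @export
drift_velocity <- function(eps_s, v = 16.5) {
  stopifnot(all(eps_s >= 0), all(eps_s <= 1), v > 0)
  out <- ifelse(eps_s == 0, 0,
                v * (1 / eps_s - sqrt(pmax(1 / eps_s^2 - 1, 0))))
  out
}

#' Velocity-modulation parameter needed for a given drift fraction
#'
#' Under speed-modulated taxis \eqn{v(\hat p) = v(1 + \gamma\,\hat p \cdot
#' \nabla c/|\nabla c|)} with an isotropic heading distribution, the
#' ensemble drift along the gradient is \eqn{v\gamma\langle p_y^2\rangle =
#' v\gamma/2} in 2D and \eqn{v\gamma/3} in 3D. Given an observed drift
#' fraction \eqn{f = v_{drift}/v} this returns the \eqn{\gamma} required:
#' \eqn{2f} (2D) or \eqn{3f} (3D). Optionally verifies the heading second
#' moment by Monte Carlo over isotropic directions.
#'
#' @param drift_fraction observed \eqn{v_{drift}/v}.
#' @param dimension 2 or 3.
#' @param n_mc if > 0, number of Monte-Carlo isotropic headings used to
#'   estimate \eqn{\langle p_y^2 \rangle} instead of the exact 1/2 or 1/3.
#' @return required \eqn{\gamma}.
#' @export
velocity_modulation_gamma <- function(drift_fraction, dimension = c(2, 3),
                                      n_mc = 0) {
  dimension <- match.arg(as.character(dimension[1]), c("2", "3"))
  stopifnot(drift_fraction >= 0)
  if (n_mc > 0) {
    if (dimension == "2") {
      py2 <- mean(sin(stats::runif(n_mc, -pi, pi))^2)
    } else {
      # isotropic on the sphere: cos(psi) uniform in [-1, 1]
      py2 <- mean(stats::runif(n_mc, -1, 1)^2)
    }
  } else {
    py2 <- if (dimension == "2") 1 / 2 else 1 / 3
  }
  drift_fraction / py2
}

#' Maximum-likelihood fit of a steady-state heading distribution
#'
#' Fits the single free parameter of either heading model to pooled theta
#' samples: \eqn{k_d} for the deterministic (von Mises, mean fixed at
#' \eqn{\pi/2}) family or \eqn{\epsilon_s} for the stochastic family.
#'
#' @param theta pooled heading samples (radians).
#' @param model \code{"deterministic"} or \code{"stochastic"}.
#' @return list with \code{parameter} (named \code{kd} or \code{eps_s}),
#'   \code{logLik}, \code{model}, and \code{n}.
#' @export
fit_angle_model <- function(theta, model = c("stochastic", "deterministic")) {
  model <- match.arg(model)
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < 10) stop("need at least 10 angle samples")
  st <- sin(theta)
  if (model == "deterministic") {
    # fit the von Mises concentration kappa = eps_d/dr; report kd = kappa/2
    nll <- function(kap) {
      -(kap * sum(st) - n * (log(2 * pi) + log(besselI(kap, 0, TRUE)) + kap))
    }
    opt <- stats::optimize(nll, c(0, 100))
    par <- c(kd = opt$minimum / 2)
  } else {
    nll <- function(e) {
      -(n / 2 * log(1 - e^2) - sum(log1p(-e * st)) - n * log(2 * pi))
    }
    opt <- stats::optimize(nll, c(-0.999, 0.999))
    par <- c(eps_s = opt$minimum)
  }
  list(parameter = par, logLik = -opt$objective, model = model, n = n)
}

#' One-parameter fit of the turn-angle distribution in dr
#'
#' Holds the steady-state parameter fixed (\eqn{k_d} for the deterministic
#' family -- so \eqn{\epsilon_d = 2 k_d d_r} varies with the fitted
#' \eqn{d_r} -- or \eqn{\epsilon_s} for the stochastic family) and fits
#' \eqn{d_r} to pooled \eqn{\Delta\phi} samples by maximum likelihood on
#' the analytic densities. Reports the maximized log-likelihood and a
#' histogram chi-squared statistic as goodness-of-fit measures.
#'
#' @param dphi pooled turn-angle samples (radians).
#' @param model \code{"deterministic"} or \code{"stochastic"}.
#' @param fixed the held parameter: \code{kd} (deterministic) or
#'   \code{eps_s} (stochastic).
#' @param dt_lag the lag \eqn{\Delta t} (s) used to form \code{dphi}.
#' @param nbins bins for the chi-squared diagnostic.
#' @return list with \code{dr}, \code{logLik}, \code{chisq}, \code{model}.
#' @export
fit_delta_phi <- function(dphi, model = c("stochastic", "deterministic"),
                          fixed, dt_lag, nbins = 41L) {
  model <- match.arg(model)
  dphi <- dphi[is.finite(dphi)]
  n <- length(dphi)
  if (n < 10) stop("need at least 10 turn-angle samples")
  if (stats::sd(dphi) < 1e-12) stop("degenerate (zero-variance) turn-angle sample")
  pdf_at <- function(dr) {
    if (model == "deterministic") {
      delta_phi_pdf_deterministic(dphi, eps_d = 2 * fixed * dr, dr = dr,
                                  dt_lag = dt_lag)
    } else {
      delta_phi_pdf_stochastic(dphi, eps_s = fixed, dr = dr, dt_lag = dt_lag)
    }
  }
  nll <- function(ldr) -sum(log(pmax(pdf_at(exp(ldr)), 1e-300)))
  opt <- stats::optimize(nll, log(c(1e-3, 50)))
  dr <- exp(opt$minimum)
  # histogram chi-squared against the fitted density
  br <- seq(min(dphi), max(dphi), length.out = nbins + 1L)
  h <- graphics::hist(dphi, breaks = br, plot = FALSE)
  mids <- h$mids
  expct <- n * diff(br) * (if (model == "deterministic") {
    delta_phi_pdf_deterministic(mids, 2 * fixed * dr, dr, dt_lag)
  } else {
    delta_phi_pdf_stochastic(mids, fixed, dr, dt_lag)
  })
  keep <- expct > 5
  chisq <- sum((h$counts[keep] - expct[keep])^2 / expct[keep])
  list(dr = dr, logLik = -opt$objective, chisq = chisq, model = model,
       fixed = fixed, n = n)
}

#' Monte-Carlo oracle samples for the turn-angle distributions
#'
#' Direct sampling of the short-interval turn-angle construction (uniform
#' pre-swap heading): deterministic, \eqn{\Delta\phi = |\epsilon_d
#' \cos\theta\, \Delta t| + N(0, 2 d_r \Delta t)}; stochastic,
#' \eqn{\Delta\phi \sim N(0, 2 d_r (1-\epsilon_s\sin\theta)\Delta t)}.
#' Used as an independent check of the quadrature densities.
#'
#' @param n number of samples.
#' @param model \code{"deterministic"} or \code{"stochastic"}.
#' @param eps \code{eps_d} or \code{eps_s} depending on model.
#' @param dr rotational diffusion (1/s).
#' @param dt_lag lag (s).
#' @return numeric samples.
#' @export
sample_delta_phi <- function(n, model = c("stochastic", "deterministic"),
                             eps, dr, dt_lag) {
  model <- match.arg(model)
  th <- stats::runif(n, -pi, pi)
  if (model == "deterministic") {
    abs(eps * cos(th) * dt_lag) + stats::rnorm(n, sd = sqrt(2 * dr * dt_lag))
  } else {
    stats::rnorm(n, sd = sqrt(2 * dr * (1 - eps * sin(th)) * dt_lag))
  }
}

#' Kolmogorov-Smirnov distance between samples and an analytic circular pdf
#'
#' Compares the empirical CDF of wrapped angle samples with the CDF of a
#' density given on a fine grid over (-pi, pi].
#'
#' @param samples angle samples (radians; wrapped internally).
#' @param pdf_fun function of theta returning the density.
#' @param ngrid grid size for the analytic CDF.
#' @return the sup-norm CDF distance.
#' @export
ks_distance_circular <- function(samples, pdf_fun, ngrid = 4096L) {
  x <- sort(wrap_angle(samples))
  grid <- seq(-pi, pi, length.out = ngrid)
  p <- pdf_fun(grid)
  cdf <- cumsum(c(0, (p[-1] + p[-ngrid]) / 2 * diff(grid)))
  cdf <- cdf / cdf[ngrid]
  Fa <- stats::approx(grid, cdf, xout = x, rule = 2)$y
  n <- length(x)
  max(abs(Fa - seq_len(n) / n), abs(Fa - (seq_len(n) - 1) / n))
}
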