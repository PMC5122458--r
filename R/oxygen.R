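#' Solve the oxygen diffusion equation on the device cross-section
#'
#' Finite-volume discretisation of \eqn{\partial c/\partial t =
#' \nabla\cdot(D_c \nabla c)} on the cell-centered grid of a
#' \code{\link{device_geometry}}, with backward-Euler (implicit) time
#' stepping. Gas-channel cells carry Dirichlet values set by the protocol
#' (air = 20\%, nitrogen = 0\%); the outer glass boundaries are no-flux.
#' Face diffusivities across the PDMS/water interface are harmonic means,
#' which keeps interior fluxes conservative at the material discontinuity.
#'
#' The implicit operator is an M-matrix, so the discrete solution obeys the
#' maximum principle: concentrations remain within the envelope of initial
#' and boundary values (up to linear-solver tolerance). The sparse
#' symmetric-positive-definite system is factorised once (Cholesky) and
#' re-used for every step.
#'
#' @param geometry a \code{device_geometry}.
#' @param dmap a \code{diffusivity_map} on the same grid.
#' @param protocol a \code{gas_protocol}.
#' @param t_end end time (s).
#' @param dt time step (s), default 1.
#' @param output_every interval (s) between stored fields, default 10; must
#'   be a multiple of \code{dt}.
#' @param c_init initial field: a scalar (\% oxygen, uniform) or a matrix
#'   matching the grid.
#' @param min_cells_per_feature resolution guard: the narrowest channel must
#'   span at least this many cells (default 4).
#' @return object of class \code{oxygen_field}: \code{y}, \code{z} (um),
#'   \code{t} (s), and \code{c}, an array \code{[ny, nz, nt]} in \% oxygen.
#' @export
solve_diffusion <- function(geometry, dmap, protocol, t_end,
                            dt = 1, output_every = 10, c_init = 20,
                            min_cells_per_feature = 4L) {
  stopifnot(inherits(geometry, "device_geometry"),
            inherits(dmap, "diffusivity_map"),
            inherits(protocol, "gas_protocol"),
            dt > 0, t_end > 0, output_every >= dt)
  if (abs(output_every / dt - round(output_every / dt)) > 1e-9) {
    stop("output_every must be a multiple of dt")
  }
  mat <- geometry$material
  ny <- nrow(mat); nz <- ncol(mat)
  # resolution guard: narrowest feature across y and z
  feat_y <- min(geometry$config$chamber_width, geometry$config$gas_width,
                geometry$config$gas_gap) / geometry$dy
  feat_z <- geometry$channel_thickness / geometry$dz
  if (min(feat_y, feat_z) < min_cells_per_feature) {
    stop("grid does not resolve the narrowest feature with at least ",
         min_cells_per_feature, " cells")
  }

  is_gas <- mat %in% c("gas_left", "gas_right")
  gas_side <- ifelse(mat == "gas_left", 1L, ifelse(mat == "gas_right", 2L, 0L))
  idx_all <- matrix(seq_len(ny * nz), ny, nz)
  unknown <- which(!is_gas)                 # linear indices of solved cells
  umap <- integer(ny * nz); umap[unknown] <- seq_along(unknown)
  n_u <- length(unknown)

  D <- dmap$D
  dy2 <- geometry$dy^2; dz2 <- geometry$dz^2
  hm <- function(a, b) 2 * a * b / (a + b)

  # vectorized face lists: (a, b, coef) for y-neighbors and z-neighbors
  fy_a <- as.integer(idx_all[-ny, , drop = FALSE])
  fy_b <- as.integer(idx_all[-1L, , drop = FALSE])
  fz_a <- as.integer(idx_all[, -nz, drop = FALSE])
  fz_b <- as.integer(idx_all[, -1L, drop = FALSE])
  fa <- c(fy_a, fz_a)
  fb <- c(fy_b, fz_b)
  coef <- dt * hm(D[fa], D[fb]) /
    c(rep(dy2, length(fy_a)), rep(dz2, length(fz_a)))
  keep <- !(is_gas[fa] & is_gas[fb])
  fa <- fa[keep]; fb <- fb[keep]; coef <- coef[keep]

  diagv <- numeric(n_u)
  bc_left <- numeric(n_u); bc_right <- numeric(n_u)
  acc <- function(vec, at, val) {
    s <- tapply(val, at, sum)
    vec[as.integer(names(s))] <- vec[as.integer(names(s))] + as.numeric(s)
    vec
  }
  # every face touching an unknown cell adds to that cell's diagonal
  ua <- umap[fa]; ub <- umap[fb]
  sel_a <- !is_gas[fa]
  sel_b <- !is_gas[fb]
  diagv <- acc(diagv, ua[sel_a], coef[sel_a])
  diagv <- acc(diagv, ub[sel_b], coef[sel_b])
  # off-diagonals between two unknown cells
  both <- sel_a & sel_b
  ii <- c(ua[both], ub[both]); jj <- c(ub[both], ua[both])
  xx <- c(-coef[both], -coef[both])
  # couplings to gas (Dirichlet) cells feed the RHS
  ga <- sel_a & is_gas[fb]   # a unknown, b gas
  gb <- sel_b & is_gas[fa]
  bc_left <- acc(bc_left, ua[ga & gas_side[fb] == 1L], coef[ga & gas_side[fb] == 1L])
  bc_right <- acc(bc_right, ua[ga & gas_side[fb] == 2L], coef[ga & gas_side[fb] == 2L])
  bc_left <- acc(bc_left, ub[gb & gas_side[fa] == 1L], coef[gb & gas_side[fa] == 1L])
  bc_right <- acc(bc_right, ub[gb & gas_side[fa] == 2L], coef[gb & gas_side[fa] == 2L])

  A <- Matrix::sparseMatrix(i = c(seq_len(n_u), ii), j = c(seq_len(n_u), jj),
                            x = c(1 + diagv, xx), dims = c(n_u, n_u))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  if (length(c_init) == 1L) {
    cfull <- matrix(c_init, ny, nz)
  } else {
    stopifnot(is.matrix(c_init), nrow(c_init) == ny, ncol(c_init) == nz)
    cfull <- c_init
  }
  cu <- as.numeric(cfull)[unknown]

  nsteps <- ceiling(t_end / dt - 1e-9)
  stride <- round(output_every / dt)
  out_steps <- seq(0L, nsteps, by = stride)
  if (out_steps[length(out_steps)] != nsteps) out_steps <- c(out_steps, nsteps)
  tout <- out_steps * dt
  carr <- array(NA_real_, c(ny, nz, length(tout)))

  store <- function(k, cu, bvals) {
    full <- numeric(ny * nz)
    full[unknown] <- cu
    full[is_gas & gas_side == 1L] <- bvals["left"]
    full[is_gas & gas_side == 2L] <- bvals["right"]
    carr[, , k] <<- full
  }
  bvals <- protocol_values(protocol, 0)
  store(1L, cu, bvals)
  ko <- 2L
  for (s in seq_len(nsteps)) {
    tn1 <- s * dt
    bvals <- protocol_values(protocol, tn1)
    b <- cu + bc_left * bvals["left"] + bc_right * bvals["right"]
    cu <- as.numeric(Matrix::solve(ch, b))
    if (ko <= length(out_steps) && s == out_steps[ko]) {
      store(ko, cu, bvals)
      ko <- ko + 1L
    }
  }

  structure(list(y = geometry$y, z = geometry$z, t = tout, c = carr,
                 geometry = geometry, protocol = protocol),
            class = "oxygen_field")
}

#' Extract the chamber concentration profile at a given height
#'
#' Restricts an \code{\link{oxygen_field}} to the sample-channel y-extent at
#' the grid height nearest \code{z_eval}, for all stored times, and exposes
#' the lateral gradient by centered differences (one-sided at the chamber
#' edges).
#'
#' @param field an \code{oxygen_field}.
#' @param z_eval evaluation height (um); must lie within the channel
#'   vertical extent.
#' @return object of class \code{chamber_profile}: \code{y} (um), \code{t}
#'   (s), matrices \code{c} and \code{dc_dy} of size \code{ny_chamber x nt}.
#' @export
chamber_profile <- function(field, z_eval = 100) {
  stopifnot(inherits(field, "oxygen_field"))
  geom <- field$geometry
  if (z_eval < 0 || z_eval > geom$channel_thickness) {
    stop("z_eval outside the sample-channel vertical extent")
  }
  j <- which.min(abs(field$z - z_eval))
  sel <- field$y > geom$chamber_y[1] & field$y < geom$chamber_y[2]
  y <- field$y[sel]
  cm <- field$c[sel, j, , drop = FALSE]
  cm <- array(cm, c(sum(sel), length(field$t)))
  g <- apply(cm, 2, function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / geom$dy
  })
  structure(list(y = y, t = field$t, c = cm, dc_dy = g,
                 chamber_y = geom$chamber_y), class = "chamber_profile")
}

#' Construct a chamber profile from concentration frames
#'
#' Builds a \code{chamber_profile} directly from a matrix of concentration
#' frames (e.g. an idealized field for testing or coupling), computing the
#' lateral gradient by centered differences.
#'
#' @param y grid centers (um), uniform spacing.
#' @param t frame times (s).
#' @param c matrix \code{length(y) x length(t)} of concentrations (\%).
#' @return a \code{chamber_profile}.
#' @export
as_chamber_profile <- function(y, t, c) {
  c <- as.matrix(c)
  stopifnot(nrow(c) == length(y), ncol(c) == length(t), length(y) >= 3)
  dy <- y[2] - y[1]
  g <- apply(c, 2, function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / dy
  })
  structure(list(y = y, t = t, c = c, dc_dy = g, chamber_y = range(y)),
            class = "chamber_profile")
}

#' Write a chamber profile to CSV (columns t, y, c, dc_dy)
#' @param profile a \code{chamber_profile}.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
write_chamber_profile <- function(profile, path) {
  stopifnot(inherits(profile, "chamber_profile"))
  df <- data.frame(t = rep(profile$t, each = length(profile$y)),
                   y = rep(profile$y, length(profile$t)),
                   c = as.numeric(profile$c),
                   dc_dy = as.numeric(profile$dc_dy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a chamber profile written by \code{write_chamber_profile}
#' @param path CSV path.
#' @return a \code{chamber_profile} (without chamber extent metadata).
#' @export
read_chamber_profile <- function(path) {
  df <- utils::read.csv(path)
  t <- sort(unique(df$t)); y <- sort(unique(df$y))
  o <- order(df$t, df$y)
  structure(list(y = y, t = t,
                 c = matrix(df$c[o], length(y), length(t)),
                 dc_dy = matrix(df$dc_dy[o], length(y), length(t)),
                 chamber_y = range(y)),
            class = "chamber_profile")
}

#' Analytic steady-state profile for a one-dimensional two-material slab
#'
#' Steady diffusion across PDMS | water | PDMS between two fixed boundary
#' concentrations, used as an independent oracle for the 2D solver when the
#' channels span the full slab height (the problem is then exactly 1D).
#' Within each material the profile is linear with slope inversely
#' proportional to the local diffusivity (constant flux).
#'
#' @param y positions (um) at which to evaluate, measured with 0 at the
#'   chamber center.
#' @param c_left,c_right boundary concentrations (\%) at the inner gas-channel
#'   walls.
#' @param half_chamber chamber half-width (um).
#' @param gap PDMS gap width (um).
#' @param D_pdms,D_water diffusivities (any common unit).
#' @return concentrations at \code{y}.
#' @export
steady_two_layer_profile <- function(y, c_left, c_right, half_chamber, gap,
                                     D_pdms, D_water) {
  R <- 2 * gap / D_pdms + 2 * half_chamber / D_water
  q <- (c_left - c_right) / R           # flux * unit area
  # resistance accumulated from the left gas wall (y = -half_chamber - gap)
  racc <- function(yy) {
    s <- pmin(pmax(yy, -half_chamber - gap), half_chamber + gap)
    r <- numeric(length(s))
    left_pdms <- pmin(s, -half_chamber) - (-half_chamber - gap)
    r <- left_pdms / D_pdms
    wat <- pmin(pmax(s, -half_chamber), half_chamber) + half_chamber
    r <- r + wat / D_water
    right_pdms <- pmax(s, half_chamber) - half_chamber
    r + right_pdms / D_pdms
  }
  c_left - q * racc(y)
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat("oxygen_field:", dim(x$c)[1], "x", dim(x$c)[2], "cells,",
      length(x$t), "times, c in [", signif(min(x$c), 3), ",",
      signif(max(x$c), 3), "] %\n")
  invisible(x)
}
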