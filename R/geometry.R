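#' Microfluidic device cross-section geometry
#'
#' Builds the 2D cross-section (y across the device, z height above the
#' bottom glass) of a PDMS gas-gradient device: a water-filled sample
#' channel (the observation chamber) flanked symmetrically by two gas
#' channels, all etched to the same thickness and bonded between glass
#' slides. Each grid cell is classified as PDMS, water, or one of the two
#' gas channels; gas cells carry Dirichlet oxygen boundary conditions, and
#' all outer (glass) boundaries are no-flux.
#'
#' Default lateral dimensions are a documented choice (the device footprint
#' is only known approximately): chamber 1000 um wide, gas channels 1000 um
#' wide separated from the chamber by 500 um of PDMS, 500 um PDMS margin
#' beyond each gas channel, slab height 575 um, channel thickness 115 um.
#'
#' @param chamber_width width of the sample channel (um).
#' @param gas_width width of each gas channel (um).
#' @param gas_gap PDMS gap between chamber edge and gas channel edge (um).
#' @param margin PDMS margin beyond the outer edge of each gas channel (um).
#' @param slab_height total PDMS slab height (um).
#' @param channel_thickness vertical extent of all channels (um, ~115).
#' @param dy,dz grid spacing (um) in y and z. Cell-centered grid.
#' @return object of class \code{device_geometry}: grid centers \code{y},
#'   \code{z}, spacings, a \code{material} matrix (ny x nz) with values
#'   \code{"pdms"}, \code{"water"}, \code{"gas_left"}, \code{"gas_right"},
#'   and the chamber extent \code{chamber_y = c(y0, y1)}.
#' @export
device_geometry <- function(chamber_width = 1000, gas_width = 1000,
                            gas_gap = 500, margin = 500,
                            slab_height = 575, channel_thickness = 115,
                            dy = 25, dz = 23) {
  dims <- c(chamber_width = chamber_width, gas_width = gas_width,
            gas_gap = gas_gap, margin = margin, slab_height = slab_height,
            channel_thickness = channel_thickness, dy = dy, dz = dz)
  pos_dims <- setdiff(names(dims), c("margin", "gas_gap"))
  if (any(!is.finite(dims)) || any(dims[pos_dims] <= 0) || margin < 0) {
    stop("all geometry dimensions must be positive (margin may be zero)")
  }
  if (channel_thickness > slab_height) {
    stop("channel thickness exceeds slab height")
  }
  # gas channels must not overlap the sample channel
  if (gas_gap <= 0) stop("gas channels overlap the sample channel")
  slab_width <- chamber_width + 2 * (gas_gap + gas_width + margin)

  ny <- max(2L, round(slab_width / dy))
  nz <- max(2L, round(slab_height / dz))
  y <- seq(-slab_width / 2 + dy / 2, by = dy, length.out = ny)
  z <- seq(dz / 2, by = dz, length.out = nz)

  half_ch <- chamber_width / 2
  gas_in <- half_ch + gas_gap
  gas_out <- gas_in + gas_width

  material <- matrix("pdms", ny, nz)
  in_z <- z <= channel_thickness
  for (j in which(in_z)) {
    material[abs(y) < half_ch, j] <- "water"
    material[y <= -gas_in & y > -gas_out, j] <- "gas_left"
    material[y >= gas_in & y < gas_out, j] <- "gas_right"
  }
  if (!any(material == "water") || !any(material == "gas_left") ||
      !any(material == "gas_right")) {
    stop("grid too coarse: a channel is not resolved")
  }

  structure(list(y = y, z = z, dy = dy, dz = dz,
                 slab_width = slab_width, slab_height = slab_height,
                 channel_thickness = channel_thickness,
                 chamber_y = c(-half_ch, half_ch),
                 material = material,
                 config = as.list(dims)),
            class = "device_geometry")
}

#' Build a geometry from a configuration list or JSON file
#'
#' @param config named list (or path to a JSON file containing one) with any
#'   of the arguments of \code{\link{device_geometry}}; missing entries take
#'   the defaults.
#' @return \code{device_geometry}.
#' @export
build_geometry <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  known <- names(formals(device_geometry))
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown geometry fields: ", paste(bad, collapse = ", "))
  do.call(device_geometry, config)
}

#' Oxygen diffusivity map
#'
#' Assigns each grid cell its oxygen diffusion constant: PDMS and water have
#' distinct diffusivities; gas cells are boundary cells and get the PDMS
#' value (never used in fluxes between two gas cells).
#'
#' @param geometry a \code{device_geometry}.
#' @param D_pdms,D_water diffusivities in mm^2/s (defaults 3.55e-3 and
#'   2.10e-3); converted to um^2/s internally.
#' @return object of class \code{diffusivity_map}: matrix \code{D} (um^2/s)
#'   aligned with \code{geometry$material}.
#' @export
diffusivity_map <- function(geometry, D_pdms = 3.55e-3, D_water = 2.10e-3) {
  stopifnot(inherits(geometry, "device_geometry"), D_pdms > 0, D_water > 0)
  D <- matrix(D_pdms * 1e6, nrow(geometry$material), ncol(geometry$material))
  D[geometry$material == "water"] <- D_water * 1e6
  structure(list(D = D, D_pdms = D_pdms * 1e6, D_water = D_water * 1e6),
            class = "diffusivity_map")
}

#' Gas perfusion protocol
#'
#' An ordered schedule of which gas flows in each side channel. Air imposes
#' a 20\% oxygen boundary condition, nitrogen 0\%.
#'
#' @param segments data.frame with columns \code{t_start} (s), \code{left},
#'   \code{right} (each \code{"air"} or \code{"nitrogen"}). May also be a
#'   path to a JSON file holding such a table.
#' @return object of class \code{gas_protocol}.
#' @export
gas_protocol <- function(segments) {
  if (is.character(segments)) {
    segments <- as.data.frame(jsonlite::read_json(segments, simplifyVector = TRUE))
  }
  segments <- as.data.frame(segments)
  stopifnot(all(c("t_start", "left", "right") %in% names(segments)),
            nrow(segments) >= 1)
  if (segments$t_start[1] != 0) stop("first protocol segment must start at t = 0")
  if (is.unsorted(segments$t_start, strictly = TRUE)) {
    stop("protocol segments must be strictly time-ordered")
  }
  ok <- c("air", "nitrogen")
  if (!all(segments$left %in% ok) || !all(segments$right %in% ok)) {
    stop("gas must be 'air' or 'nitrogen'")
  }
  structure(list(segments = segments), class = "gas_protocol")
}

#' Boundary oxygen values imposed by a protocol at a time
#' @param protocol a \code{gas_protocol}.
#' @param t time (s).
#' @return named numeric \code{c(left =, right =)} in \% oxygen.
#' @export
protocol_values <- function(protocol, t) {
  stopifnot(inherits(protocol, "gas_protocol"))
  seg <- protocol$segments
  i <- findInterval(t, seg$t_start)
  if (i < 1) i <- 1
  conc <- c(air = 20, nitrogen = 0)
  c(left = unname(conc[seg$left[i]]), right = unname(conc[seg$right[i]]))
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("device_geometry:", x$slab_width, "x", x$slab_height, "um,",
      nrow(x$material), "x", ncol(x$material), "cells\n")
  cat("  chamber y in [", x$chamber_y[1], ",", x$chamber_y[2],
      "] um, channel thickness", x$channel_thickness, "um\n")
  invisible(x)
}
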