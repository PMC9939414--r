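#' Parameters of the synthetic bilobed-aneurysm geometry
#'
#' Defines a parametric 2D stand-in for a sidewall cerebral aneurysm with
#' two overlapping domes: a straight parent channel spanning the domain in
#' x, with a sac opening through a neck in its upper wall. The sac is the
#' union of two discs whose centers lie on a (possibly tilted) sac axis;
#' the lower disc intersects the upper channel wall in a chord of width
#' \code{neck_width}, which defines the neck plane.
#'
#' Defaults are internal-carotid-scale: 4 mm parent channel, 3 mm neck,
#' 3 / 2.4 mm dome radii overlapping into one bilobed sac with a visible
#' waist between the lower and upper dome.
#'
#' @param channel_width Parent-channel gap, m.
#' @param channel_length Channel (domain) length in x, m.
#' @param neck_width Neck chord width, m. Must satisfy
#'   \code{neck_width < 2 * dome1_radius} so the chord exists.
#' @param dome1_radius,dome2_radius Radii of the proximal (lower) and
#'   distal (upper) domes, m. Both zero gives a plain straight channel.
#' @param dome_offset Center-to-center distance between the domes along
#'   the sac axis, m; must be < \code{dome1_radius + dome2_radius} when
#'   both radii are positive (the domes must overlap into one sac).
#' @param sac_tilt Tilt of the sac axis from the channel normal, rad.
#' @param grid_nx,grid_ny Cell counts of the Cartesian grid.
#' @param dx Isotropic cell size, m. \code{dx * grid_nx} must cover
#'   \code{channel_length}.
#' @param neck_x_frac Position of the neck center along the channel as a
#'   fraction of \code{channel_length}; upstream of center by default so
#'   at least two channel widths of parent wall remain on each side.
#' @param wall_margin Solid margin below the channel's lower wall, m.
#'
#' @return An object of class \code{"geometry_params"}.
#' @seealso [build_geometry()]
#' @export
geometry_params <- function(channel_width = 4e-3,
                            channel_length = 24e-3,
                            neck_width = 3e-3,
                            dome1_radius = 3e-3,
                            dome2_radius = 2.4e-3,
                            dome_offset = 3.5e-3,
                            sac_tilt = 0.35,
                            grid_nx = 192,
                            grid_ny = 112,
                            dx = channel_length / grid_nx,
                            neck_x_frac = 0.4,
                            wall_margin = 1e-3) {
  p <- list(channel_width = channel_width, channel_length = channel_length,
            neck_width = neck_width, dome1_radius = dome1_radius,
            dome2_radius = dome2_radius, dome_offset = dome_offset,
            sac_tilt = sac_tilt, grid_nx = as.integer(grid_nx),
            grid_ny = as.integer(grid_ny), dx = dx,
            neck_x_frac = neck_x_frac, wall_margin = wall_margin)
  validate_geometry_params(p)
  structure(p, class = "geometry_params")
}

validate_geometry_params <- function(p) {
  with(p, {
    stopifnot(channel_width > 0, channel_length > 0, neck_width > 0,
              dome1_radius >= 0, dome2_radius >= 0, dome_offset >= 0,
              grid_nx > 0, grid_ny > 0, dx > 0, wall_margin >= 0,
              neck_x_frac > 0, neck_x_frac < 1)
    if (neck_width >= channel_length)
      stop("neck_width must be smaller than channel_length")
    if (dx * grid_nx < channel_length - 1e-12)
      stop("grid does not cover the channel: dx * grid_nx < channel_length")
    if (dome1_radius > 0 && dome2_radius > 0 &&
        dome_offset >= dome1_radius + dome2_radius)
      stop("non-overlapping domes: dome_offset >= dome1_radius + dome2_radius ",
           "would give a disconnected sac")
    if (dome1_radius > 0 && neck_width >= 2 * dome1_radius)
      stop("neck_width must be < 2 * dome1_radius for the neck chord to exist")
    if (neck_width / dx < 6)
      stop("grid too coarse to resolve the neck: fewer than 6 cells across ",
           "neck_width (", format(neck_width / dx, digits = 3), ")")
  })
  invisible(p)
}

#' Build the discretized aneurysm geometry
#'
#' Constructs the level-set representation of the lumen on the Cartesian
#' grid: a signed distance-like function (negative inside the lumen), the
#' lumen mask, an ordered closed wall chain with inward unit normals and
#' arc length, and the neck / inlet / outlet segments. The lumen is the
#' union of the parent-channel slab and the two dome discs; the level
#' function is the pointwise minimum of the member signed distances
#' (exact signed distance away from junctions, Lipschitz everywhere).
#'
#' @param params A [geometry_params()] object.
#' @return An object of class \code{"aneurysm_geometry"}; a list with
#'   \code{sdf}, \code{lumen_mask}, \code{sac_mask}, \code{coil_mask}
#'   (all (nx, ny); coil mask initially empty), \code{wall} (data frame
#'   of ordered wall points: \code{x, y, nx, ny, s, in_view, on_cap}),
#'   \code{neck_segment}, \code{inlet_segment}, \code{outlet_segment},
#'   grid metadata and the originating parameters.
#' @export
#' @examples
#' geom <- build_geometry(geometry_params())
#' geom
build_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params
  nx <- p$grid_nx; ny <- p$grid_ny; dx <- p$dx
  Lx <- nx * dx; Ly <- ny * dx
  y_bot <- p$wall_margin
  y_top <- y_bot + p$channel_width
  x_neck <- p$neck_x_frac * p$channel_length
  xc <- cell_centers_x(nx, dx)
  yc <- cell_centers_y(ny, dx)
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  # channel slab: signed distance to the infinite y-slab [y_bot, y_top]
  sdf <- abs(Y - (y_bot + y_top) / 2) - p$channel_width / 2

  has_sac <- p$dome1_radius > 0
  dome1 <- dome2 <- NULL
  axis_dir <- c(sin(p$sac_tilt), cos(p$sac_tilt))
  if (has_sac) {
    # lower dome center: above the wall so its chord on y = y_top has
    # half-width neck_width / 2
    h1 <- sqrt(p$dome1_radius^2 - (p$neck_width / 2)^2)
    dome1 <- c(x_neck, y_top + h1)
    sdf <- pmin(sdf, sqrt((X - dome1[1])^2 + (Y - dome1[2])^2) - p$dome1_radius)
    if (p$dome2_radius > 0) {
      dome2 <- dome1 + p$dome_offset * axis_dir
      sdf <- pmin(sdf, sqrt((X - dome2[1])^2 + (Y - dome2[2])^2) - p$dome2_radius)
      if (dome2[2] + p$dome2_radius > Ly - 2 * dx)
        stop("distal dome reaches the top of the grid; enlarge grid_ny")
    }
  }

  lumen <- sdf < 0
  sac <- lumen & (Y > y_top)

  wall <- wall_chain(sdf, dx, Lx)
  # field of view for maxima: sac wall plus parent wall within two channel
  # widths of the neck, never the synthetic end caps
  wall$in_view <- !wall$on_cap &
    (wall$y > y_top + 0.5 * dx | abs(wall$x - x_neck) <= 2 * p$channel_width)

  geom <- structure(list(
    sdf = sdf, lumen_mask = lumen, sac_mask = sac,
    coil_mask = matrix(FALSE, nx, ny),
    wall = wall,
    neck_segment = list(x = c(x_neck - p$neck_width / 2,
                              x_neck + p$neck_width / 2),
                        y = c(y_top, y_top)),
    inlet_segment = list(x = c(0, 0), y = c(y_bot, y_top)),
    outlet_segment = list(x = c(Lx, Lx), y = c(y_bot, y_top)),
    nx = nx, ny = ny, dx = dx, Lx = Lx, Ly = Ly,
    y_bot = y_bot, y_top = y_top, x_neck = x_neck,
    dome1_center = dome1, dome2_center = dome2, sac_axis = axis_dir,
    params = params), class = "aneurysm_geometry")
  geom$fingerprint <- geometry_fingerprint(geom)
  geom
}

# Ordered closed wall chain from the zero level set. The lumen is open at
# the x ends (inlet/outlet); for the chain the level function is capped
# just inside the domain so grDevices::contourLines returns one closed
# loop. Cap-derived points are flagged `on_cap`.
wall_chain <- function(sdf, dx, Lx) {
  nx <- nrow(sdf); ny <- ncol(sdf)
  xc <- cell_centers_x(nx, dx); yc <- cell_centers_y(ny, dx)
  x_cap_lo <- 0.75 * dx; x_cap_hi <- Lx - 0.75 * dx
  capped <- pmax(sdf, x_cap_lo - matrix(xc, nx, ny),
                 matrix(xc, nx, ny) - x_cap_hi)
  cl <- grDevices::contourLines(xc, yc, capped, levels = 0)
  if (length(cl) == 0L) stop("empty lumen: no zero level set found")
  # keep the longest contour (the lumen boundary)
  len <- vapply(cl, function(s) length(s$x), integer(1))
  s0 <- cl[[which.max(len)]]
  px <- s0$x; py <- s0$y
  # drop duplicated closing vertex if present
  n <- length(px)
  if (n > 1 && abs(px[1] - px[n]) < 1e-15 && abs(py[1] - py[n]) < 1e-15) {
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  # enforce counter-clockwise orientation (lumen on the left of travel)
  area2 <- sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)
  if (area2 < 0) { px <- rev(px); py <- rev(py) }
  seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
  s <- c(0, cumsum(seg))[seq_len(n)]
  # inward unit normals from the (uncapped) level-function gradient
  g <- grad_centered(sdf, dx)
  gxw <- interp_bilinear(g$gx, px, py, dx)
  gyw <- interp_bilinear(g$gy, px, py, dx)
  on_cap <- px < x_cap_lo + dx | px > x_cap_hi - dx
  # on the caps the level-function gradient is x-directed by construction
  gxw[on_cap & px < Lx / 2] <- 1; gyw[on_cap & px < Lx / 2] <- 0
  gxw[on_cap & px >= Lx / 2] <- -1; gyw[on_cap & px >= Lx / 2] <- 0
  gn <- sqrt(gxw^2 + gyw^2)
  bad <- gn < 1e-12
  gn[bad] <- 1
  nxv <- -gxw / gn; nyv <- -gyw / gn
  nrm <- sqrt(nxv^2 + nyv^2)
  nxv <- nxv / nrm; nyv <- nyv / nrm
  data.frame(x = px, y = py, nx = nxv, ny = nyv, s = s,
             on_cap = on_cap, in_view = !on_cap,
             perimeter = s[n] + seg[n])
}

geometry_fingerprint <- function(geom) {
  p <- geom$params
  paste(format(c(unlist(p[c("channel_width", "channel_length", "neck_width",
                            "dome1_radius", "dome2_radius", "dome_offset",
                            "sac_tilt", "dx", "neck_x_frac", "wall_margin")]),
                 geom$nx, geom$ny, sum(geom$lumen_mask)),
               digits = 15), collapse = "|")
}

#' Assign the coil region of the sac
#'
#' Marks the portion of the sac lumen occupied by coil, filling from the
#' distal dome tip toward the neck along the sac axis. With the default
#' \code{fill_fraction = 1} (the configuration used for all coiled runs)
#' the whole sac lumen is coil; partial fills place the coil front
#' perpendicular to the sac axis.
#'
#' @param geometry An [build_geometry()] result.
#' @param fill_fraction Fraction of the sac area occupied by coil, in
#'   [0, 1].
#' @return The geometry with \code{coil_mask} set.
#' @export
set_coil <- function(geometry, fill_fraction = 1) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  if (!is.numeric(fill_fraction) || length(fill_fraction) != 1L ||
      !is.finite(fill_fraction) || fill_fraction < 0 || fill_fraction > 1)
    stop("fill_fraction must be a number in [0, 1]")
  sac_idx <- which(geometry$sac_mask)
  n_fill <- round(fill_fraction * length(sac_idx))
  mask <- matrix(FALSE, geometry$nx, geometry$ny)
  if (n_fill > 0 && length(sac_idx) > 0) {
    ij <- arrayInd(sac_idx, c(geometry$nx, geometry$ny))
    xs <- (ij[, 1] - 0.5) * geometry$dx
    ys <- (ij[, 2] - 0.5) * geometry$dx
    proj <- (xs - geometry$x_neck) * geometry$sac_axis[1] +
      (ys - geometry$y_top) * geometry$sac_axis[2]
    keep <- sac_idx[order(proj, decreasing = TRUE)][seq_len(n_fill)]
    mask[keep] <- TRUE
  }
  geometry$coil_mask <- mask
  geometry
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  p <- x$params
  cat("Bilobed aneurysm geometry (2D level set)\n")
  cat(sprintf("  grid        : %d x %d cells, dx = %.3g mm\n",
              x$nx, x$ny, 1e3 * x$dx))
  cat(sprintf("  channel     : %.2g x %.2g mm, neck %.2g mm at x = %.2g mm\n",
              1e3 * p$channel_length, 1e3 * p$channel_width,
              1e3 * p$neck_width, 1e3 * x$x_neck))
  cat(sprintf("  domes       : r = %.2g / %.2g mm, offset %.2g mm, tilt %.2f rad\n",
              1e3 * p$dome1_radius, 1e3 * p$dome2_radius,
              1e3 * p$dome_offset, p$sac_tilt))
  cat(sprintf("  lumen cells : %d (sac %d, coil %d)\n",
              sum(x$lumen_mask), sum(x$sac_mask), sum(x$coil_mask)))
  cat(sprintf("  wall chain  : %d points, perimeter %.3g mm\n",
              nrow(x$wall), 1e3 * x$wall$perimeter[1]))
  invisible(x)
}

#' @export
plot.aneurysm_geometry <- function(x, ...) {
  xc <- 1e3 * cell_centers_x(x$nx, x$dx)
  yc <- 1e3 * cell_centers_y(x$ny, x$dx)
  field <- matrix(0, x$nx, x$ny)
  field[x$lumen_mask] <- 1
  field[x$coil_mask] <- 2
  graphics::image(xc, yc, field, asp = 1, col = c("grey30", "white", "grey70"),
                  xlab = "x [mm]", ylab = "y [mm]",
                  main = "lumen (white) and coil (grey)", ...)
  graphics::lines(1e3 * x$wall$x, 1e3 * x$wall$y, col = "red3", lwd = 1)
  graphics::lines(1e3 * x$neck_segment$x, 1e3 * x$neck_segment$y,
                  col = "blue3", lwd = 2)
  invisible(x)
}
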