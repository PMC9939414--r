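test_that("parameter validation rejects degenerate requests", {
  expect_error(geometry_params(dome_offset = 6e-3), "disconnected")
  expect_error(geometry_params(neck_width = 7e-3), "neck chord")
  expect_error(geometry_params(grid_nx = 36, grid_ny = 21,
                               dx = 24e-3 / 36), "coarse")
  expect_error(geometry_params(channel_width = -1), "not TRUE")
})

test_that("level function and masks represent the channel-dome union", {
  geom <- build_geometry(geometry_params())
  # parent-channel cell nearest the centerline, far from the sac:
  # level value = distance to the nearest wall
  ymid <- 0.5 * (geom$y_bot + geom$y_top)
  yc <- coilflow:::cell_centers_y(geom$ny, geom$dx)
  j <- which.min(abs(yc - ymid))
  i <- round(0.9 * geom$nx)
  expect_equal(geom$sdf[i, j],
               abs(yc[j] - ymid) - geom$params$channel_width / 2,
               tolerance = 1e-12)
  # lumen area from pixel counting vs closed-form union area
  a_pix <- sum(geom$lumen_mask) * geom$dx^2
  a_exact <- analytic_lumen_area(geom$params, geom$Lx)
  per <- analytic_lumen_perimeter(geom$params, geom$Lx)
  expect_lt(abs(a_pix - a_exact), 2 * per * geom$dx)
  # sac mask is the lumen above the upper wall
  expect_true(all(which(geom$sac_mask) %in% which(geom$lumen_mask)))
})

test_that("degenerate dome radii give a plain straight channel", {
  geom <- build_geometry(geometry_params(dome1_radius = 0, dome2_radius = 0))
  expect_equal(sum(geom$sac_mask), 0)
  expect_equal(sum(geom$coil_mask), 0)
  # lumen is exactly the slab
  yc <- coilflow:::cell_centers_y(geom$ny, geom$dx)
  slab <- matrix(rep(yc > geom$y_bot & yc < geom$y_top, each = geom$nx),
                 geom$nx, geom$ny)
  expect_identical(geom$lumen_mask, slab)
})

test_that("wall chain is closed, ordered, unit-normalled and near the zero set", {
  geom <- build_geometry(geometry_params())
  w <- geom$wall
  expect_true(all(abs(sqrt(w$nx^2 + w$ny^2) - 1) < 1e-12))
  expect_true(all(diff(w$s) > 0))
  # every true wall point (not the synthetic inlet/outlet caps) lies
  # within one cell of the zero level set
  sd <- coilflow:::interp_bilinear(geom$sdf, w$x, w$y, geom$dx)
  expect_true(all(abs(sd[!w$on_cap]) < geom$dx))
  # neck endpoints on the zero set within one cell
  sdn <- coilflow:::interp_bilinear(geom$sdf, geom$neck_segment$x,
                                    geom$neck_segment$y, geom$dx)
  expect_true(all(abs(sdn) < geom$dx))
  # total arc length close to the analytic perimeter at moderate resolution
  per <- analytic_lumen_perimeter(geom$params, geom$Lx)
  expect_lt(abs(w$perimeter[1] - per) / per, 0.05)
})

test_that("lumen area converges at first order under grid refinement", {
  errs <- vapply(c(96L, 192L), function(nxk) {
    gp <- geometry_params(grid_nx = nxk, grid_ny = as.integer(nxk * 112 / 192))
    g <- build_geometry(gp)
    abs(sum(g$lumen_mask) * g$dx^2 - analytic_lumen_area(gp, g$Lx))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("coil fill fraction carves the sac from the dome tip", {
  geom <- build_geometry(geometry_params())
  expect_equal(sum(set_coil(geom, 0)$coil_mask), 0)
  full <- set_coil(geom, 1)
  expect_identical(full$coil_mask, geom$sac_mask)
  half <- set_coil(geom, 0.5)
  n_sac <- sum(geom$sac_mask)
  expect_equal(sum(half$coil_mask), round(0.5 * n_sac))
  # coil fills from the distal tip: filled cells have larger axis
  # projection than unfilled sac cells (front is one cell-row thick)
  proj <- function(mask) {
    ij <- which(mask, arr.ind = TRUE)
    (ij[, 1] - 0.5) * geom$dx * geom$sac_axis[1] +
      (ij[, 2] - 0.5) * geom$dx * geom$sac_axis[2]
  }
  filled <- proj(half$coil_mask)
  rest <- proj(geom$sac_mask & !half$coil_mask)
  expect_gt(min(filled), max(rest) - 2 * geom$dx)
  expect_error(set_coil(geom, 1.2), "fill_fraction")
})
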