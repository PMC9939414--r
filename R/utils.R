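# Internal grid helpers shared by geometry, solver and index code.
# Scalar fields are (nx, ny) matrices on cell centers: x_i = (i - 1/2) dx,
# y_j = (j - 1/2) dx, origin at the domain corner.

cell_centers_x <- function(nx, dx) (seq_len(nx) - 0.5) * dx
cell_centers_y <- function(ny, dx) (seq_len(ny) - 0.5) * dx

# Bilinear interpolation of one or more cell-centered fields at arbitrary
# points. Clamps to the outermost cell centers (constant extrapolation in
# the half-cell rim). `field` is an (nx, ny) matrix; x, y vectors.
interp_bilinear <- function(field, x, y, dx) {
  nx <- nrow(field); ny <- ncol(field)
  fx <- x / dx + 0.5  # fractional cell-center index
  fy <- y / dx + 0.5
  i0 <- pmin(pmax(floor(fx), 1), nx - 1)
  j0 <- pmin(pmax(floor(fy), 1), ny - 1)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  f00 <- field[cbind(i0, j0)]
  f10 <- field[cbind(i0 + 1, j0)]
  f01 <- field[cbind(i0, j0 + 1)]
  f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

# Central-difference gradient of a cell-centered field (one-sided at the
# domain rim). Returns list(gx, gy), each (nx, ny).
grad_centered <- function(field, dx) {
  nx <- nrow(field); ny <- ncol(field)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (field[3:nx, ] - field[1:(nx - 2), ]) / (2 * dx)
  gx[1, ] <- (field[2, ] - field[1, ]) / dx
  gx[nx, ] <- (field[nx, ] - field[nx - 1, ]) / dx
  gy[, 2:(ny - 1)] <- (field[, 3:ny] - field[, 1:(ny - 2)]) / (2 * dx)
  gy[, 1] <- (field[, 2] - field[, 1]) / dx
  gy[, ny] <- (field[, ny] - field[, ny - 1]) / dx
  list(gx = gx, gy = gy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
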