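#' Ideal lattice and field fixtures
#'
#' Synthetic rate maps with known structure, used as scoring oracles:
#' hexagonal and square 2D lattices, spherical blobs, ellipsoidal fields,
#' planar slabs and wall-hugging fields. All are generated analytically.
#'
#' @param type lattice symmetry: `"hex"` (three plane waves at 60 degrees)
#'   or `"square"` (two orthogonal plane waves).
#' @param shape grid dims (length 2).
#' @param wavelength plane-wave wavelength in bins.
#' @param angle lattice orientation offset, degrees.
#' @return a `rate_map2d` with uniform occupancy.
#' @export
lattice_map_2d <- function(type = c("hex", "square"), shape = c(41, 41),
                           wavelength = 12, angle = 0) {
  type <- match.arg(type)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]))
  k <- if (type == "hex") 4 * pi / (sqrt(3) * wavelength) else
    2 * pi / wavelength
  dirs <- if (type == "hex") angle + c(0, 60, 120) else angle + c(0, 90)
  rho <- 0
  for (a in dirs) {
    th <- deg2rad(a)
    rho <- rho + cos(k * (g$x * cos(th) + g$y * sin(th)))
  }
  rho <- pmax(rho, 0)
  .as_rate_map(array(rho, shape))
}

#' @rdname lattice_map_2d
#' @param centre blob centre (index units; default grid centre).
#' @param radius blob radius / Gaussian sigma, bins.
#' @export
blob_map_3d <- function(shape = c(41, 41, 41), centre = (shape + 1) / 2,
                        radius = 5) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  .as_rate_map(array(exp(-d2 / (2 * radius^2)), shape))
}

#' @rdname lattice_map_2d
#' @param semi_axes ellipsoid semi-axes in voxels (solid, binary field).
#' @export
ellipsoid_map_3d <- function(shape = c(41, 41, 41),
                             centre = (shape + 1) / 2,
                             semi_axes = c(8, 4, 4)) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  q <- (g$x - centre[1])^2 / semi_axes[1]^2 +
       (g$y - centre[2])^2 / semi_axes[2]^2 +
       (g$z - centre[3])^2 / semi_axes[3]^2
  .as_rate_map(array(as.numeric(q <= 1), shape))
}

#' @rdname lattice_map_2d
#' @param axis slab normal axis (1 = x, 2 = y, 3 = z).
#' @param levels slab centre positions along `axis` (index units).
#' @param thickness slab thickness, voxels.
#' @export
slab_map_3d <- function(shape = c(41, 41, 41), axis = 3, levels = 21,
                        thickness = 3) {
  a <- array(0, shape)
  idx <- slice.index(a, axis)
  for (lv in levels)
    a[abs(idx - lv) <= (thickness - 1) / 2] <- 1
  .as_rate_map(a)
}

#' @rdname lattice_map_2d
#' @param wall which wall the field hugs (`"x0"`, `"x1"`, `"y0"`, `"y1"`).
#' @param depth field depth in bins from the wall.
#' @export
wall_map_2d <- function(shape = c(41, 41), wall = "x0", depth = 1) {
  a <- array(0, shape)
  switch(wall,
         x0 = { a[seq_len(depth), ] <- 1 },
         x1 = { a[shape[1] - seq_len(depth) + 1, ] <- 1 },
         y0 = { a[, seq_len(depth)] <- 1 },
         y1 = { a[, shape[2] - seq_len(depth) + 1] <- 1 },
         stop("unknown wall"))
  .as_rate_map(a)
}
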