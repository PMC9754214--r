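# Primitive 3D geometry for ordered key-point curves. Points travel through
# the package as n x 3 numeric matrices with columns x, y, z (cm).

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = FALSE)
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("points must have 3 columns (x, y, z)")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("points must be finite")
  colnames(p) <- c("x", "y", "z")
  p
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Total least-squares line through 3D points
#'
#' Fits a spatial straight line to a set of points by the principal axis of
#' the centred coordinates (total least squares), which is well defined for
#' any orientation including vertical stalks. The direction is oriented so
#' that it points from the first to the last point of the sequence.
#'
#' @param points An n x 3 matrix (n >= 2) of points.
#' @return A list with components `anchor` (the centroid) and `direction`
#'   (a unit 3-vector).
#' @export
#' @examples
#' fit_line_3d(cbind(0, 0, 0:4))$direction
fit_line_3d <- function(points) {
  p <- .as_points(points)
  if (nrow(p) < 2) stop("fit_line_3d: need at least 2 points")
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  if (max(abs(x)) < 1e-12) stop("fit_line_3d: degenerate geometry, all points coincide")
  dir <- svd(x, nu = 0, nv = 1)$v[, 1]
  span <- p[nrow(p), ] - p[1, ]
  s <- sum(dir * span)
  if (s < 0) {
    dir <- -dir
  } else if (s == 0) {
    # closed/ambiguous sequence: make the sign deterministic
    nz <- which(abs(dir) > 1e-12)[1]
    if (length(nz) && dir[nz] < 0) dir <- -dir
  }
  list(anchor = as.numeric(ctr), direction = as.numeric(dir / .norm3(dir)))
}

#' Minimal rotation aligning one direction with another
#'
#' Rodrigues rotation about `from x to`. The antiparallel case rotates 180
#' degrees about an arbitrary axis perpendicular to `from`.
#'
#' @param from,to Unit 3-vectors.
#' @return A 3 x 3 rotation matrix `R` with `R %*% from == to`.
#' @export
rotation_aligning <- function(from, to) {
  f <- .unit(as.numeric(from))
  t2 <- .unit(as.numeric(to))
  d <- sum(f * t2)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to f
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross3(f, ref))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  v <- .cross3(f, t2)
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + d)
}

#' Rotate points about a centre
#'
#' @param points n x 3 matrix.
#' @param R 3 x 3 rotation matrix.
#' @param center Optional 3-vector; rotation is applied about this point.
#' @return The rotated n x 3 matrix.
#' @export
rotate_points <- function(points, R, center = c(0, 0, 0)) {
  p <- .as_points(points)
  ctr <- as.numeric(center)
  out <- sweep(sweep(p, 2, ctr) %*% t(R), 2, -ctr)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Discrete (Menger) curvature of a point triple
#'
#' Curvature of the circumscribed circle of three points,
#' `4 * area / (|a| |b| |c|)`, in 1/cm. Collinear triples give 0.
#'
#' @param p_prev,p,p_next 3-vectors.
#' @return Non-negative curvature (1/cm).
#' @export
#' @examples
#' menger_curvature(c(10, 0, 0), c(0, 10, 0), c(-10, 0, 0))  # circle r = 10
menger_curvature <- function(p_prev, p, p_next) {
  a <- as.numeric(p) - as.numeric(p_prev)
  b <- as.numeric(p_next) - as.numeric(p)
  cvec <- as.numeric(p_next) - as.numeric(p_prev)
  la <- .norm3(a); lb <- .norm3(b); lc <- .norm3(cvec)
  if (la < 1e-12 || lb < 1e-12) stop("menger_curvature: duplicated points")
  if (lc < 1e-12) return(Inf)  # folded back on itself
  4 * (.norm3(.cross3(a, b)) / 2) / (la * lb * lc)
}

#' Menger curvature along a polyline
#'
#' @param points n x 3 matrix (n >= 3).
#' @return Numeric vector of length n: interior node curvatures, with NA at
#'   the two endpoints.
#' @export
polyline_menger <- function(points) {
  p <- .as_points(points)
  n <- nrow(p)
  if (n < 3) stop("polyline_menger: need at least 3 points")
  out <- rep(NA_real_, n)
  for (i in 2:(n - 1)) out[i] <- menger_curvature(p[i - 1, ], p[i, ], p[i + 1, ])
  out
}

#' Cumulative arc length of a polyline
#'
#' @param points n x 3 matrix.
#' @return Numeric vector of length n, starting at 0 (cm).
#' @export
polyline_arclength <- function(points) {
  p <- .as_points(points)
  if (nrow(p) == 1) return(0)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Intersection of a plane with a polyline
#'
#' Computes every crossing of the polyline through the plane by linear
#' interpolation on sign changes of the signed distance and returns the
#' crossing closest (Euclidean) to `near`. Vertices lying exactly on the
#' plane count as crossings.
#'
#' @param normal Unit 3-vector, the plane normal.
#' @param anchor 3-vector, a point on the plane.
#' @param polyline n x 3 matrix.
#' @param near 3-vector used to select among multiple crossings.
#' @return The crossing point (3-vector), or `NULL` when no segment crosses.
#' @export
plane_polyline_intersection <- function(normal, anchor, polyline, near) {
  p <- .as_points(polyline)
  nrm <- .unit(as.numeric(normal))
  d <- as.numeric((sweep(p, 2, as.numeric(anchor)) %*% nrm))
  n <- nrow(p)
  if (n < 2) return(NULL)
  crossings <- list()
  on_plane <- which(abs(d) < 1e-12)
  for (i in on_plane) crossings[[length(crossings) + 1L]] <- p[i, ]
  d1 <- d[-n]; d2 <- d[-1]
  idx <- which(d1 * d2 < 0)
  for (i in idx) {
    t <- d1[i] / (d1[i] - d2[i])
    crossings[[length(crossings) + 1L]] <- p[i, ] + t * (p[i + 1, ] - p[i, ])
  }
  if (!length(crossings)) return(NULL)
  cr <- do.call(rbind, crossings)
  dist2 <- rowSums(sweep(cr, 2, as.numeric(near))^2)
  as.numeric(cr[which.min(dist2), ])
}

#' Planar azimuth of a 3-vector
#'
#' Angle of the horizontal (x, y) component measured from the +X axis,
#' in degrees in (-180, 180]. Near-vertical vectors (horizontal magnitude
#' below `eps_h`) are undefined and flagged.
#'
#' @param v 3-vector.
#' @param eps_h Minimum horizontal magnitude (cm).
#' @return A list with `angle` (deg or NA) and `defined` (logical).
#' @export
azimuth_xy <- function(v, eps_h = 1e-6) {
  v <- as.numeric(v)
  h <- sqrt(v[1]^2 + v[2]^2)
  if (!is.finite(h) || h < eps_h) return(list(angle = NA_real_, defined = FALSE))
  a <- atan2(v[2], v[1]) * 180 / pi
  if (a <= -180) a <- a + 360
  list(angle = a, defined = TRUE)
}

# wrap an angle difference (deg) into (-180, 180]
.wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a <= -180] <- a[a <= -180] + 360
  a
}
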