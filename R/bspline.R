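# Uniform cubic B-spline machinery. A key segment P_m -> P_{m+1} is governed
# by the control window (P_{m-1}, P_m, P_{m+1}, P_{m+2}) with reflected phantom
# endpoints at the boundary; local parameter t runs over [0, 1] within the segment.

#' Cubic B-spline basis weights
#'
#' The four uniform cubic B-spline basis functions
#' \deqn{F_0 = (1-t)^3/6,\; F_1 = (3t^3-6t^2+4)/6,\;
#'       F_2 = (-3t^3+3t^2+3t+1)/6,\; F_3 = t^3/6,}
#' a partition of unity with non-negative weights on \eqn{t \in [0,1]}.
#'
#' @param t Numeric vector of local parameters in `[0, 1]`.
#' @return A `length(t)` x 4 matrix of weights.
#' @export
#' @examples
#' bspline_basis(0)   # (1/6, 4/6, 1/6, 0)
#' rowSums(bspline_basis(runif(5)))
bspline_basis <- function(t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > 1 + 1e-12)) {
    stop("bspline_basis: t must lie in [0, 1]")
  }
  t <- pmin(pmax(t, 0), 1)
  cbind(
    F0 = (1 - t)^3 / 6,
    F1 = (3 * t^3 - 6 * t^2 + 4) / 6,
    F2 = (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
    F3 = t^3 / 6
  )
}

# first and second derivatives of the basis with respect to t
.bspline_basis_d1 <- function(t) {
  cbind(-(1 - t)^2 / 2,
        (9 * t^2 - 12 * t) / 6,
        (-9 * t^2 + 6 * t + 3) / 6,
        t^2 / 2)
}

.bspline_basis_d2 <- function(t) {
  cbind(1 - t, 3 * t - 2, -3 * t + 1, t)
}

# extended control polygon with reflected phantom endpoints
# (P_0 = 2 P_1 - P_2, P_{n+1} = 2 P_n - P_{n-1}): the spline then starts and
# ends exactly at the data endpoints (natural end condition) instead of
# jumping to the replicated-window average
.extend_controls <- function(p) {
  n <- nrow(p)
  rbind(2 * p[1, ] - p[2, ], p, 2 * p[n, ] - p[n - 1, ])
}

# control window rows (in the extended polygon) for segment m = 1..n-1
.window_index <- function(m, n) {
  cbind(m, m + 1L, m + 2L, m + 3L)
}

#' Analytic curvature of a cubic B-spline window
#'
#' Curvature \eqn{\kappa(t) = |r' \times r''| / |r'|^3} of the spline piece
#' defined by a 4-point control window, from the component-wise cubic
#' polynomials and their derivatives. Degenerate parameterizations
#' (`|r'| < 1e-12`) return 0 with a flag.
#'
#' @param window A 4 x 3 matrix of control points.
#' @param t Numeric vector of local parameters in `[0, 1]`.
#' @return A list with `kappa` (1/cm, same length as `t`) and `degenerate`
#'   (logical vector).
#' @export
bspline_curvature <- function(window, t) {
  w <- .as_points(window)
  if (nrow(w) != 4) stop("bspline_curvature: window must have 4 control points")
  d1 <- .bspline_basis_d1(t) %*% w
  d2 <- .bspline_basis_d2(t) %*% w
  cx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  cy <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  cz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  num <- sqrt(cx^2 + cy^2 + cz^2)
  sp2 <- rowSums(d1^2)
  degen <- sp2 < 1e-24
  kappa <- ifelse(degen, 0, num / sp2^1.5)
  list(kappa = as.numeric(kappa), degenerate = degen)
}

#' Evaluate a cubic B-spline window at given parameters
#'
#' @param window 4 x 3 control matrix.
#' @param t Parameters in `[0, 1]`.
#' @return `length(t)` x 3 matrix of spline points.
#' @export
bspline_point <- function(window, t) {
  w <- .as_points(window)
  out <- bspline_basis(t) %*% w
  colnames(out) <- c("x", "y", "z")
  out
}

#' Densify a key-point polyline with a local cubic B-spline
#'
#' For every key segment the spline is evaluated at `t = g/(c+1)`,
#' `g = 1..c`, using the segment's control window, and the evaluated nodes
#' are interleaved with the original key points, giving
#' `n + (n-1) * c` dense nodes for `n` key points. Per-node analytic
#' curvature, cumulative arc length, and the map back to the owning key
#' point are populated.
#'
#' @param points n x 3 matrix of key points (n >= 2; windows at the ends
#'   use reflected phantom endpoints, so the spline interpolates the base
#'   and tip).
#' @param c Number of interpolated nodes per segment.
#' @return An object of class `"midrib_curve"`: a list with `points`
#'   (dense nodes), `curvature` (1/cm), `arclength` (cm), `owner` (index of
#'   the owning key point), `is_key` (logical), `segment`, `t_local`, and
#'   `n_key`.
#' @export
#' @examples
#' L1 <- cbind(seq(0, 24, by = 4), 0, 0)
#' dc <- bspline_smooth(L1)
#' nrow(dc$points)  # 7 + 6 * 30
bspline_smooth <- function(points, c = 30L) {
  p <- .as_points(points)
  n <- nrow(p)
  c <- as.integer(c)
  if (n < 2) stop("bspline_smooth: need at least 2 key points")
  if (c < 1) stop("bspline_smooth: c must be >= 1")
  nseg <- n - 1L
  tg <- seq_len(c) / (c + 1)
  B <- bspline_basis(tg)
  n_dense <- n + nseg * c
  pts <- matrix(NA_real_, n_dense, 3)
  kap <- numeric(n_dense)
  owner <- integer(n_dense)
  is_key <- logical(n_dense)
  segment <- integer(n_dense)
  t_loc <- numeric(n_dense)

  key_pos <- (seq_len(n) - 1L) * (c + 1L) + 1L
  pts[key_pos, ] <- p
  is_key[key_pos] <- TRUE
  owner[key_pos] <- seq_len(n)
  segment[key_pos] <- pmin(seq_len(n), nseg)
  t_loc[key_pos] <- c(rep(0, n - 1L), 1)

  pext <- .extend_controls(p)
  win <- .window_index(seq_len(nseg), n)
  for (m in seq_len(nseg)) {
    w <- pext[win[m, ], , drop = FALSE]
    rows <- key_pos[m] + seq_len(c)
    pts[rows, ] <- B %*% w
    kv <- bspline_curvature(w, tg)
    kap[rows] <- kv$kappa
    owner[rows] <- ifelse(seq_len(c) <= (c + 1) / 2, m, m + 1L)
    segment[rows] <- m
    t_loc[rows] <- tg
  }
  # curvature at the interleaved key nodes: spline curvature at the segment
  # boundary parameter
  for (m in seq_len(n)) {
    sm <- if (m < n) m else nseg
    tt <- if (m < n) 0 else 1
    kap[key_pos[m]] <- bspline_curvature(pext[win[sm, ], , drop = FALSE], tt)$kappa
  }
  colnames(pts) <- c("x", "y", "z")
  structure(list(
    points = pts, curvature = kap, arclength = polyline_arclength(pts),
    owner = owner, is_key = is_key, segment = segment, t_local = t_loc,
    n_key = n, c = c
  ), class = "midrib_curve")
}

#' @export
print.midrib_curve <- function(x, ...) {
  cat("Dense midrib curve: ", nrow(x$points), " nodes (", x$n_key,
      " key points, c = ", x$c, ")\n", sep = "")
  cat(sprintf("  arc length %.2f cm, max curvature %.4g 1/cm\n",
              max(x$arclength), max(x$curvature)))
  invisible(x)
}
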