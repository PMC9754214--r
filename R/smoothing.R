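# The correction pipeline for digitized key points: stalk-axis alignment,
# broken-midrib QC, equidistant interpolation, and the curvature-constrained
# iterative cubic B-spline smoother.

#' Correct the positive (growth) direction of a sample
#'
#' Fits a total least-squares line to the stalk key points and rotates the
#' whole sample (stalk and midrib together) about the stalk centroid so that
#' the fitted stalk axis coincides with +Z.
#'
#' @param sample A `midrib_sample` (see [midrib_sample()]).
#' @return The sample with rotated `stalk` and `midrib` matrices; the refit
#'   stalk direction is `(0, 0, 1)` to within 1e-6.
#' @export
correct_positive_direction <- function(sample) {
  stopifnot(inherits(sample, "midrib_sample"))
  fit <- fit_line_3d(sample$stalk)
  dir <- fit$direction
  # the growth axis points up regardless of acquisition order (a stalk file
  # recorded top-to-bottom must give the same corrected frame); plants are
  # never tilted past horizontal, so the sign of the z component decides
  if (dir[3] < 0) dir <- -dir
  R <- rotation_aligning(dir, c(0, 0, 1))
  sample$stalk <- rotate_points(sample$stalk, R, fit$anchor)
  sample$midrib <- rotate_points(sample$midrib, R, fit$anchor)
  sample
}

#' Broken-midrib quality control
#'
#' Flags midribs whose raw node (Menger) curvature exceeds the threshold,
#' indicating a snapped and manually repaired midrib. The test runs on raw
#' key points, before any interpolation or smoothing; the inequality is
#' strict.
#'
#' @param midrib_points n x 3 matrix of raw midrib key points (n >= 3).
#' @param broken_thre Curvature threshold (1/cm), default 0.2.
#' @return A list with `is_broken`, `worst_kappa` (1/cm) and `worst_index`.
#' @export
detect_broken <- function(midrib_points, broken_thre = 0.2) {
  kappa <- polyline_menger(midrib_points)
  worst <- which.max(kappa)
  list(is_broken = isTRUE(kappa[worst] > broken_thre),
       worst_kappa = as.numeric(kappa[worst]),
       worst_index = as.integer(worst))
}

#' Equidistant interpolation of key points
#'
#' Inserts `N = ceiling(Dm / D_b) - 1` linearly interpolated points at
#' uniform fractions into every raw segment of length `Dm`, so that no
#' segment exceeds `D_b`. Original points are retained and flagged;
#' zero-length raw segments are dropped with a warning.
#'
#' @param points n x 3 matrix of key points (n >= 2).
#' @param D_b Target spacing (cm), default 4.
#' @return A list with `points` (the densified key polyline) and `original`
#'   (logical flags).
#' @export
#' @examples
#' eq <- equidistant_interpolate(rbind(c(0, 0, 0), c(10, 0, 0)), D_b = 4)
#' eq$points[, 1]  # inserted at fractions 1/3 and 2/3
equidistant_interpolate <- function(points, D_b = 4.0) {
  p <- .as_points(points)
  if (nrow(p) < 2) stop("equidistant_interpolate: need at least 2 points")
  if (D_b <= 0) stop("equidistant_interpolate: D_b must be positive")
  out <- list(p[1, ])
  flag <- TRUE
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    Dm <- .norm3(b - a)
    if (Dm < 1e-9) {
      warning("equidistant_interpolate: dropping zero-length segment at row ", i)
      next
    }
    N <- ceiling(Dm / D_b) - 1
    if (N > 0) {
      fr <- seq_len(N) / (N + 1)
      for (f in fr) {
        out[[length(out) + 1L]] <- a + f * (b - a)
        flag <- c(flag, FALSE)
      }
    }
    out[[length(out) + 1L]] <- b
    flag <- c(flag, TRUE)
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, original = flag)
}

#' Curvature-constrained iterative B-spline smoothing
#'
#' The global smoothing stage. Each iteration (i) densifies the current key
#' points with [bspline_smooth()]; (ii) flags dense nodes whose analytic
#' curvature exceeds `kappa_thre` and maps them to their owning key points
#' (endpoints excluded); (iii) for each flagged key point builds the
#' correction plane through the midpoint of its two neighbouring key points
#' with normal along their chord, and moves the key point to the crossing of
#' the smoothed curve with that plane nearest to its current position
#' (orthogonal projection onto the plane when the curve does not cross).
#' One safeguard keeps the correction from degrading clean geometry: a
#' point is only moved when its displacement perpendicular to the local
#' chord exceeds the natural sag `kappa * h^2 / 6` that a noise-free arc of
#' the local large-scale curvature would show against a uniform B-spline —
#' snapping such points too would contract every genuinely curved midrib
#' toward its chord, iteration after iteration. Iterations continue until
#' no node is flagged, no point moves, or `max_iter` is reached. The first
#' and last key points are never modified.
#'
#' @param L1 Either the list returned by [equidistant_interpolate()] or an
#'   n x 3 matrix of key points (all treated as measured).
#' @param control A [midrib_control()] list.
#' @return A list with `key_points` (the corrected key polyline),
#'   `original` (provenance flags carried through from `L1`), `dense` (the
#'   final `midrib_curve`), and `report` (`n_iterations`, `converged`,
#'   `stalled`, `flagged_per_iteration`, `max_curvature_per_iteration`,
#'   `max_curvature_final`).
#' @export
ciscb_smooth <- function(L1, control = midrib_control()) {
  control <- as_midrib_control(control)
  if (is.list(L1) && !is.null(L1$points)) {
    key <- .as_points(L1$points)
    original <- if (!is.null(L1$original)) L1$original else rep(TRUE, nrow(key))
  } else {
    key <- .as_points(L1)
    original <- rep(TRUE, nrow(key))
  }
  n <- nrow(key)
  if (n < 2) stop("ciscb_smooth: need at least 2 key points")

  # interpolation parents: for every node, the enclosing measured nodes and
  # the chord fraction; when a measured node is corrected, its chord's
  # interpolated children follow with the interpolation-weighted share of
  # the displacement, so the chord stops remembering the old position
  orig_idx <- which(original)
  k <- findInterval(seq_len(n), orig_idx)
  prev_orig <- orig_idx[pmax(k, 1L)]
  next_orig <- orig_idx[pmin(k + 1L, length(orig_idx))]
  next_orig[original] <- prev_orig[original]
  frac <- ifelse(original, 0,
                 (seq_len(n) - prev_orig) / pmax(next_orig - prev_orig, 1L))

  flagged_keys <- function(dense) {
    hot <- dense$curvature > control$kappa_thre
    keys <- sort(unique(dense$owner[hot]))
    keys[keys > 1L & keys < n]
  }

  correct_once <- function(key, dense, flags) {
    smooth_poly <- dense$points[!dense$is_key, , drop = FALSE]
    newkey <- key
    moved <- FALSE
    for (j in flags) {
      normal <- key[j + 1L, ] - key[j - 1L, ]
      if (.norm3(normal) < 1e-12) next
      normal <- normal / .norm3(normal)
      anchor <- (key[j - 1L, ] + key[j + 1L, ]) / 2
      hit <- plane_polyline_intersection(normal, anchor, smooth_poly, key[j, ])
      if (is.null(hit)) {
        # no crossing: orthogonal projection onto the plane
        hit <- key[j, ] - sum((key[j, ] - anchor) * normal) * normal
      }
      # a clean key point on a curved midrib sits about kappa*h^2/6 off the
      # uniform B-spline (the spline sag); only displacements beyond that
      # natural offset are digitizing error, so smaller ones are kept --
      # snapping them too would contract every genuinely curved arc toward
      # its chord, iteration after iteration
      h <- (.norm3(key[j, ] - key[j - 1L, ]) + .norm3(key[j + 1L, ] - key[j, ])) / 2
      jm <- max(1L, j - 4L); jp <- min(n, j + 4L)
      kl <- tryCatch(menger_curvature(key[jm, ], key[j, ], key[jp, ]),
                     error = function(e) 0)
      if (!is.finite(kl)) kl <- 0
      deadband <- max(1.5 * kl * h^2 / 6, 0.02)
      # only the displacement component perpendicular to the local chord is
      # digitizing error; the tangential part is mere reparametrization
      disp <- key[j, ] - hit
      perp <- disp - sum(disp * normal) * normal
      if (.norm3(perp) > deadband) {
        newkey[j, ] <- hit
        moved <- TRUE
      }
    }
    # interpolated children follow their parents, but only for gross
    # corrections (a mis-digitized chord): routine sub-centimetre noise
    # corrections leave the chord anchors frozen, which keeps the iteration
    # from drifting curved regions inward collectively
    if (moved) {
      delta <- newkey - key
      gross <- sqrt(rowSums(delta^2)) >= 1
      delta[!gross, ] <- 0
      if (any(gross)) {
        for (j in which(!original)) {
          if (any(newkey[j, ] != key[j, ])) next
          shift <- (1 - frac[j]) * delta[prev_orig[j], ] + frac[j] * delta[next_orig[j], ]
          newkey[j, ] <- newkey[j, ] + shift
        }
      }
    }
    list(key = newkey, moved = moved)
  }

  dense <- bspline_smooth(key, control$c)
  flags <- flagged_keys(dense)
  flag_hist <- integer(0)
  maxk_hist <- numeric(0)
  n_iter <- 0L
  stalled <- FALSE
  while (length(flags) > 0L && n_iter < control$max_iter) {
    flag_hist <- c(flag_hist, length(flags))
    maxk_hist <- c(maxk_hist, max(dense$curvature))
    cand <- correct_once(key, dense, flags)
    if (!cand$moved) {
      # every flagged point sits within its natural-sag deadband: the key
      # points are already consistent with the smooth curve
      stalled <- TRUE
      break
    }
    key <- cand$key
    dense <- bspline_smooth(key, control$c)
    n_iter <- n_iter + 1L
    flags <- flagged_keys(dense)
  }
  report <- list(
    n_iterations = n_iter,
    converged = length(flags) == 0L,
    stalled = stalled,
    flagged_per_iteration = flag_hist,
    max_curvature_per_iteration = maxk_hist,
    max_curvature_final = max(dense$curvature)
  )
  list(key_points = key, original = original, dense = dense, report = report)
}
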