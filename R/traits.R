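# Direction-plane normalization and the fifteen midrib shape traits.
#
# Traits are computed on the dense smoothed curve expressed in a canonical
# frame: base at the origin, growth axis +Z, main midrib plane XOZ with the
# tip at x >= 0.

#' Names of the fifteen midrib traits
#'
#' In the fixed column order used throughout the package: `TipTop` (0/1,
#' tip droops below the highest point), `LeafLength` (cm), `LeafAngle` (deg),
#' `HorizontalLength` (cm), `OutwardGrowthMeasure` and `UpwardGrowthMeasure`
#' (ratios), `VerticalHeight` (cm), `CurvaturePos` (ratio), `CurvatureRatio`
#' (chord/arc straightness), `DeviationAngle` (deg), `DeviationTip` (ratio),
#' `MaxCurvature` (1/cm), `MaxWindingRate` (deg/cm), `WindingRatePos`
#' (ratio), `ProjectionArea` (cm^2).
#'
#' @return Character vector of length 15.
#' @export
trait_names <- function() {
  c("TipTop", "LeafLength", "LeafAngle", "HorizontalLength",
    "OutwardGrowthMeasure", "UpwardGrowthMeasure", "VerticalHeight",
    "CurvaturePos", "CurvatureRatio", "DeviationAngle", "DeviationTip",
    "MaxCurvature", "MaxWindingRate", "WindingRatePos", "ProjectionArea")
}

#' Normalize the midrib direction plane
#'
#' Assumes the growth direction has already been corrected to +Z. Translates
#' the base to the origin, fits a total least-squares line to the XY
#' projections of all nodes, and rotates about Z so that line maps onto the
#' X axis, with the sign chosen so the tip lands at x >= 0. Near-vertical
#' leaves (horizontal extent below `min_horizontal`) keep the identity
#' rotation and are flagged degenerate.
#'
#' @param curve A `midrib_curve`, or an n x 3 matrix of curve nodes (in
#'   which case per-node curvature is taken as discrete Menger curvature).
#' @param min_horizontal Degeneracy threshold (cm), default 1.
#' @return A `midrib_curve` in the canonical frame with extra fields
#'   `degenerate_plane` (logical) and `rotation_z` (deg applied).
#' @export
normalize_direction_plane <- function(curve, min_horizontal = 1.0) {
  cv <- .as_curve(curve)
  p <- cv$points
  if (nrow(p) < 2) stop("normalize_direction_plane: need at least 2 nodes")
  p <- sweep(p, 2, p[1, ])
  hor <- sqrt(p[, 1]^2 + p[, 2]^2)
  degenerate <- max(hor) < min_horizontal
  ang <- 0
  if (!degenerate) {
    xy <- p[, 1:2, drop = FALSE]
    xy_c <- sweep(xy, 2, colMeans(xy))
    dir2 <- svd(xy_c, nu = 0, nv = 1)$v[, 1]
    ang <- -atan2(dir2[2], dir2[1])
    R <- matrix(c(cos(ang), sin(ang), 0,
                  -sin(ang), cos(ang), 0,
                  0, 0, 1), 3, 3)
    p <- p %*% t(R)
    if (p[nrow(p), 1] < 0) {
      p[, 1] <- -p[, 1]
      p[, 2] <- -p[, 2]
      ang <- ang + pi
    }
  }
  colnames(p) <- c("x", "y", "z")
  cv$points <- p
  cv$arclength <- polyline_arclength(p)
  cv$degenerate_plane <- degenerate
  cv$rotation_z <- ang * 180 / pi
  cv
}

# accept a midrib_curve or a bare matrix (then curvature = Menger)
.as_curve <- function(curve) {
  if (inherits(curve, "midrib_curve")) return(curve)
  p <- .as_points(curve)
  kap <- if (nrow(p) >= 3) {
    k <- polyline_menger(p)
    k[is.na(k)] <- 0
    k
  } else {
    rep(0, nrow(p))
  }
  structure(list(points = p, curvature = kap,
                 arclength = polyline_arclength(p),
                 owner = seq_len(nrow(p)), is_key = rep(TRUE, nrow(p)),
                 segment = pmin(seq_len(nrow(p)), nrow(p) - 1L),
                 t_local = rep(0, nrow(p)), n_key = nrow(p), c = 0L),
            class = "midrib_curve")
}

# node index at (or just past) a given arc length
.node_at_arclength <- function(arclength, s) {
  i <- which(arclength >= s - 1e-9)[1]
  if (is.na(i)) length(arclength) else max(i, 2L)
}

#' Extent traits of a normalized curve
#'
#' Computes `LeafLength` (total arc length S), `VerticalHeight` (z of the
#' first highest node), `HorizontalLength` (maximum horizontal distance from
#' the base over all nodes), `LeafAngle` (angle between +Z and the chord from
#' the base to the node at arc length `min(s_angle, 0.1 S)`),
#' `UpwardGrowthMeasure` = VerticalHeight/S, `OutwardGrowthMeasure` =
#' HorizontalLength/S, `TipTop` (1 when the tip lies more than `epsilon_z`
#' below the highest node), and `DeviationTip` = (S - s(highest))/S.
#'
#' @param n A normalized `midrib_curve`.
#' @param control A [midrib_control()] list.
#' @return Named list of the eight values.
#' @export
compute_extent_traits <- function(n, control = midrib_control()) {
  control <- as_midrib_control(control)
  p <- n$points
  s <- n$arclength
  S <- s[length(s)]
  if (S < 1e-6) stop("compute_extent_traits: degenerate curve (zero length)")
  i_star <- which.max(p[, 3])  # first occurrence on ties
  vertical <- p[i_star, 3]
  horizontal <- max(sqrt(p[, 1]^2 + p[, 2]^2))
  tip_drop <- vertical - p[nrow(p), 3]
  tiptop <- as.numeric(tip_drop > control$epsilon_z)
  dev_tip <- (S - s[i_star]) / S
  i_a <- .node_at_arclength(s, min(control$s_angle, 0.1 * S))
  chord <- p[i_a, ] - p[1, ]
  leaf_angle <- as.numeric(
    acos(pmin(pmax(chord[3] / .norm3(chord), -1), 1)) * 180 / pi)
  list(LeafLength = S,
       LeafAngle = leaf_angle,
       HorizontalLength = horizontal,
       OutwardGrowthMeasure = min(horizontal / S, 1),
       UpwardGrowthMeasure = min(max(vertical, 0) / S, 1),
       VerticalHeight = vertical,
       TipTop = tiptop,
       DeviationTip = dev_tip)
}

#' Curvature traits of a normalized curve
#'
#' `MaxCurvature` is the largest per-node curvature, `CurvaturePos` its arc
#' position as a fraction of total length (first index on ties), and
#' `CurvatureRatio` the base-to-tip chord length over the arc length
#' (1 = perfectly straight).
#'
#' @param n A normalized `midrib_curve`.
#' @return Named list of the three values.
#' @export
compute_curvature_traits <- function(n) {
  p <- n$points
  s <- n$arclength
  S <- s[length(s)]
  kap <- n$curvature
  i_max <- which.max(kap)
  chord <- .norm3(p[nrow(p), ] - p[1, ])
  list(MaxCurvature = as.numeric(kap[i_max]),
       CurvaturePos = s[i_max] / S,
       CurvatureRatio = min(chord / S, 1))
}

#' Deviation and winding traits of a normalized curve
#'
#' `DeviationAngle` is the absolute azimuth of the basal chord (base to the
#' node at arc length `min(s_angle, 0.1 S)`) relative to the fitted main
#' plane (the X axis after normalization); 0 when the chord is near
#' vertical. The winding rate at an interior node is the absolute wrapped
#' azimuth change between its two adjacent segment projections divided by
#' the local arc step (deg/cm), evaluated only where both segments have
#' horizontal magnitude >= 1e-3 cm; `MaxWindingRate` is its maximum and
#' `WindingRatePos` the arc position of that maximum (both 0 when no valid
#' segment pair exists).
#'
#' @param n A normalized `midrib_curve`.
#' @param control A [midrib_control()] list.
#' @return Named list of the three values.
#' @export
compute_deviation_traits <- function(n, control = midrib_control()) {
  control <- as_midrib_control(control)
  p <- n$points
  s <- n$arclength
  S <- s[length(s)]
  i_a <- .node_at_arclength(s, min(control$s_angle, 0.1 * S))
  az <- azimuth_xy(p[i_a, ] - p[1, ])
  deviation <- if (az$defined) abs(az$angle) else 0

  # winding is evaluated on the key-point chords (the digitizing scale);
  # sub-centimetre dense segments would divide tiny azimuth flips by tiny
  # arc steps and explode
  keyi <- if (!is.null(n$is_key)) which(n$is_key) else seq_len(nrow(p))
  kp <- p[keyi, , drop = FALSE]
  ks <- s[keyi]
  npk <- nrow(kp)
  max_rate <- 0; pos <- 0
  if (npk >= 3) {
    seg <- kp[-1, , drop = FALSE] - kp[-npk, , drop = FALSE]
    hmag <- sqrt(seg[, 1]^2 + seg[, 2]^2)
    segaz <- atan2(seg[, 2], seg[, 1]) * 180 / pi
    ds <- (ks[-(1:2)] - ks[1:(npk - 2)]) / 2  # half-span at interior node i
    ok <- hmag[-length(hmag)] >= 1e-3 & hmag[-1] >= 1e-3 & ds > 1e-9
    if (any(ok)) {
      turn <- abs(.wrap_angle(segaz[-1] - segaz[-length(segaz)]))
      rate <- ifelse(ok, turn / ds, -Inf)
      i_w <- which.max(rate)
      if (rate[i_w] > 0) {
        max_rate <- rate[i_w]
        pos <- ks[i_w + 1L] / S
      }
    }
  }
  list(DeviationAngle = deviation, MaxWindingRate = max_rate,
       WindingRatePos = pos)
}

#' Projected occupied area of a normalized curve
#'
#' Absolute shoelace area of the polygon formed by the (x, z) main-plane
#' projection of the curve nodes, closed by the straight chord from tip
#' back to base (cm^2). Collinear curves give 0.
#'
#' @param n A normalized `midrib_curve` with at least 3 nodes.
#' @return Area in cm^2.
#' @export
compute_projection_area <- function(n) {
  p <- n$points
  if (nrow(p) < 3) stop("compute_projection_area: need at least 3 nodes")
  x <- p[, 1]; z <- p[, 3]
  abs(sum(x * c(z[-1], z[1]) - c(x[-1], x[1]) * z)) / 2
}

#' Compute the full fifteen-trait vector
#'
#' Aggregates [compute_extent_traits()], [compute_curvature_traits()],
#' [compute_deviation_traits()] and [compute_projection_area()] and enforces
#' the trait invariants (ratios clamped to `[0, 1]`).
#'
#' @param n A normalized `midrib_curve`.
#' @param control A [midrib_control()] list.
#' @return A named numeric vector over [trait_names()], with attribute
#'   `degenerate_plane`.
#' @export
compute_traits <- function(n, control = midrib_control()) {
  control <- as_midrib_control(control)
  ext <- compute_extent_traits(n, control)
  cur <- compute_curvature_traits(n)
  dev <- compute_deviation_traits(n, control)
  area <- compute_projection_area(n)
  v <- c(ext, cur, dev, list(ProjectionArea = area))
  out <- vapply(trait_names(), function(nm) as.numeric(v[[nm]]), numeric(1))
  ratio_traits <- c("OutwardGrowthMeasure", "UpwardGrowthMeasure",
                    "CurvaturePos", "CurvatureRatio", "DeviationTip",
                    "WindingRatePos")
  out[ratio_traits] <- pmin(pmax(out[ratio_traits], 0), 1)
  attr(out, "degenerate_plane") <- isTRUE(n$degenerate_plane)
  out
}
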