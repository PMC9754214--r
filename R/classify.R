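# Seven-type architectural classification of midrib curves: six mutually
# exclusive base types plus an independent deflection flag.

#' Base-type labels
#' @return Character vector of the six base types in rule-priority order.
#' @export
midrib_types <- function() {
  c("drooping", "creeping", "vertical", "tip_curved", "bending", "stretch")
}

#' Classify a midrib curve
#'
#' The deflection flag is `DeviationAngle > deflection_thre` (strict; the
#' deflection type can co-occur with any base type). The base type is the
#' first matching rule, in priority order:
#' \enumerate{
#'   \item drooping: the tip lies more than `epsilon_z` below the base;
#'   \item creeping: `VerticalHeight < h_creep`;
#'   \item vertical: `LeafAngle < theta_vertical` and
#'     `CurvatureRatio >= straight_base_thre`;
#'   \item tip_curved: `TipTop == 1` and the chord/arc straightness of the
#'     base-to-highest-point sub-curve is `>= straight_base_thre`;
#'   \item bending: `MaxCurvature > kappa_bend` or
#'     `CurvatureRatio < ratio_bend`;
#'   \item stretch: otherwise.
#' }
#'
#' @param traits Named trait vector from [compute_traits()].
#' @param n The normalized `midrib_curve` the traits came from.
#' @param control A [midrib_control()] list (thresholds).
#' @return A list with `base_type` (character) and `deflected` (logical).
#' @export
classify_midrib <- function(traits, n, control = midrib_control()) {
  control <- as_midrib_control(control)
  p <- n$points
  deflected <- isTRUE(traits[["DeviationAngle"]] > control$deflection_thre)
  tip_below_base <- (p[nrow(p), 3] - p[1, 3]) < -control$epsilon_z

  base_straightness <- {
    i_star <- which.max(p[, 3])
    s <- n$arclength
    if (i_star > 1 && s[i_star] > 1e-9) {
      min(.norm3(p[i_star, ] - p[1, ]) / s[i_star], 1)
    } else {
      1
    }
  }

  base_type <-
    if (tip_below_base) {
      "drooping"
    } else if (traits[["VerticalHeight"]] < control$h_creep) {
      "creeping"
    } else if (traits[["LeafAngle"]] < control$theta_vertical &&
               traits[["CurvatureRatio"]] >= control$straight_base_thre) {
      "vertical"
    } else if (traits[["TipTop"]] == 1 &&
               base_straightness >= control$straight_base_thre) {
      "tip_curved"
    } else if (traits[["MaxCurvature"]] > control$kappa_bend ||
               traits[["CurvatureRatio"]] < control$ratio_bend) {
      "bending"
    } else {
      "stretch"
    }
  list(base_type = base_type, deflected = deflected)
}

#' Tabulate classifications over a trait table
#'
#' @param rows A data.frame with at least `base_type` and `deflected`
#'   columns (invalid rows, `valid == FALSE`, are dropped when a `valid`
#'   column is present); an optional `subgroup` column yields a cross-tab.
#' @return A list with `counts` and `proportions` (named over the six base
#'   types), `deflected_fraction`, `n`, and optionally `by_subgroup`.
#' @export
classify_batch <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("classify_batch: need at least one row")
  }
  if ("valid" %in% names(rows)) rows <- rows[!is.na(rows$valid) & rows$valid, , drop = FALSE]
  if (nrow(rows) == 0) stop("classify_batch: no valid rows")
  lv <- midrib_types()
  bt <- factor(rows$base_type, levels = lv)
  counts <- table(bt)
  out <- list(
    counts = as.integer(counts),
    proportions = as.numeric(counts) / nrow(rows),
    deflected_fraction = mean(rows$deflected, na.rm = TRUE),
    n = nrow(rows)
  )
  names(out$counts) <- lv
  names(out$proportions) <- lv
  if ("subgroup" %in% names(rows)) {
    out$by_subgroup <- table(rows$subgroup, bt)
  }
  out
}
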