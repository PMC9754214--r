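#' Control parameters for the midrib processing pipeline
#'
#' Collects every tunable parameter of the correction, smoothing, trait and
#' classification stages in one validated list, in the spirit of
#' [stats::glm.control()]. All lengths are in centimetres, curvatures in 1/cm,
#' angles in degrees.
#'
#' @param D_b Target key-point spacing after equidistant interpolation (cm).
#' @param c Number of B-spline interpolation nodes inserted per key segment.
#' @param kappa_thre Dense-node curvature threshold (1/cm) above which a node
#'   is flagged for iterative correction.
#' @param max_iter Cap on the number of correction iterations.
#' @param broken_thre Raw node (Menger) curvature (1/cm) above which a sample
#'   is rejected as a broken midrib.
#' @param epsilon_z Vertical tolerance (cm) used when deciding whether the
#'   leaf tip droops below the highest point (or below the base).
#' @param s_angle Chord length (cm) used for the basal leaf-angle and
#'   deviation-angle measurements; the chord actually used runs to arc length
#'   `min(s_angle, 0.1 * LeafLength)`.
#' @param min_horizontal Horizontal extent (cm) below which a leaf is treated
#'   as vertical and direction-plane normalization degenerates to identity.
#' @param deflection_thre Deviation angle (deg) above which a midrib is
#'   flagged as deflected.
#' @param h_creep Vertical height (cm) below which a midrib is classified as
#'   creeping.
#' @param theta_vertical Leaf angle (deg) below which a straight midrib is
#'   classified as vertical.
#' @param straight_base_thre Chord/arc straightness ratio used by the vertical
#'   and tip-curved rules.
#' @param kappa_bend Maximum-curvature threshold (1/cm) for the bending rule.
#' @param ratio_bend Whole-curve straightness below which a midrib is bending.
#'
#' @return A list of class `"midrib_control"`.
#' @export
#' @examples
#' ctrl <- midrib_control(c = 10)
#' ctrl$kappa_thre
midrib_control <- function(D_b = 4.0,
                           c = 30L,
                           kappa_thre = 0.004,
                           max_iter = 20L,
                           broken_thre = 0.2,
                           epsilon_z = 0.1,
                           s_angle = 5.0,
                           min_horizontal = 1.0,
                           deflection_thre = 10.0,
                           h_creep = 12.0,
                           theta_vertical = 25.0,
                           straight_base_thre = 0.95,
                           kappa_bend = 0.05,
                           ratio_bend = 0.75) {
  ctrl <- list(
    D_b = as.numeric(D_b), c = as.integer(c),
    kappa_thre = as.numeric(kappa_thre), max_iter = as.integer(max_iter),
    broken_thre = as.numeric(broken_thre), epsilon_z = as.numeric(epsilon_z),
    s_angle = as.numeric(s_angle), min_horizontal = as.numeric(min_horizontal),
    deflection_thre = as.numeric(deflection_thre), h_creep = as.numeric(h_creep),
    theta_vertical = as.numeric(theta_vertical),
    straight_base_thre = as.numeric(straight_base_thre),
    kappa_bend = as.numeric(kappa_bend), ratio_bend = as.numeric(ratio_bend)
  )
  pos <- c("D_b", "kappa_thre", "broken_thre", "epsilon_z", "s_angle",
           "deflection_thre", "h_creep", "theta_vertical",
           "straight_base_thre", "kappa_bend", "ratio_bend")
  for (nm in pos) {
    if (!is.finite(ctrl[[nm]]) || ctrl[[nm]] <= 0) {
      stop("midrib_control: '", nm, "' must be a positive finite number")
    }
  }
  if (ctrl$c < 1L) stop("midrib_control: 'c' must be >= 1")
  if (ctrl$max_iter < 1L) stop("midrib_control: 'max_iter' must be >= 1")
  structure(ctrl, class = "midrib_control")
}

#' Merge user-supplied values into a control object
#'
#' @param control An existing `midrib_control` list or NULL.
#' @param ... Named values overriding individual parameters.
#' @return A validated `midrib_control` object.
#' @keywords internal
as_midrib_control <- function(control = NULL, ...) {
  dots <- list(...)
  if (is.null(control)) control <- midrib_control()
  if (!inherits(control, "midrib_control")) {
    control <- do.call(midrib_control, control)
  }
  if (length(dots)) {
    known <- names(formals(midrib_control))
    bad <- setdiff(names(dots), known)
    if (length(bad)) stop("unknown control parameter(s): ", paste(bad, collapse = ", "))
    args <- unclass(control)
    args[names(dots)] <- dots
    control <- do.call(midrib_control, args)
  }
  control
}
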