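#' Fit the smooth midrib curve model to a digitized sample
#'
#' The main entry point: runs broken-midrib QC, positive-direction (stalk
#' axis) correction, equidistant interpolation, curvature-constrained
#' iterative B-spline smoothing, direction-plane normalization, trait
#' extraction and type classification for one plant, and returns a fitted
#' model object.
#'
#' @param sample A `midrib_sample`, or an n x 3 matrix of midrib key points
#'   (then `stalk` must be given).
#' @param stalk Optional m x 3 stalk matrix when `sample` is a bare midrib
#'   matrix.
#' @param control A [midrib_control()] list.
#' @param smooth Logical; `FALSE` skips interpolation and smoothing and
#'   computes traits directly from the raw key-point polyline (used for
#'   raw-versus-smoothed validation).
#' @return An object of class `"midrib_fit"` with components `sample`,
#'   `control`, `valid`, `broken`, `corrected` (sample after axis
#'   correction), `L1`, `key_points` (corrected key points), `dense`
#'   (`midrib_curve`), `normalized`, `traits` (named vector), `class_`
#'   (base type + deflection), and `report`. Broken samples return with
#'   `valid = FALSE` and no traits rather than throwing, so batch
#'   processing never aborts.
#' @seealso [coef.midrib_fit()], [predict.midrib_fit()],
#'   [simulate.midrib_fit()], [process_batch()]
#' @export
#' @examples
#' arch <- build_reference_curve(archetype_specs()$stretch)
#' smp <- digitize_plant(arch, midrib_noise(sigma = 0.3), seed = 7)
#' fit <- fit_midrib(smp)
#' coef(fit)[c("LeafLength", "LeafAngle")]
fit_midrib <- function(sample, stalk = NULL, control = midrib_control(),
                       smooth = TRUE) {
  control <- as_midrib_control(control)
  if (!inherits(sample, "midrib_sample")) {
    if (is.null(stalk)) stop("fit_midrib: supply a midrib_sample or midrib + stalk matrices")
    sample <- midrib_sample("sample", stalk, sample)
  }
  out <- list(sample = sample, control = control, smoothed = smooth)
  class(out) <- "midrib_fit"

  qc <- detect_broken(sample$midrib, control$broken_thre)
  out$broken <- qc
  if (qc$is_broken) {
    out$valid <- FALSE
    out$error <- sprintf("broken midrib: node curvature %.3f at key point %d",
                         qc$worst_kappa, qc$worst_index)
    out$report <- list(n_iterations = NA_integer_, converged = NA)
    return(out)
  }

  corrected <- correct_positive_direction(sample)
  out$corrected <- corrected

  if (smooth) {
    L1 <- equidistant_interpolate(corrected$midrib, control$D_b)
    sm <- ciscb_smooth(L1, control)
    out$L1 <- L1
    out$key_points <- sm$key_points
    out$dense <- sm$dense
    out$report <- sm$report
  } else {
    out$key_points <- corrected$midrib
    out$dense <- .as_curve(corrected$midrib)
    out$report <- list(n_iterations = 0L, converged = NA,
                       flagged_per_iteration = integer(0),
                       max_curvature_final = max(out$dense$curvature))
  }

  out$normalized <- normalize_direction_plane(out$dense, control$min_horizontal)
  out$traits <- compute_traits(out$normalized, control)
  out$class_ <- classify_midrib(out$traits, out$normalized, control)
  out$valid <- TRUE
  out
}

#' @export
print.midrib_fit <- function(x, ...) {
  cat("Midrib curve fit: sample '", x$sample$sample_id, "'\n", sep = "")
  if (!x$valid) {
    cat("  INVALID:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %d key points -> %d dense nodes; %s iterations (%s)\n",
              nrow(x$sample$midrib), nrow(x$dense$points),
              x$report$n_iterations,
              if (isTRUE(x$report$converged)) "converged" else "stopped"))
  cat(sprintf("  type: %s%s;  LeafLength %.1f cm, LeafAngle %.1f deg\n",
              x$class_$base_type,
              if (x$class_$deflected) " (deflected)" else "",
              x$traits[["LeafLength"]], x$traits[["LeafAngle"]]))
  invisible(x)
}

#' Trait vector of a fitted midrib
#' @param object A `midrib_fit`.
#' @param ... Unused.
#' @return Named numeric vector over [trait_names()] (NA-filled when the
#'   sample failed QC).
#' @export
coef.midrib_fit <- function(object, ...) {
  if (!object$valid) {
    v <- rep(NA_real_, length(trait_names()))
    names(v) <- trait_names()
    return(v)
  }
  object$traits
}

#' @export
summary.midrib_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.midrib_fit")
}

#' @export
print.summary.midrib_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$valid) {
    cat("\nTraits:\n")
    tv <- f$traits
    for (nm in trait_names()) cat(sprintf("  %-22s %10.4f\n", nm, tv[[nm]]))
    cat(sprintf("\nMax final curvature: %.4g 1/cm; flagged per iteration: %s\n",
                f$report$max_curvature_final,
                paste(f$report$flagged_per_iteration, collapse = " ")))
  }
  invisible(x)
}

#' Points on the fitted curve at requested arc lengths
#'
#' Linear interpolation along the normalized dense curve.
#'
#' @param object A valid `midrib_fit`.
#' @param arclength Numeric vector of arc lengths (cm); defaults to 50
#'   equally spaced stations.
#' @param frame `"normalized"` (canonical frame) or `"corrected"` (stalk-
#'   aligned frame).
#' @param ... Unused.
#' @return A `length(arclength)` x 3 matrix.
#' @export
predict.midrib_fit <- function(object, arclength = NULL,
                               frame = c("normalized", "corrected"), ...) {
  if (!object$valid) stop("predict: sample failed QC; no fitted curve")
  frame <- match.arg(frame)
  crv <- if (frame == "normalized") object$normalized else object$dense
  S <- crv$arclength[length(crv$arclength)]
  if (is.null(arclength)) arclength <- seq(0, S, length.out = 50)
  out <- sapply(1:3, function(j) {
    stats::approx(crv$arclength, crv$points[, j], xout = pmin(pmax(arclength, 0), S))$y
  })
  out <- matrix(out, ncol = 3)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Distances of raw key points from the smoothed curve
#'
#' For each raw midrib key point (in the corrected frame), the Euclidean
#' distance to the nearest node of the smoothed dense curve — the
#' displacement attributed to digitizing error.
#'
#' @param object A valid `midrib_fit`.
#' @param ... Unused.
#' @return Numeric vector, one value per raw key point.
#' @export
residuals.midrib_fit <- function(object, ...) {
  if (!object$valid) return(rep(NA_real_, nrow(object$sample$midrib)))
  raw <- object$corrected$midrib
  dn <- object$dense$points
  apply(raw, 1, function(q) sqrt(min(colSums((t(dn) - q)^2))))
}

#' @export
fitted.midrib_fit <- function(object, ...) {
  if (!object$valid) stop("fitted: sample failed QC")
  object$dense$points
}

#' Simulate new digitizations from a fitted midrib
#'
#' Treats the fitted smoothed curve as ground truth and redigitizes it with
#' the given noise model, yielding replicate synthetic samples.
#'
#' @param object A valid `midrib_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param noise A [midrib_noise()] spec.
#' @param ... Unused.
#' @return A list of `midrib_sample` objects.
#' @export
simulate.midrib_fit <- function(object, nsim = 1, seed = 1,
                                noise = midrib_noise(), ...) {
  if (!object$valid) stop("simulate: sample failed QC")
  crv <- list(points = object$normalized$points,
              arclength = object$normalized$arclength,
              curvature = object$normalized$curvature)
  lapply(seq_len(nsim), function(i) {
    digitize_plant(crv, noise, seed = seed + i - 1,
                   sample_id = sprintf("%s_sim%d", object$sample$sample_id, i))
  })
}

#' Diagnostic plot of a fitted midrib
#'
#' Front (x-z) and top (x-y) views of the raw key points and the smoothed
#' dense curve in the normalized frame.
#'
#' @param x A valid `midrib_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.midrib_fit <- function(x, ...) {
  if (!x$valid) stop("plot: sample failed QC")
  norm <- x$normalized
  # raw key points carried into the normalized frame
  raw <- x$corrected$midrib
  raw <- sweep(raw, 2, x$dense$points[1, ])
  ang <- x$normalized$rotation_z * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  raw <- raw %*% t(R)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(norm$points[, 1], norm$points[, 3], type = "l",
                 xlab = "x (cm)", ylab = "z (cm)", main = "front view", asp = 1, ...)
  graphics::points(raw[, 1], raw[, 3], col = 2, pch = 19, cex = 0.7)
  graphics::plot(norm$points[, 1], norm$points[, 2], type = "l",
                 xlab = "x (cm)", ylab = "y (cm)", main = "top view", asp = 1, ...)
  graphics::points(raw[, 1], raw[, 2], col = 2, pch = 19, cex = 0.7)
  invisible(x)
}
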