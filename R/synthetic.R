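# Synthetic ground-truth midribs and a simulator of the 3D digitizer's
# acquisition and error process. The curve family is arc-length
# parameterized: planar inclination phi(s) = theta0 + integral of the linear
# curvature profile kappa(s) = kappa0 + kappa1 * s, and horizontal azimuth
# alpha(s) = psi * s (constant drift). This minimal family spans all seven
# architectural types.

#' Specification of a synthetic midrib curve
#'
#' @param length Arc length L (cm).
#' @param base_angle Inclination from vertical at the base (deg).
#' @param kappa0 Curvature at the base (1/cm).
#' @param kappa1 Linear curvature slope (1/cm^2); `kappa0 + kappa1 * s` must
#'   stay non-negative on `[0, L]`.
#' @param psi Azimuth drift rate (deg/cm); non-zero values wind the midrib
#'   out of its vertical plane.
#' @return An object of class `"midrib_spec"`.
#' @export
midrib_spec <- function(length, base_angle = 30, kappa0 = 0.01, kappa1 = 0,
                        psi = 0) {
  if (!is.finite(length) || length <= 0) stop("midrib_spec: length must be positive")
  kmin <- min(kappa0, kappa0 + kappa1 * length)
  if (kmin < -1e-12) stop("midrib_spec: curvature profile must stay non-negative")
  structure(list(length = length, base_angle = base_angle, kappa0 = kappa0,
                 kappa1 = kappa1, psi = psi), class = "midrib_spec")
}

#' Acquisition and error model of the digitizer
#'
#' @param sigma Marginal isotropic jitter (cm, per coordinate) of interior
#'   midrib key points. The error is a two-component mixture mirroring how
#'   digitizer data actually degrade: a small device/background term on
#'   every point plus occasional gross probe slips (`slip_prob`,
#'   `slip_sigma`); the background standard deviation is derived so the
#'   overall per-coordinate standard deviation equals `sigma`.
#' @param slip_prob Probability that a key point is a gross fluctuation
#'   error (probe slip) rather than background noise.
#' @param slip_sigma Standard deviation (cm) of slip errors.
#' @param landmark_sigma Jitter (cm) for the base and tip key points, which
#'   are placed on distinct anatomical landmarks; defaults to the device
#'   accuracy of 0.25 cm.
#' @param stalk_tilt_max Maximum whole-plant tilt (deg); the actual tilt is
#'   drawn uniformly on `[0, stalk_tilt_max]` about a random horizontal axis.
#' @param stalk_z_sd Per-node vertical offset noise of stalk key points (cm).
#' @param stalk_xy_sd Per-node horizontal noise of stalk key points (cm).
#' @param spacing Length-2 range (cm) of the nominal key-point spacing along
#'   the midrib.
#' @param curvature_quantile Where the true curvature exceeds this quantile
#'   of the curve's curvature profile, the nominal spacing drops to the
#'   bottom of its range (denser sampling where the midrib bends, as a
#'   digitizer operator would collect).
#' @return An object of class `"midrib_noise"`.
#' @export
midrib_noise <- function(sigma = 1.0, slip_prob = 0.1, slip_sigma = 3.0,
                         landmark_sigma = 0.25,
                         stalk_tilt_max = 5, stalk_z_sd = 0.5,
                         stalk_xy_sd = 0.2, spacing = c(5, 9),
                         curvature_quantile = 0.75) {
  if (sigma < 0 || landmark_sigma < 0) stop("midrib_noise: sigma must be >= 0")
  if (slip_prob < 0 || slip_prob > 1) stop("midrib_noise: slip_prob must be in [0, 1]")
  if (length(spacing) != 2 || spacing[1] <= 0 || spacing[2] < spacing[1]) {
    stop("midrib_noise: spacing must be an increasing positive range")
  }
  # split the marginal variance into background + slips
  var_bg <- (sigma^2 - slip_prob * slip_sigma^2) / (1 - slip_prob)
  if (is.nan(var_bg)) var_bg <- 0  # slip_prob == 1
  if (var_bg < 0) {
    var_bg <- 0
    slip_sigma <- sigma / sqrt(slip_prob)
  }
  structure(list(sigma = sigma, slip_prob = slip_prob,
                 slip_sigma = slip_sigma, bg_sigma = sqrt(var_bg),
                 landmark_sigma = landmark_sigma,
                 stalk_tilt_max = stalk_tilt_max, stalk_z_sd = stalk_z_sd,
                 stalk_xy_sd = stalk_xy_sd, spacing = spacing,
                 curvature_quantile = curvature_quantile),
            class = "midrib_noise")
}

# run expr with a private RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Build a dense noise-free reference curve from a spec
#'
#' Integrates the inclination and azimuth profiles at step `ds` from the
#' origin and computes the ground-truth trait vector by running the trait
#' code on the dense noise-free curve (after direction-plane normalization),
#' so that parameter-recovery benchmarks test the correction chain rather
#' than trait-definition agreement.
#'
#' @param spec A `midrib_spec`.
#' @param ds Integration step (cm), default 0.1 (must be <= 0.5).
#' @param control A [midrib_control()] list (trait parameters).
#' @return A list with `points` (dense curve from the origin), `arclength`,
#'   `curvature` (profile kappa(s)), `truth` (named trait vector), and
#'   `spec`.
#' @export
build_reference_curve <- function(spec, ds = 0.1, control = midrib_control()) {
  stopifnot(inherits(spec, "midrib_spec"))
  if (ds > 0.5) stop("build_reference_curve: ds must be <= 0.5")
  L <- spec$length
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  theta0 <- spec$base_angle * pi / 180
  phi <- theta0 + spec$kappa0 * s + spec$kappa1 * s^2 / 2
  alpha <- spec$psi * pi / 180 * s
  tx <- sin(phi) * cos(alpha)
  ty <- sin(phi) * sin(alpha)
  tz <- cos(phi)
  # trapezoidal integration of the unit tangent
  dsv <- diff(s)
  px <- c(0, cumsum((tx[-1] + tx[-length(tx)]) / 2 * dsv))
  py <- c(0, cumsum((ty[-1] + ty[-length(ty)]) / 2 * dsv))
  pz <- c(0, cumsum((tz[-1] + tz[-length(tz)]) / 2 * dsv))
  pts <- cbind(x = px, y = py, z = pz)
  norm <- normalize_direction_plane(pts, min_horizontal = control$min_horizontal)
  truth <- compute_traits(norm, control)
  list(points = pts, arclength = polyline_arclength(pts),
       curvature = spec$kappa0 + spec$kappa1 * s, truth = truth, spec = spec)
}

# interpolate curve points at given arc lengths
.curve_at <- function(curve, s) {
  sapply(1:3, function(j) {
    stats::approx(curve$arclength, curve$points[, j], xout = s, rule = 2)$y
  })
}

#' Simulate digitizer acquisition of one plant
#'
#' Places 5 stalk-node key points on a vertical axis below the midrib base
#' with per-node offset noise, samples midrib key points along the reference
#' curve at the spacing rule (halved spacing where the true curvature is in
#' the upper quantile), jitters them, and rigidly tilts the whole plant by a
#' random angle up to `stalk_tilt_max`. Deterministic given `seed`.
#'
#' @param curve Output of [build_reference_curve()].
#' @param noise A [midrib_noise()] spec.
#' @param seed Integer seed.
#' @param sample_id Id for the resulting sample.
#' @return A `midrib_sample`.
#' @export
digitize_plant <- function(curve, noise = midrib_noise(), seed = 1,
                           sample_id = "synthetic") {
  stopifnot(inherits(noise, "midrib_noise"))
  .with_seed(seed, {
    L <- curve$arclength[length(curve$arclength)]
    kq <- stats::quantile(curve$curvature, noise$curvature_quantile,
                          names = FALSE)
    # arc positions: nominal spacing, denser in high-curvature zones but
    # never below spacing[1] (below that scale probe jitter is
    # indistinguishable from a broken midrib under the QC rule)
    s_keys <- 0
    while (s_keys[length(s_keys)] < L) {
      here <- s_keys[length(s_keys)]
      step <- stats::runif(1, noise$spacing[1], noise$spacing[2])
      k_here <- stats::approx(curve$arclength, curve$curvature, xout = here,
                              rule = 2)$y
      if (k_here > kq) step <- stats::runif(1, noise$spacing[1], noise$spacing[1] + 1)
      s_keys <- c(s_keys, min(here + step, L))
    }
    if (length(s_keys) >= 3 && diff(s_keys)[length(s_keys) - 1] < noise$spacing[1] / 2) {
      s_keys <- s_keys[-(length(s_keys) - 1)]  # merge a sliver tip segment
    }
    while (length(s_keys) < 4) {
      s_keys <- sort(unique(c(s_keys, L * seq_len(3) / 4)))
    }
    midrib <- .curve_at(curve, s_keys)
    nk <- nrow(midrib)
    slip <- stats::runif(nk) < noise$slip_prob
    sds <- ifelse(slip, noise$slip_sigma, noise$bg_sigma)
    sds[c(1, nk)] <- noise$landmark_sigma
    jit <- matrix(stats::rnorm(3 * nk), nk, 3) * sds
    midrib <- midrib + jit

    stalk_z <- seq(-60, 0, length.out = 5)
    stalk <- cbind(stats::rnorm(5, 0, noise$stalk_xy_sd),
                   stats::rnorm(5, 0, noise$stalk_xy_sd),
                   stalk_z + stats::rnorm(5, 0, noise$stalk_z_sd))

    tilt <- stats::runif(1, 0, noise$stalk_tilt_max) * pi / 180
    axis_az <- stats::runif(1, 0, 2 * pi)
    axis <- c(cos(axis_az), sin(axis_az), 0)
    R <- rotation_aligning(c(0, 0, 1),
                           c(sin(tilt) * c(-axis[2], axis[1]), cos(tilt)))
    stalk <- rotate_points(stalk, R)
    midrib <- rotate_points(midrib, R)
    midrib_sample(sample_id, stalk, midrib,
                  metadata = list(seed = seed, tilt_deg = tilt * 180 / pi))
  })
}

#' Archetype curve specifications
#'
#' One constructed parameter set per architectural type (the deflected
#' archetype is a stretch-type midrib with strong azimuth drift). Intended
#' labels are carried in the names.
#'
#' @return Named list of `midrib_spec` objects.
#' @export
archetype_specs <- function() {
  list(
    vertical   = midrib_spec(60, base_angle = 6,  kappa0 = 0.0008, kappa1 = 0),
    tip_curved = midrib_spec(50, base_angle = 35, kappa0 = 0,      kappa1 = 9.77e-4),
    stretch    = midrib_spec(70, base_angle = 55, kappa0 = 0.003,  kappa1 = 0),
    bending    = midrib_spec(45, base_angle = 12, kappa0 = 0.07,   kappa1 = -0.0014),
    creeping   = midrib_spec(55, base_angle = 80, kappa0 = 0.004,  kappa1 = 0),
    drooping   = midrib_spec(70, base_angle = 45, kappa0 = 0.03,   kappa1 = 0),
    deflected  = midrib_spec(70, base_angle = 55, kappa0 = 0.003,  kappa1 = 0,
                             psi = 0.6)
  )
}

#' Generate a synthetic population with ground truth
#'
#' Draws curve specs uniformly from ranges chosen to span the seven
#' architectural types and realistic trait ranges, digitizes each plant with
#' the given noise model, and returns the paired ground-truth table. Fully
#' seeded and reproducible.
#'
#' @param n Number of plants; with `archetypes = TRUE`, `n` is ignored and
#'   the seven archetypes are generated instead.
#' @param noise A [midrib_noise()] spec.
#' @param seed Integer seed.
#' @param ranges Named list of uniform ranges (`length`, `base_angle`,
#'   `kappa0`, `kappa1`, `psi`).
#' @param archetypes Generate the seven archetypes instead of random draws.
#' @param control A [midrib_control()] list used for the truth traits.
#' @param ds Integration step for the reference curves (cm).
#' @return A list with `samples` (list of `midrib_sample`), `truth` (a
#'   data.frame: sample_id, spec columns, the 15 truth traits, and for
#'   archetypes the intended label), and `curves` (reference curves).
#' @export
generate_population <- function(n, noise = midrib_noise(), seed = 1,
                                ranges = list(length = c(40, 95),
                                              base_angle = c(5, 70),
                                              kappa0 = c(0, 0.018),
                                              kappa1 = c(0, 4e-4),
                                              psi = c(-0.5, 0.5)),
                                archetypes = FALSE,
                                control = midrib_control(),
                                ds = 0.1) {
  specs <- if (archetypes) {
    archetype_specs()
  } else {
    if (n < 1) stop("generate_population: n must be >= 1")
    .with_seed(seed, {
      lapply(seq_len(n), function(i) {
        midrib_spec(
          length = stats::runif(1, ranges$length[1], ranges$length[2]),
          base_angle = stats::runif(1, ranges$base_angle[1], ranges$base_angle[2]),
          kappa0 = stats::runif(1, ranges$kappa0[1], ranges$kappa0[2]),
          kappa1 = stats::runif(1, ranges$kappa1[1], ranges$kappa1[2]),
          psi = stats::runif(1, ranges$psi[1], ranges$psi[2])
        )
      })
    })
  }
  ids <- if (archetypes) {
    sprintf("arch_%s", names(specs))
  } else {
    sprintf("syn%04d", seq_along(specs))
  }
  curves <- lapply(specs, build_reference_curve, ds = ds, control = control)
  samples <- vector("list", length(specs))
  truth_rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    samples[[i]] <- digitize_plant(curves[[i]], noise, seed = seed + i,
                                   sample_id = ids[i])
    tr <- as.list(curves[[i]]$truth)
    names(tr) <- trait_names()
    truth_rows[[i]] <- data.frame(
      sample_id = ids[i], length = specs[[i]]$length,
      base_angle = specs[[i]]$base_angle, kappa0 = specs[[i]]$kappa0,
      kappa1 = specs[[i]]$kappa1, psi = specs[[i]]$psi,
      as.data.frame(tr), stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_rows)
  if (archetypes) truth$intended <- names(specs)
  rownames(truth) <- NULL
  list(samples = samples, truth = truth, curves = curves)
}
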