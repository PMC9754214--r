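# Shared fixtures, built in code.

# points on a circle of radius r in the XZ plane, by arc length
circle_points_xz <- function(r, s) {
  cbind(x = r * (1 - cos(s / r)), y = 0, z = r * sin(s / r))
}

# noiseless digitizer settings
noiseless <- function(spacing = c(4, 4)) {
  midrib_noise(sigma = 0, slip_prob = 0, landmark_sigma = 0,
               stalk_tilt_max = 0, stalk_z_sd = 0, stalk_xy_sd = 0,
               spacing = spacing)
}

# a noiseless quarter-circle sample (R = 40 cm), digitized at uniform 4 cm
# arc steps with a vertical stalk
quarter_circle_sample <- function(R = 40, seed = 3) {
  spec <- midrib_spec(length = pi * R / 2, base_angle = 0, kappa0 = 1 / R)
  crv <- build_reference_curve(spec)
  digitize_plant(crv, noiseless(), seed = seed, sample_id = "quarter")
}

# straight key points along +X with one node displaced laterally
displaced_line_keys <- function(n = 16, spacing = 4, at = 8, amount = 2) {
  key <- cbind(x = seq(0, by = spacing, length.out = n), y = 0, z = 0)
  key[at, "y"] <- amount
  key
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}
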