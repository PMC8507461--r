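test_that("source position respects the C-arm kinematics", {
  room <- fix_room()
  expect_equal(source_position(room, 0, 0), c(0, 0, -0.75), tolerance = 1e-14)
  # rotations preserve the distance to the isocenter
  for (ang in list(c(15, 0), c(-35, 0), c(26, 10), c(38, -20))) {
    p <- source_position(room, ang[1], ang[2])
    expect_equal(sqrt(sum(p^2)), room$d_source_iso, tolerance = 1e-12)
  }
  # opposite rotations compose to the identity
  R <- irscatter:::rot_y(15 * pi / 180) %*% irscatter:::rot_y(-15 * pi / 180)
  expect_equal(R, diag(3), tolerance = 1e-14)
  expect_error(source_position(room, 150), "120")
})

test_that("beam aperture reproduces the logged field size at the receptor", {
  room <- fix_room()
  ev <- fix_event(field_area = 835)
  bc <- beam_cone(room, ev)
  expect_equal(bc$half_side * 2 * 100, sqrt(835), tolerance = 1e-12)
  expect_equal(bc$half_angle, atan(sqrt(835) / 100 / 2 / 1.1), tolerance = 1e-12)

  # forward-project the four aperture corners onto the receptor plane
  corners <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(sg) {
    dir <- bc$axis * bc$d_sd + sg[1] * bc$half_side * bc$e1 +
      sg[2] * bc$half_side * bc$e2
    dir <- dir / sqrt(sum(dir^2))
    t <- bc$d_sd / sum(dir * bc$axis)      # plane through receptor, normal axis
    bc$apex + t * dir
  })
  side1 <- sqrt(sum((corners[[1]] - corners[[2]])^2))
  side2 <- sqrt(sum((corners[[1]] - corners[[3]])^2))
  expect_equal(side1 * side2 * 1e4, 835, tolerance = 1e-3)

  # doubling the field area doubles the subtended solid angle (small angles)
  omega <- function(area) {
    a <- sqrt(area) / 100
    4 * atan(a * a / (2 * bc$d_sd * sqrt(4 * bc$d_sd^2 + 2 * a^2)))
  }
  expect_equal(omega(600 * 2) / omega(600), 2, tolerance = 0.02)
})

test_that("phantom chord lengths match analytic quadric intersections", {
  ph <- bomab_phantom()
  # miss entirely
  expect_equal(path_length(ph, c(5, 5, 5), c(0, 0, 1)), 0)
  # through the gut cylinder center along its thickness semi-axis b = 10 cm
  expect_equal(path_length(ph, c(0, 0, -1), c(0, 0, 1)), 20, tolerance = 1e-9)
  # along the width semi-axis at chest height: chest (2*15) plus both arms (2*10)
  expect_equal(path_length(ph, c(-1, 0.15, 0), c(1, 0, 0)), 30 + 20,
               tolerance = 1e-9)
  # at gut height: gut (2*17) plus both arms (2 * 2*5)
  expect_equal(path_length(ph, c(-1, 0, 0), c(1, 0, 0)), 54, tolerance = 1e-9)
  # head ellipsoid straight through the middle: 2 * semi_z = 14 cm
  expect_equal(path_length(ph, c(0, 0.70, -1), c(0, 0, 1)), 14, tolerance = 1e-9)
  # prism box
  pb <- prism_phantom(c(30, 60, 20))
  expect_equal(path_length(pb, c(0, 0, -1), c(0, 0, 1)), 20, tolerance = 1e-12)
  # truncation at t_max = 1.05 m: entry at 0.9 m, so 0.15 m of the chord
  expect_equal(path_length(pb, c(0, 0, -1), c(0, 0, 1), t_max = 1.05), 15,
               tolerance = 1e-9)

  # bounded by the bounding-box diagonal; symmetric under ray reversal
  set.seed(7)
  diag_cm <- sqrt(0.5^2 + 2^2 + 0.3^2) * 100
  for (i in 1:50) {
    u <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    u <- u / sqrt(sum(u^2))
    o <- c(runif(1, -0.4, 0.4), runif(1, -1.2, 0.9), -2)
    fwd <- path_length(ph, o, u)
    expect_lte(fwd, diag_cm)
    rev <- path_length(ph, o + 6 * u, -u)
    expect_equal(rev, fwd, tolerance = 1e-7)
  }
})

test_that("BOMAB volume agrees with Monte-Carlo point sampling within 0.5%", {
  ph <- bomab_phantom()
  set.seed(11)
  n <- 1e6
  lim <- list(x = c(-0.3, 0.3), y = c(-1.15, 0.85), z = c(-0.12, 0.12))
  p <- cbind(runif(n, lim$x[1], lim$x[2]), runif(n, lim$y[1], lim$y[2]),
             runif(n, lim$z[1], lim$z[2]))
  inside <- rep(FALSE, n)
  for (s in ph$segments) {
    inside <- inside | switch(s$kind,
      ecyl = ((p[, 1] - s$center[1]) / s$a)^2 +
        ((p[, 3] - s$center[3]) / s$b)^2 < 1 &
        abs(p[, 2] - s$center[2]) < s$half,
      ellipsoid = ((p[, 1] - s$center[1]) / s$semi[1])^2 +
        ((p[, 2] - s$center[2]) / s$semi[2])^2 +
        ((p[, 3] - s$center[3]) / s$semi[3])^2 < 1,
      box = abs(p[, 1] - s$center[1]) < s$half3[1] &
        abs(p[, 2] - s$center[2]) < s$half3[2] &
        abs(p[, 3] - s$center[3]) < s$half3[3])
  }
  vbox <- diff(lim$x) * diff(lim$y) * diff(lim$z)
  v_mc <- mean(inside) * vbox
  expect_equal(v_mc, irscatter:::phantom_volume(ph), tolerance = 0.005)
})

test_that("shield transmission is the closed-form lead attenuation", {
  sh <- shield_model(center = c(-0.45, 0, 0.45), u = c(0, 1, 0), v = c(0, 0, 1),
                     width = 0.6, height = 0.6, pb_mm = 0.5)
  # segment not crossing the rectangle
  expect_equal(shield_transmission(sh, 80, c(0, 0, 0), c(0.5, 0, 0)), 1)
  # segment parallel to the shield plane
  expect_equal(shield_transmission(sh, 80, c(-0.45, -1, 0.45), c(-0.45, -0.8, 0.45)), 1)
  # crossing: exp(-mu_Pb(80 keV) * 0.05 cm)
  expect_equal(shield_transmission(sh, 80, c(0, 0, 0.45), c(-1, 0, 0.45)),
               exp(-mu_total("lead", 80) * 0.05), tolerance = 1e-12)
  # zero lead equivalence is the identity
  sh0 <- shield_model(center = c(-0.45, 0, 0.45), u = c(0, 1, 0), v = c(0, 0, 1),
                      width = 0.6, height = 0.6, pb_mm = 0)
  expect_equal(shield_transmission(sh0, 80, c(0, 0, 0.45), c(-1, 0, 0.45)), 1)
  expect_equal(shield_transmission(NULL, 80, c(0, 0, 0), c(-1, 0, 0)), 1)
  expect_error(shield_model(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 1, 0.5),
               "orthogonal")
})

test_that("room configuration files round-trip", {
  sh <- shield_model(center = c(-0.45, 0.1, 0.45), u = c(0, 1, 0),
                     v = c(0, 0, 1), width = 0.6, height = 0.6, pb_mm = 0.5)
  room <- room_model(d_source_iso = 0.8, d_iso_detector = 0.3,
                     d_iso_reference = 0.2, phantom = prism_phantom(c(30, 60, 22)),
                     table_aleq_mm = 2, shield = sh)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_room(room, f)
  back <- read_room(f)
  expect_equal(back$d_source_iso, 0.8)
  expect_equal(back$d_iso_reference, 0.2)
  expect_equal(back$phantom$segments$body$half3,
               room$phantom$segments$body$half3)
  expect_equal(back$shield$pb_mm, 0.5)
  expect_equal(back$shield$normal, room$shield$normal)
  expect_error(room_model(d_iso_reference = 1), "d_iso_reference")
})
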