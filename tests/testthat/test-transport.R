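test_that("interaction branching follows the partial coefficients", {
  set.seed(5)
  n <- 2e5
  kinds <- sample_interaction(rep(60, n), "soft_tissue")
  mp <- mu_partial("soft_tissue", 60)
  for (k in c("photoelectric", "compton", "rayleigh")) {
    p <- switch(k, photoelectric = mp$pe, compton = mp$compton,
                rayleigh = mp$rayleigh) / mp$total
    obs <- mean(kinds == k)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
  # fixed seed reproduces the branch sequence
  set.seed(9); a <- sample_interaction(rep(40, 1000), "water")
  set.seed(9); b <- sample_interaction(rep(40, 1000), "water")
  expect_identical(a, b)
})

test_that("Compton sampling respects kinematics and the Klein-Nishina law", {
  set.seed(3)
  e <- rep(60, 2e5)
  sc <- sample_compton(e)
  k <- 60 / 511
  expect_true(all(sc$energy_out <= 60 + 1e-12))
  expect_true(all(sc$energy_out >= 60 / (1 + 2 * k) - 1e-12))
  expect_true(all(abs(sc$cos_theta) <= 1 + 1e-12))
  # energy and angle are consistent through the Compton relation
  expect_equal(sc$energy_out, 60 / (1 + k * (1 - sc$cos_theta)),
               tolerance = 1e-12)
  # forward scatter keeps the full energy
  expect_equal(60 / (1 + k * (1 - 1)), 60)

  # first angular moment versus numerical quadrature of the closed form
  num <- integrate(function(mu) mu * klein_nishina_dcs(60, mu), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(function(mu) klein_nishina_dcs(60, mu), -1, 1,
                   rel.tol = 1e-10)$value
  expect_lt(abs(mean(sc$cos_theta) - num / den),
            3 * sd(sc$cos_theta) / sqrt(length(e)))
  # quadrature of the differential cross-section equals the closed-form total
  expect_equal(2 * pi * den, klein_nishina_total(60), tolerance = 1e-8)
})

test_that("next-event estimation reduces to closed forms in vacuum", {
  for (r in c(0.5, 1, 2)) {
    ne <- next_event_contribution(60, c(0, 0, 0), c(0, 0, 1),
                                  c(r, 0, 0), kind = "isotropic")
    expect_equal(ne$fluence, 1 / (4 * pi * (100 * r)^2), tolerance = 1e-12)
  }
  n1 <- next_event_contribution(60, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                                kind = "compton")
  n2 <- next_event_contribution(60, c(0, 0, 0), c(0, 0, 1), c(2, 0, 0),
                                kind = "compton")
  expect_equal(n1$fluence / n2$fluence, 4, tolerance = 1e-12)
  expect_equal(n1$energy_out, 60 / (1 + 60 / 511), tolerance = 1e-12)
  # rayleigh is elastic with the Thomson shape
  nr <- next_event_contribution(60, c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                                kind = "rayleigh")
  expect_equal(nr$energy_out, 60)
  expect_equal(nr$fluence, 3 / (16 * pi) * 2 / 200^2, tolerance = 1e-12)
})

test_that("event simulations are reproducible and guard their inputs", {
  room <- fix_room()
  ev <- fix_event()
  det <- fix_chest_point()
  t1 <- run_event_simulation(ev, room, det, 3000, seed = 4)
  t2 <- run_event_simulation(ev, room, det, 3000, seed = 4)
  expect_identical(t1$fluence, t2$fluence)
  expect_identical(t1$simulated_pka, t2$simulated_pka)
  t3 <- run_event_simulation(ev, room, det, 3000, seed = 5)
  expect_false(identical(t1$fluence, t3$fluence))
  # a detector inside the phantom is rejected
  inside <- detector_points(data.frame(point_id = "bad", x = 0, y = 0, z = 0))
  expect_error(run_event_simulation(ev, room, inside, 100), "inside the phantom")
  expect_error(run_event_simulation(ev, room, det[0, ], 100), "non-empty")
  expect_true(all(t1$fluence >= 0))
  expect_true(all(t1$var_mean >= 0))
  expect_gt(t1$simulated_pka, 0)
  expect_gt(t1$simulated_kair, 0)
})

test_that("scatter fluence decreases with detector distance", {
  room <- fix_room()
  ev <- fix_event(p_ka = 10)
  det <- detector_points(data.frame(point_id = c("d05", "d10", "d20"),
                                    x = c(-0.5, -1, -2), y = 0, z = 0.1))
  tal <- run_event_simulation(ev, room, det, 2e4, seed = 12)
  hp <- vapply(det$point_id,
               function(p) unlist(fluence_to_hp10(tal, p)), numeric(2))
  expect_gt(hp[1, "d05"] - 3 * (hp[2, "d05"] + hp[2, "d10"]), hp[1, "d10"])
  expect_gt(hp[1, "d10"] - 3 * (hp[2, "d10"] + hp[2, "d20"]), hp[1, "d20"])
})

test_that("energy never increases along a history", {
  set.seed(21)
  e0 <- runif(5e4, 20, 150)
  sc <- sample_compton(e0)
  expect_true(all(sc$energy_out <= e0 + 1e-12))
  # scattered spectrum at a detector never exceeds the source endpoint
  room <- fix_room()
  ev <- fix_event(kvp = 80)
  tal <- run_event_simulation(ev, room, fix_chest_point(), 5000, seed = 2)
  mids <- (tal$energy_edges[-1] + tal$energy_edges[-141]) / 2
  expect_equal(sum(tal$fluence[1, mids > 80]), 0)
})

test_that("tally variance scales like 1/n over two decades", {
  room <- fix_room()
  ev <- fix_event()
  det <- fix_chest_point()
  sizes <- c(2e3, 2e4, 2e5)
  v <- vapply(sizes, function(n) {
    tal <- run_event_simulation(ev, room, det, n, seed = 99, n_batches = 50L)
    fluence_to_hp10(tal, "p1")$u_stat_rel^2
  }, numeric(1))
  slope <- coef(lm(log10(v) ~ log10(sizes)))[2]
  expect_lt(abs(slope + 1), 0.1)
})
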