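test_that("residue dipole matches closed forms and is translation invariant", {
  top <- dumbbell_topology(q = 0.8)
  frame <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_equal(residue_dipole(top, frame, 1), c(0, 0, 1.6))
  expect_equal(residue_dipole(top, frame + 5, 1), c(0, 0, 1.6))
  # TIP3P geometry water: |mu| = 2.35 D within 0.01 D
  wat <- water_topology(1)
  ang <- 104.52 * pi / 180
  fw <- rbind(c(0, 0, 0),
              c(0.9572, 0, 0),
              c(0.9572 * cos(ang), 0.9572 * sin(ang), 0))
  mu <- residue_dipole(wat, fw, 1)
  expect_equal(sqrt(sum(mu^2)) / aq_constants()$debye_eA, 2.35,
               tolerance = 0.01 / 2.35)
})

test_that("cos(theta) picks out the z alignment of the dipole", {
  top <- dumbbell_topology(q = 1)
  co <- array(0, dim = c(2, 2, 3))
  co[1, 1, ] <- c(0, 0, 0.5); co[1, 2, ] <- c(0, 0, -0.5)   # along +z
  co[2, 1, ] <- c(0.5, 0, 0); co[2, 2, ] <- c(-0.5, 0, 0)   # in xy plane
  w <- trajectory_window(c(0, 0.01), co, unwrapped = TRUE)
  cs <- cos_theta_series(w, top, 1)
  expect_equal(cs$cos_theta, c(1, 0))
  # zero dipole in every frame is an error
  co0 <- array(0, dim = c(2, 2, 3))
  w0 <- trajectory_window(c(0, 0.01), co0, unwrapped = TRUE)
  expect_error(cos_theta_series(w0, top, 1), "zero dipole")
})

test_that("generator ground-truth orientations are recovered through the analysis", {
  spec <- synth_spec(duration = 10, dt_frame = 0.02, waters_per_pore = 1,
                     seed = 23, field = field_protocol(E0 = 0.035))
  sim <- simulate_system(spec)
  win <- unwrap_trajectory(sim$window)
  for (key in names(sim$truth$dipoles)[c(1, 7, 20)]) {
    tr <- sim$truth$dipoles[[key]]
    cs <- cos_theta_series(win, sim$topology, tr$residue_id)
    expect_lt(max(abs(cs$cos_theta - tr$cos_theta)), 1e-6)
  }
})

test_that("mirroring the trajectory in z flips the sign of cos(theta)", {
  spec <- synth_spec(duration = 2, dt_frame = 0.02, waters_per_pore = 1,
                     seed = 24)
  sim <- simulate_system(spec)
  rid <- sim$truth$dipoles[[1]]$residue_id
  cs <- cos_theta_series(sim$window, sim$topology, rid)
  mir <- sim$window
  mir$coords[, , 3] <- -mir$coords[, , 3]
  cs_m <- cos_theta_series(mir, sim$topology, rid)
  expect_equal(cs_m$cos_theta, -cs$cos_theta)
})

test_that("orientation histograms integrate to one and match known densities", {
  # all mass at cos(theta) = 1: single occupied end bin
  h1 <- orientation_histogram(rep(1, 100))
  expect_equal(sum(h1$density * (h1$bin_hi - h1$bin_lo)), 1, tolerance = 1e-9)
  expect_equal(sum(h1$density > 0), 1)
  expect_gt(h1$density[nrow(h1)], 0)
  # normalisation holds for arbitrary inputs
  set.seed(2)
  for (i in 1:5) {
    h <- orientation_histogram(runif(1 + rpois(1, 50), -1, 1),
                               n_bins = sample(5:80, 1))
    expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1, tolerance = 1e-9)
  }
  # uniform orientations: flat density 0.5 (chi-squared at 1%)
  set.seed(3)
  u <- runif(2e4, -1, 1)
  h <- orientation_histogram(u, n_bins = 20)
  counts <- h$density * 2e4 * 0.1
  chi2 <- sum((counts - 1e3)^2 / 1e3)
  expect_lt(chi2, qchisq(0.99, df = 19))
  # Boltzmann free rotor: histogram mean tracks the Langevin function
  set.seed(5)
  x <- 2
  hh <- orientation_histogram(sample_free_rotor(5e4, x))
  expect_lt(abs(histogram_mean(hh) - langevin_function(x)) /
              langevin_function(x), 0.02)
})

test_that("transition detection counts dwell-confirmed crossings", {
  # constant series: nothing
  t10 <- seq(0, 10, by = 0.01)
  none <- detect_transitions(rep(0.7, length(t10)), t10,
                             dwell_threshold = 0.2)
  expect_equal(none$n_events, 0)
  # square wave (cosine phase), period 2 ns over 10 ns: 10 crossings
  sq <- sign(cos(pi * t10)); sq[sq == 0] <- 1
  tr <- detect_transitions(0.7 * sq, t10, dwell_threshold = 0.2)
  expect_equal(tr$n_events, 10)
  expect_equal(tr$rate, 1.0)
  expect_equal(tr$events$direction[1:2], c("down", "up"))
  expect_true(all(diff(tr$events$time) > 0))
})

test_that("transition detection is robust to sub-dwell chatter and noise", {
  t10 <- seq(0, 10, by = 0.01)
  sq <- 0.7 * sign(cos(pi * t10)); sq[sq == 0] <- 0.7
  # zero-mean noise far below the excursion changes nothing
  set.seed(7)
  noisy <- sq + rnorm(length(sq), sd = 0.05)
  tr_n <- detect_transitions(noisy, t10, dwell_threshold = 0.2)
  expect_equal(tr_n$n_events, 10)
  # an isolated 3-frame blip (0.03 ns < dwell 0.2 ns) is chatter: ignored
  blip <- rep(0.7, length(t10))
  blip[500:502] <- -0.7
  tr_b <- detect_transitions(blip, t10, dwell_threshold = 0.2)
  expect_equal(tr_b$n_events, 0)
  expect_error(detect_transitions(blip, t10, dwell_threshold = 0.01),
               "2 frame intervals")
})

test_that("telegraph transition rates are recovered from sampled series", {
  res <- data.frame(resname = "SER", resno = 211L, z_pos = 8, dipole_D = 2,
                    cos_amp = 0.7, flip_rate_zero_field = 0.5,
                    flip_barrier = 6)
  spec <- synth_spec(duration = 100, dt_frame = 0.02, waters_per_pore = 1,
                     residues = res, seed = 17)
  sim <- simulate_system(spec)
  win <- unwrap_trajectory(sim$window)
  rates <- vapply(names(sim$truth$dipoles), function(key) {
    tr <- sim$truth$dipoles[[key]]
    cs <- cos_theta_series(win, sim$topology, tr$residue_id)
    detect_transitions(cs, dwell_threshold = 0.04)$rate
  }, 0)
  expect_lt(abs(mean(rates) - 0.5) / 0.5, 0.1)
})
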