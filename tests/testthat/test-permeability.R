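test_that("a full constant-speed traversal contributes unity to n(t)", {
  rg <- default_region()
  dt <- 0.01
  z <- seq(-15, 15, by = 0.2)   # crosses the whole channel
  w <- window_from_z(z, dt = dt)
  top <- water_topology(1)
  ns <- collective_coordinate(w, top, rg)
  v <- 0.2 / dt
  expect_lt(abs(ns$n[length(ns$n)] - 1), 2 * dt * v / rg$L_fixed + 1e-9)
})

test_that("opposite equal velocities cancel and empty channels give zero", {
  rg <- default_region()
  z <- cbind(seq(-8, 8, by = 0.1), seq(8, -8, by = -0.1))
  w <- window_from_z(z)
  ns <- collective_coordinate(w, water_topology(2), rg)
  expect_equal(ns$n, rep(0, nrow(z)))
  # waters far outside the cylinder: nothing accumulates
  z2 <- cbind(seq(-8, 8, by = 0.1))
  w2 <- window_from_z(z2, xy = matrix(c(50, 50), 1))
  ns2 <- collective_coordinate(w2, water_topology(1), rg)
  expect_equal(ns2$n, rep(0, nrow(z2)))
})

test_that("n(t) equals the brute-force per-water displacement sum", {
  set.seed(14)
  rg <- default_region()
  nf <- 400; nw <- 8
  z <- matrix(0, nf, nw)
  z[1, ] <- runif(nw, -12, 12)
  for (i in 2:nf) z[i, ] <- z[i - 1, ] + rnorm(nw, sd = 0.8)
  xy <- cbind(runif(nw, -3, 3), runif(nw, -3, 3))
  w <- window_from_z(z, xy = xy)
  top <- water_topology(nw)
  ns <- collective_coordinate(w, top, rg)
  # independent oracle: loop over steps and waters
  n_oracle <- numeric(nf)
  inS <- function(i, j) z[i, j] >= rg$z_lo && z[i, j] < rg$z_hi &&
    sqrt(sum((xy[j, ] - rg$center_xy)^2)) <= rg$radius
  for (i in 2:nf) {
    dn <- 0
    for (j in 1:nw)
      if (inS(i, j) && inS(i - 1, j)) dn <- dn + (z[i, j] - z[i - 1, j]) / 20
    n_oracle[i] <- n_oracle[i - 1] + dn
  }
  expect_lt(max(abs(ns$n - n_oracle)), 1e-10)
  # wrapped input is refused
  ww <- w; ww$unwrapped <- FALSE
  expect_error(collective_coordinate(ww, top, rg), "unwrap")
})

test_that("multi-origin MSD matches closed forms", {
  tt <- (0:200) * 0.01
  ball <- 3 * tt
  m <- msd_multi_origin(ball, tt, 1)
  expect_equal(m$msd, 9 * m$lag^2, tolerance = 1e-12)
  cst <- msd_multi_origin(rep(2, 201), tt, 1)
  expect_equal(cst$msd, rep(0, nrow(cst)))
  expect_error(msd_multi_origin(ball, tt, 1.5), "half")
  # Gaussian random walk: MSD(tau) ~ 2 D tau
  set.seed(4)
  D <- 0.5; dt <- 0.01; n <- 10000
  x <- cumsum(c(0, rnorm(n - 1, sd = sqrt(2 * D * dt))))
  m2 <- msd_multi_origin(x, (0:(n - 1)) * dt, 0.2)
  for (k in c(5, 10, 20)) {
    expected <- 2 * D * m2$lag[k]
    se <- expected * sqrt(2 * k / n) * 2
    expect_lt(abs(m2$msd[k] - expected), 3 * se)
  }
})

test_that("D_n is half the fitted MSD slope, clamped at zero", {
  m <- data.frame(lag = (1:20) * 0.1, msd = 0.01 * (1:20) * 0.1)
  expect_equal(as.numeric(fit_Dn(m, c(0.1, 2))), 0.005)
  frozen <- data.frame(lag = (1:20) * 0.1, msd = rep(0, 20))
  expect_equal(as.numeric(fit_Dn(frozen, c(0.1, 2))), 0)
  dec <- data.frame(lag = (1:20) * 0.1, msd = 1 - 0.01 * (1:20) * 0.1)
  expect_warning(val <- fit_Dn(dec, c(0.1, 2)), "clamped")
  expect_equal(as.numeric(val), 0)
  expect_true(attr(val, "clamped"))
  expect_error(fit_Dn(m, c(0.1, 0.3)), "fewer than 4")
})

test_that("osmotic permeability is the exact unit conversion of D_n", {
  expect_equal(osmotic_permeability(0), 0)
  expect_equal(osmotic_permeability(1, v_w = 3.0e-23), 3.0e-14)
  expect_equal(osmotic_permeability(2.5), 2 * osmotic_permeability(1.25))
  expect_error(osmotic_permeability(-1), "non-negative")
})

test_that("permeation events follow the reset-and-radius rules", {
  rg <- default_region()
  # monotone up-traversal: one +z event
  w1 <- window_from_z(seq(-12, 12, by = 0.5))
  expect_equal(permeation_events(w1, water_topology(1), rg),
               c(up = 1, down = 0))
  # entering to mid-channel then retreating: no event
  w2 <- window_from_z(c(seq(-12, 0, by = 0.5), seq(0, -12, by = -0.5)))
  expect_equal(permeation_events(w2, water_topology(1), rg),
               c(up = 0, down = 0))
  # a pass that strays outside the cylinder radius mid-channel is invalid
  nf <- 49
  z <- seq(-12, 12, length.out = nf)
  xy_path <- matrix(0, nf, 2)
  xy_path[25, 1] <- rg$radius + 1
  co <- array(0, dim = c(nf, 3, 3))
  co[, 1, 1] <- xy_path[, 1]; co[, 1, 3] <- z
  co[, 2, ] <- co[, 1, ]; co[, 3, ] <- co[, 1, ]
  w3 <- trajectory_window((0:(nf - 1)) * 0.01, co, unwrapped = TRUE)
  expect_equal(permeation_events(w3, water_topology(1), rg),
               c(up = 0, down = 0))
})

test_that("scripted dithered traversals match the hand count exactly", {
  set.seed(31)
  rg <- default_region()
  nw <- 50
  nf <- 301
  z <- matrix(0, nf, nw)
  dirs <- rep(c(1, -1), length.out = nw)  # 25 up, 25 down by construction
  for (j in 1:nw) {
    base <- seq(-13, 13, length.out = nf) * dirs[j]
    z[, j] <- base + rnorm(nf, sd = 0.05)
    z[1, j] <- base[1]; z[nf, j] <- base[nf]
  }
  w <- window_from_z(z)
  ev <- permeation_events(w, water_topology(nw), rg)
  expect_equal(ev, c(up = 25, down = 25))
  pw <- permeation_events(w, water_topology(nw), rg, per_water = TRUE)
  expect_equal(pw$up, as.integer(dirs == 1))
  expect_equal(pw$down, as.integer(dirs == -1))
})

test_that("self-diffusivity classifies ballistic, diffusive and frozen motion", {
  rg <- default_region()
  # ballistic: exponent exactly 2
  wball <- window_from_z(seq(-12, 12, by = 0.1))
  rb <- self_diffusivity_z(wball, water_topology(1), rg)
  expect_false(rb$empty)
  expect_equal(rb$fickian_exponent, 2, tolerance = 1e-6)
  # frozen waters: no passage, flagged empty (not an error)
  wfrozen <- window_from_z(matrix(0, 50, 2))
  rf <- self_diffusivity_z(wfrozen, water_topology(2), rg)
  expect_true(rf$empty)
  expect_true(is.na(rf$D_self))
  # free random walks (reservoir-confined pool; channel long relative to the
  # diffusion length at the fitted lags, so segment conditioning is
  # negligible): exponent ~1, D within 20%
  spec <- synth_spec(waters_per_pore = 8, water_D = 0.2, duration = 100,
                     dt_frame = 0.01, residues = NULL, seed = 19,
                     channel_z = c(-40, 40), confinement = "reservoir")
  sim <- simulate_system(spec)
  rr <- self_diffusivity_z(sim$window, sim$topology, sim$regions$A,
                           max_lag = 0.2)
  expect_false(rr$empty)
  expect_lt(abs(rr$fickian_exponent - 1), 0.1)
  expect_lt(abs(rr$D_self - 0.2) / 0.2, 0.2)
})

test_that("time reversal negates n increments and preserves D_n", {
  spec <- synth_spec(duration = 10, dt_frame = 0.01, waters_per_pore = 5,
                     residues = NULL, seed = 51)
  sim <- simulate_system(spec)
  win <- unwrap_trajectory(sim$window)
  rg <- sim$regions$A
  ns <- collective_coordinate(win, sim$topology, rg)
  rev_win <- win
  rev_win$coords <- win$coords[rev(seq_len(dim(win$coords)[1])), , , drop = FALSE]
  ns_r <- collective_coordinate(rev_win, sim$topology, rg)
  expect_equal(diff(ns_r$n), -rev(diff(ns$n)), tolerance = 1e-12)
  m <- msd_multi_origin(ns$n, ns$time, 0.2)
  mr <- msd_multi_origin(ns_r$n, ns_r$time, 0.2)
  expect_equal(as.numeric(fit_Dn(m)), as.numeric(fit_Dn(mr)), tolerance = 1e-12)
})

test_that("p_f is invariant under rigid translation of system and region", {
  spec <- synth_spec(duration = 5, dt_frame = 0.01, waters_per_pore = 5,
                     residues = NULL, seed = 52)
  sim <- simulate_system(spec)
  win <- unwrap_trajectory(sim$window)
  rg <- sim$regions$B
  pf0 <- pore_permeability(win, sim$topology, rg, max_lag = 0.2,
                           include_self = FALSE)$p_f
  shift <- c(3, -2, 7)
  win2 <- win
  for (d in 1:3) win2$coords[, , d] <- win$coords[, , d] + shift[d]
  win2$origin <- win$origin + shift
  rg2 <- channel_region(rg$pore_label, rg$center_xy + shift[1:2], rg$radius,
                        rg$z_lo + shift[3], rg$z_hi + shift[3])
  pf1 <- pore_permeability(win2, sim$topology, rg2, max_lag = 0.2,
                           include_self = FALSE)$p_f
  expect_equal(pf0, pf1, tolerance = 1e-12)
})

test_that("net collective displacement is consistent with net event counts", {
  # drift trajectory: waters pushed steadily upward
  set.seed(61)
  rg <- default_region()
  nw <- 6; nf <- 2001
  z <- matrix(0, nf, nw)
  z[1, ] <- runif(nw, -14, 14)
  for (i in 2:nf)
    z[i, ] <- z[i - 1, ] + 0.02 + rnorm(nw, sd = 0.1)
  w <- window_from_z(z)
  ns <- collective_coordinate(w, water_topology(nw), rg)
  ev <- permeation_events(w, water_topology(nw), rg)
  net <- abs(as.numeric(ev["up"]) - as.numeric(ev["down"]))
  expect_gte(abs(ns$n[nf]) + 1, net)
  expect_gt(ns$n[nf], 0)
})
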