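test_that("topology invariants are enforced", {
  top <- water_topology(2)
  expect_s3_class(top, "aq_topology")
  bad <- top$atoms
  bad$atom_id[2] <- bad$atom_id[1]
  expect_error(aq_topology(bad), "duplicate atom_id")
  bad2 <- top$atoms[-2, ]  # water with 2 atoms
  bad2$atom_id <- seq_len(nrow(bad2)) - 1L
  expect_error(aq_topology(bad2), "exactly 3 atoms")
  bad3 <- top$atoms
  bad3$charge[1] <- -0.8
  expect_error(aq_topology(bad3), "neutral")
})

test_that("topology + charge table round-trips through PDB", {
  spec <- synth_spec(duration = 0.5, dt_frame = 0.01, waters_per_pore = 3,
                     seed = 21)
  sim <- simulate_system(spec)
  d <- withr::local_tempdir()
  frame1 <- sim$window$coords[1, , ]
  write_topology(sim$topology, frame1, file.path(d, "s.pdb"),
                 file.path(d, "q.txt"))
  back <- read_topology(file.path(d, "s.pdb"), file.path(d, "q.txt"))
  for (cn in c("atom_id", "name", "residue_name", "residue_id", "pore_label",
               "is_heavy", "is_water"))
    expect_identical(back$atoms[[cn]], sim$topology$atoms[[cn]])
  expect_equal(back$atoms$charge, sim$topology$atoms$charge, tolerance = 1e-9)
  expect_equal(attr(back, "coords"), unname(frame1), tolerance = 2e-3)
})

test_that("missing charge entries are reported by (residue_name, atom_name)", {
  spec <- synth_spec(duration = 0.1, dt_frame = 0.01, waters_per_pore = 2,
                     residues = NULL, seed = 5)
  sim <- simulate_system(spec)
  d <- withr::local_tempdir()
  frame1 <- sim$window$coords[1, , ]
  write_topology(sim$topology, frame1, file.path(d, "s.pdb"),
                 file.path(d, "q.txt"))
  ct <- read.table(file.path(d, "q.txt"), header = TRUE)
  write.table(ct[ct$atom_name != "OH2", ], file.path(d, "q2.txt"),
              row.names = FALSE, quote = FALSE)
  expect_error(read_topology(file.path(d, "s.pdb"), file.path(d, "q2.txt")),
               "HOH OH2")
})

test_that("DCD round trip preserves coordinates to float precision", {
  spec <- synth_spec(duration = 0.2, dt_frame = 0.01, waters_per_pore = 4,
                     residues = NULL, seed = 2)
  sim <- simulate_system(spec)
  d <- withr::local_tempdir()
  path <- file.path(d, "t.dcd")
  write_trajectory(sim$window, path)
  back <- read_trajectory(path, sim$topology, origin = c(0, 0, 0))
  expect_equal(dim(back$coords), dim(sim$window$coords))
  expect_lt(max(abs(back$coords - sim$window$coords)), 1e-3)
  expect_false(back$unwrapped)
  expect_equal(diff(back$times)[1], 0.01, tolerance = 1e-6)
})

test_that("DCD reader rejects truncation and atom-count mismatch", {
  spec <- synth_spec(duration = 0.2, dt_frame = 0.01, waters_per_pore = 4,
                     residues = NULL, seed = 2)
  sim <- simulate_system(spec)
  d <- withr::local_tempdir()
  path <- file.path(d, "t.dcd")
  write_trajectory(sim$window, path)
  # truncate mid-frame: no partial frame may be returned
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  writeBin(raw[1:(sz - 10)], file.path(d, "trunc.dcd"))
  expect_error(read_trajectory(file.path(d, "trunc.dcd"), sim$topology),
               "truncated")
  expect_error(read_trajectory(path, water_topology(2)), "mismatch")
})

test_that("unwrap removes single boundary jumps and is identity on continuous input", {
  # particle crossing +z of an 80 A box: wrapped 79 -> 1 becomes 79 -> 81
  w <- window_from_z(c(79, 1), box = c(Inf, Inf, 80), unwrapped = FALSE)
  uw <- unwrap_trajectory(w)
  expect_equal(uw$coords[, 1, 3], c(79, 81))
  cont <- window_from_z(seq(0, 5, by = 0.5), box = c(Inf, Inf, 80))
  cont$unwrapped <- FALSE
  expect_equal(unwrap_trajectory(cont)$coords, cont$coords)
})

test_that("unwrap recovers the generator's ground-truth random walk exactly", {
  spec <- synth_spec(duration = 5, dt_frame = 0.01, waters_per_pore = 5,
                     residues = NULL, seed = 33)
  sim <- simulate_system(spec)
  expect_false(sim$window$unwrapped)
  uw <- unwrap_trajectory(sim$window)
  a <- sim$topology$atoms
  ox <- which(a$is_water & grepl("^O", a$name))
  expect_equal(unname(uw$coords[, ox, 3]),
               unname(sim$truth$waters$z_unwrapped), tolerance = 1e-10)
  # unwrap then rewrap recovers the original wrapped coordinates
  rw <- wrap_trajectory(uw)
  expect_equal(rw$coords, sim$window$coords, tolerance = 1e-9)
})

test_that("channel water selection matches a brute-force cylinder test", {
  set.seed(9)
  n <- 100
  z <- matrix(runif(n, -15, 15), 1)
  xy <- cbind(runif(n, -6, 6), runif(n, -6, 6))
  w <- window_from_z(z, xy = xy)
  top <- water_topology(n)
  rg <- default_region()
  got <- select_channel_waters(w, top, rg, 1)
  brute <- which(z[1, ] >= rg$z_lo & z[1, ] < rg$z_hi &
                   sqrt(xy[, 1]^2 + xy[, 2]^2) <= rg$radius)
  expect_identical(got, sort(top$atoms$residue_id[3 * (brute - 1) + 1]))
  # purity: same frame, same set
  expect_identical(got, select_channel_waters(w, top, rg, 1))
})

test_that("selection boundaries are half-open in z and inclusive in radius", {
  rg <- default_region()
  w <- window_from_z(matrix(c(0, rg$z_hi, rg$z_lo), 1),
                     xy = rbind(c(0, 0), c(0, 0), c(rg$radius, 0)))
  top <- water_topology(3)
  got <- select_channel_waters(w, top, rg, 1)
  expect_true(1 %in% got)        # centre included
  expect_false(2 %in% got)       # z = z_hi excluded (half-open)
  expect_true(3 %in% got)        # on-radius included, z = z_lo included
})

test_that("non-uniform frame spacing is rejected", {
  co <- array(0, dim = c(3, 1, 3))
  expect_error(trajectory_window(c(0, 0.01, 0.03), co), "non-uniform")
})
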