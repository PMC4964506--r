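## synthetic_data: ground-truth-known topologies and trajectories emulating
## the statistical structure the analysis assumes (independent Brownian
## channel waters, two-state telegraph residue dipoles biased by a
## perpendicular field, scripted heavy-atom rearrangements).

# ---------------------------------------------------------------------------
# Field protocol
# ---------------------------------------------------------------------------

#' Define an external electric-field protocol
#'
#' A uniform field along `direction` with peak intensity `E0`, applied as a
#' 10 ns-style square pulse (`static`) or a Gaussian envelope.
#'
#' @param direction length-3 vector; normalised internally. Default `+y`,
#'   i.e. perpendicular to the pore axis (z).
#' @param E0 peak intensity, V/Angstrom (>= 0). The study conditions use
#'   0.012, 0.02, 0.035, 0.05 and 0.065 V/A.
#' @param duration pulse duration, ns (default 10).
#' @param envelope `"static"` or `"gaussian"`.
#' @param gaussian_center,gaussian_sigma Gaussian envelope parameters (ns);
#'   defaults centre the pulse and put ~3 sigma inside the duration.
#' @return Object of class `aq_field`.
#' @export
field_protocol <- function(direction = c(0, 1, 0), E0 = 0, duration = 10,
                           envelope = c("static", "gaussian"),
                           gaussian_center = duration / 2,
                           gaussian_sigma = duration / 6) {
  envelope <- match.arg(envelope)
  if (E0 < 0) stop("E0 must be non-negative")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  structure(list(direction = as.numeric(direction) / nrm, E0 = E0,
                 duration = duration, envelope = envelope,
                 gaussian_center = gaussian_center,
                 gaussian_sigma = gaussian_sigma),
            class = "aq_field")
}

#' Field intensity at a time point
#'
#' @param protocol `aq_field`.
#' @param t time (ns), scalar or vector.
#' @return E(t) in V/A: `E0` inside `[0, duration]` for the static envelope
#'   (0 outside), or the Gaussian `E0 * exp(-(t - c)^2 / (2 sigma^2))`.
#' @export
field_intensity <- function(protocol, t) {
  if (protocol$envelope == "static") {
    protocol$E0 * as.numeric(t >= 0 & t <= protocol$duration)
  } else {
    protocol$E0 * exp(-(t - protocol$gaussian_center)^2 /
                        (2 * protocol$gaussian_sigma^2))
  }
}

#' Force exerted by the field on a partial charge
#'
#' The field couples to atomic partial charges as `f_ia = q_ia * E(t)` along
#' the field direction.
#'
#' @param charge partial charge (e).
#' @param protocol `aq_field`.
#' @param t time (ns, scalar).
#' @return Length-3 force vector in eV/A.
#' @export
field_force <- function(charge, protocol, t) {
  if (t < 0) stop("t must be non-negative")
  charge * field_intensity(protocol, t) * protocol$direction
}

# ---------------------------------------------------------------------------
# Synthetic system specification
# ---------------------------------------------------------------------------

#' Default gating-residue set for the synthetic tetramer
#'
#' One dumbbell residue per gate site per pore: the selectivity-filter /
#' upper-gate residues SER-211, HSD-201 and ARG-216 near the extracellular
#' channel mouth and the lower-gate residues HSD-95 and CYS-178 near the
#' cytoplasmic mouth. Dipole magnitudes are representative side-chain values
#' (Debye); `cos_amp` is the magnitude of cos(theta) in the two telegraph
#' states; `flip_rate_zero_field` is the zero-field switching rate (1/ns) and
#' `flip_barrier` (kT) caps the field-induced barrier reduction.
#'
#' @return data.frame with one row per residue.
#' @export
default_gating_residues <- function() {
  data.frame(
    resname = c("SER", "HSD", "ARG", "HSD", "CYS"),
    resno   = c(211L, 201L, 216L, 95L, 178L),
    z_pos   = c(8, 8, 8, -8, -8),
    dipole_D = c(2.1, 3.7, 5.4, 3.7, 1.6),
    cos_amp = 0.7,
    flip_rate_zero_field = 0.5,
    flip_barrier = 6,
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic four-pore channel system
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: four independent pores along z, each holding `waters_per_pore`
#' non-interacting waters with known 1D diffusivity, plus gating residues
#' whose dipoles undergo two-state telegraph flipping biased by the field.
#' The same seed and spec always reproduce the same trajectories.
#'
#' @param waters_per_pore number of in-channel waters N per pore.
#' @param water_D true 1D water diffusivity, A^2/ps.
#' @param channel_radius,channel_z cylinder radius (A) and z bounds
#'   (length 2, A) shared by the four pores.
#' @param pore_centers 4 x 2 matrix of pore axis positions (A).
#' @param residues data.frame as [default_gating_residues()]; may have zero
#'   rows for water-only systems.
#' @param field `aq_field` protocol.
#' @param duration trajectory length (ns).
#' @param dt_frame frame spacing (ns).
#' @param seed integer; fully determines the output.
#' @param confinement `"periodic"`: waters live on a z-ring of circumference
#'   L (the channel at steady state, in-channel occupancy exactly N; the
#'   independent-particle identity D_n = N D / L^2 is then exact and serves
#'   as the analysis oracle). `"reservoir"`: reflecting walls
#'   `reservoir_pad` A beyond each channel mouth with free passage through
#'   the channel (used for permeation-event realism).
#' @param reservoir_pad reservoir slab thickness (A, default 20).
#' @param thermal_jitter per-atom Gaussian positional noise sd (A) added to
#'   residue atoms (0 = clean ground truth).
#' @param gating optional list `(enabled, scale, threshold)`: when enabled,
#'   water diffusivity is scaled by `scale` whenever the instantaneous field
#'   intensity is at least `threshold` V/A — a qualitative stand-in for
#'   dipolar-gating-reduced permeability.
#' @param rmsd_injections optional data.frame
#'   `(pore_label, residue, displacement, onset)` of scripted rigid
#'   heavy-atom displacements (A, ns); `residue` is a `"SER-211"`-style label.
#' @param box_xy lateral box length (A).
#' @return Object of class `aq_synth_spec`.
#' @export
synth_spec <- function(waters_per_pore = 10, water_D = 0.2,
                       channel_radius = 4, channel_z = c(-10, 10),
                       pore_centers = rbind(A = c(-15, -15), B = c(15, -15),
                                            C = c(-15, 15), D = c(15, 15)),
                       residues = default_gating_residues(),
                       field = field_protocol(E0 = 0),
                       duration = 10, dt_frame = 0.01, seed = 1,
                       confinement = c("periodic", "reservoir"),
                       reservoir_pad = 20, thermal_jitter = 0,
                       gating = list(enabled = FALSE, scale = 0.5,
                                     threshold = 0.035),
                       rmsd_injections = NULL, box_xy = 80) {
  confinement <- match.arg(confinement)
  if (waters_per_pore < 1 || waters_per_pore > 499)
    stop("waters_per_pore must be in 1..499")
  if (water_D < 0) stop("water_D must be non-negative")
  if (!is.null(residues) && nrow(residues) > 0) {
    if (any(residues$dipole_D < 0)) stop("dipole magnitudes must be >= 0")
  }
  structure(list(
    n_pores = 4L, pore_labels = c("A", "B", "C", "D"),
    waters_per_pore = as.integer(waters_per_pore), water_D = water_D,
    channel_radius = channel_radius, channel_z = as.numeric(channel_z),
    pore_centers = pore_centers, residues = residues, field = field,
    duration = duration, dt_frame = dt_frame, seed = as.integer(seed),
    confinement = confinement, reservoir_pad = reservoir_pad,
    thermal_jitter = thermal_jitter, gating = gating,
    rmsd_injections = rmsd_injections, box_xy = box_xy
  ), class = "aq_synth_spec")
}

#' Channel regions of a synthetic spec
#'
#' @param spec `aq_synth_spec`.
#' @return Named list of four `aq_channel` objects (pores A-D).
#' @export
synth_regions <- function(spec) {
  out <- lapply(seq_len(4), function(p)
    channel_region(spec$pore_labels[p], spec$pore_centers[p, ],
                   spec$channel_radius, spec$channel_z[1], spec$channel_z[2]))
  names(out) <- spec$pore_labels
  out
}

#' @keywords internal
.derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + 7919 * tag) %% 2147483647)
}

# residue_id scheme: pore p (0-based): waters p*1000 + 1..N,
# residues p*1000 + 500 + resno (resno < 500 assumed)
#' @keywords internal
.water_rid <- function(p, i) (p - 1L) * 1000L + i

#' @keywords internal
.res_rid <- function(p, resno) (p - 1L) * 1000L + 500L + as.integer(resno)

# TIP3P-like rigid H offsets relative to O (A)
.h_offsets <- rbind(c(0.9572, 0, 0),
                    c(-0.2399872, 0.9266272, 0))

#' @keywords internal
.synth_times <- function(spec) {
  nsteps <- round(spec$duration / spec$dt_frame)
  (0:nsteps) * spec$dt_frame
}

#' @keywords internal
.synth_box <- function(spec) {
  L <- spec$channel_z[2] - spec$channel_z[1]
  Lz <- if (spec$confinement == "periodic") L else L + 2 * spec$reservoir_pad
  c(spec$box_xy, spec$box_xy, Lz)
}

#' @keywords internal
.synth_origin <- function(spec) {
  zlo <- if (spec$confinement == "periodic") spec$channel_z[1]
  else spec$channel_z[1] - spec$reservoir_pad
  c(-spec$box_xy / 2, -spec$box_xy / 2, zlo)
}

# build the topology rows for waters (+ optionally residues)
#' @keywords internal
.synth_topology <- function(spec, include_residues = TRUE) {
  rows <- list()
  for (p in seq_len(4)) {
    lab <- spec$pore_labels[p]
    for (i in seq_len(spec$waters_per_pore)) {
      rid <- .water_rid(p, i)
      rows[[length(rows) + 1L]] <- data.frame(
        # HOH: 3-character water residue name (fixed-column PDB safe);
        # charges are the TIP3P values
        name = c("OH2", "H1", "H2"), residue_name = "HOH",
        residue_id = rid, pore_label = lab,
        mass = c(15.9994, 1.008, 1.008),
        charge = c(-0.834, 0.417, 0.417),
        is_heavy = c(TRUE, FALSE, FALSE), is_water = TRUE,
        stringsAsFactors = FALSE)
    }
    if (include_residues && !is.null(spec$residues) && nrow(spec$residues) > 0) {
      for (r in seq_len(nrow(spec$residues))) {
        rr <- spec$residues[r, ]
        rid <- .res_rid(p, rr$resno)
        q <- rr$dipole_D * .debye() / 0.5  # dumbbell separation 0.5 A
        rows[[length(rows) + 1L]] <- data.frame(
          name = c("C1", "C2"), residue_name = rr$resname,
          residue_id = rid, pore_label = lab,
          mass = 12.011, charge = c(q, -q),
          is_heavy = TRUE, is_water = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms <- cbind(atom_id = seq_len(nrow(atoms)) - 1L, atoms)
  aq_topology(atoms)
}

# ---------------------------------------------------------------------------
# Water dynamics
# ---------------------------------------------------------------------------

#' Simulate the in-channel water trajectories of a synthetic spec
#'
#' Each water oxygen performs independent 1D Brownian motion along z with
#' Gaussian steps of variance `2 * water_D * dt` per frame interval; lateral
#' positions are static offsets inside the cylinder radius; hydrogens ride
#' rigidly on their oxygen. Under `confinement = "periodic"` (default) waters
#' occupy the channel permanently (z-ring of circumference L); under
#' `"reservoir"` they reflect off walls `reservoir_pad` A beyond each mouth
#' and pass freely through the channel. When gating is enabled, the
#' diffusivity is scaled by `gating$scale` whenever the field intensity
#' reaches `gating$threshold`.
#'
#' @param spec `aq_synth_spec`.
#' @return List: `window` (`aq_trajectory`, water atoms only; wrapped in
#'   periodic mode), `topology` (waters only), `truth` (ground truth:
#'   unwrapped z matrix `[frames x waters]` with columns named by
#'   residue_id, true `water_D`, per-step effective diffusivity).
#' @export
simulate_channel_waters <- function(spec) {
  set.seed(.derive_seed(spec$seed, 1L))
  top <- .synth_topology(spec, include_residues = FALSE)
  times <- .synth_times(spec)
  nf <- length(times); nsteps <- nf - 1L
  N <- spec$waters_per_pore; ntot <- 4L * N
  dt_ps <- spec$dt_frame * 1000
  zlo <- spec$channel_z[1]; zhi <- spec$channel_z[2]; L <- zhi - zlo

  # per-step effective diffusivity (gating scales D during the field window)
  Dstep <- rep(spec$water_D, max(nsteps, 1L))
  if (isTRUE(spec$gating$enabled) && nsteps > 0) {
    Emid <- field_intensity(spec$field, (times[-nf] + times[-1]) / 2)
    Dstep[Emid >= spec$gating$threshold] <-
      spec$water_D * spec$gating$scale
  }
  sd_step <- sqrt(2 * Dstep * dt_ps)

  z0 <- stats::runif(ntot, zlo, zhi)
  ang <- stats::runif(ntot, 0, 2 * pi)
  rad <- spec$channel_radius * 0.8 * sqrt(stats::runif(ntot))
  if (nsteps > 0) {
    steps <- matrix(stats::rnorm(nsteps * ntot), nsteps, ntot) * sd_step
    z_true <- rbind(z0, sweep(apply(steps, 2, cumsum), 2, z0, "+"))
    if (nsteps == 1) z_true <- rbind(z0, z0 + steps[1, ])
  } else z_true <- matrix(z0, 1, ntot)
  dimnames(z_true) <- NULL

  if (spec$confinement == "periodic") {
    z_out <- zlo + (z_true - zlo) - L * floor((z_true - zlo) / L)
    unwrapped <- FALSE
  } else {
    a <- zlo - spec$reservoir_pad; b <- zhi + spec$reservoir_pad
    P <- b - a
    w <- (z_true - a) %% (2 * P)
    z_out <- a + ifelse(w <= P, w, 2 * P - w)
    z_true <- z_out  # the reflected path is the physical (continuous) one
    unwrapped <- TRUE
  }

  # assemble coordinates: per water O + 2 rigid H
  pore_of <- rep(seq_len(4), each = N)
  ox <- spec$pore_centers[pore_of, 1] + rad * cos(ang)
  oy <- spec$pore_centers[pore_of, 2] + rad * sin(ang)
  na <- 3L * ntot
  co <- array(0, dim = c(nf, na, 3))
  o_idx <- 3L * (seq_len(ntot) - 1L) + 1L
  co[, o_idx, 1] <- matrix(ox, nf, ntot, byrow = TRUE)
  co[, o_idx, 2] <- matrix(oy, nf, ntot, byrow = TRUE)
  co[, o_idx, 3] <- z_out
  for (h in 1:2) {
    co[, o_idx + h, 1] <- co[, o_idx, 1] + .h_offsets[h, 1]
    co[, o_idx + h, 2] <- co[, o_idx, 2] + .h_offsets[h, 2]
    co[, o_idx + h, 3] <- co[, o_idx, 3] + .h_offsets[h, 3]
  }

  window <- trajectory_window(times, co, unwrapped = unwrapped,
                              box = .synth_box(spec),
                              origin = .synth_origin(spec))
  rids <- .water_rid(pore_of, rep(seq_len(N), times = 4))
  colnames(z_true) <- rids
  list(window = window, topology = top,
       truth = list(z_unwrapped = z_true, water_D = spec$water_D,
                    D_step = Dstep, residue_ids = rids,
                    pore_label = spec$pore_labels[pore_of]))
}

# ---------------------------------------------------------------------------
# Residue dipole dynamics (two-state telegraph)
# ---------------------------------------------------------------------------

# exact continuous-time telegraph over piecewise-constant rate segments.
# seg: data.frame(t0, t1, k_to_plus, k_to_minus). Returns transition times
# and the state at requested sample times. state in {+1, -1}.
#' @keywords internal
.telegraph <- function(seg, sample_times, state0) {
  state <- state0
  t_cur <- seg$t0[1]
  ev_t <- numeric(0); ev_to <- integer(0)
  for (i in seq_len(nrow(seg))) {
    t_end <- seg$t1[i]
    repeat {
      k_leave <- if (state > 0) seg$k_to_minus[i] else seg$k_to_plus[i]
      if (k_leave <= 0) { t_cur <- t_end; break }
      wait <- stats::rexp(1, k_leave)
      if (t_cur + wait >= t_end) { t_cur <- t_end; break }
      t_cur <- t_cur + wait
      state <- -state
      ev_t <- c(ev_t, t_cur); ev_to <- c(ev_to, state)
    }
  }
  st <- rep(state0, length(sample_times))
  if (length(ev_t) > 0) {
    idx <- findInterval(sample_times, ev_t)
    states_after <- c(state0, ev_to)
    st <- states_after[idx + 1L]
  }
  list(times = ev_t, to_state = ev_to, states = st)
}

# rate segments for a residue under the protocol
#' @keywords internal
.rate_segments <- function(spec, mu_eA, s, ts_proj, k0, barrier, times) {
  Tend <- max(times)
  kT <- .kT()
  if (spec$field$envelope == "static") {
    bounds <- sort(unique(c(0, min(spec$field$duration, Tend), Tend)))
  } else {
    bounds <- times
  }
  t0 <- bounds[-length(bounds)]; t1 <- bounds[-1]
  Emid <- field_intensity(spec$field, (t0 + t1) / 2)
  x <- mu_eA * Emid * s / kT
  gain <- exp(pmin(mu_eA * Emid * ts_proj, barrier * kT) / kT)
  data.frame(t0 = t0, t1 = t1,
             k_to_plus = k0 * gain * exp(x / 2),
             k_to_minus = k0 * gain * exp(-x / 2))
}

#' Simulate residue dipole flipping for a synthetic spec
#'
#' Each residue's dipole is a telegraph process between two orientations with
#' cos(theta) = +c and -c against the +z axis. The field (along +/-y) biases
#' the switching rates `k_into_state = k0 * g * exp(+/- mu E s / 2 kT)`
#' where `s` is the projection of the flip axis onto the field direction, so
#' the stationary occupancy ratio is the Boltzmann factor `exp(mu E s / kT)`.
#' The common gain `g = exp(min(mu E s_ts, barrier kT) / kT)` models
#' field-stabilisation of the transition state (the flip path passes through
#' the orientation best aligned with the field, `s_ts = sqrt(1 - s^2)`), so
#' switching accelerates with intensity while the occupancy bias is
#' unaffected. Atom coordinates are dumbbells placed so that the dipole
#' computed from the charges reproduces the ground-truth orientation exactly.
#'
#' @param spec `aq_synth_spec` with a non-empty residue table.
#' @return List: `window` (`aq_trajectory` of residue atoms, unwrapped),
#'   `topology` (residue atoms only... full ids match [simulate_system()]),
#'   `truth`: per residue the exact transition times, sampled states, the
#'   cos(theta) ground truth, rates used and theoretical occupancy.
#' @export
simulate_residue_dipoles <- function(spec) {
  if (is.null(spec$residues) || nrow(spec$residues) == 0)
    stop("spec has no residues")
  set.seed(.derive_seed(spec$seed, 2L))
  times <- .synth_times(spec)
  nf <- length(times)
  kT <- .kT()
  dirv <- spec$field$direction
  nres <- nrow(spec$residues)
  natoms <- 2L * nres * 4L

  rows <- list(); truth <- list()
  co <- array(0, dim = c(nf, natoms, 3))
  ai <- 0L
  for (p in seq_len(4)) {
    lab <- spec$pore_labels[p]
    for (r in seq_len(nres)) {
      rr <- spec$residues[r, ]
      cc <- rr$cos_amp
      w <- c(0, sqrt(1 - cc^2), cc)          # flip axis: states are +/- w
      s <- sum(w * dirv)
      ts_proj <- sqrt(max(0, 1 - s^2))
      mu_eA <- rr$dipole_D * .debye()
      seg <- .rate_segments(spec, mu_eA, s, ts_proj,
                            rr$flip_rate_zero_field, rr$flip_barrier, times)
      state0 <- if (stats::runif(1) < 0.5) 1L else -1L
      tg <- .telegraph(seg, times, state0)
      com <- c(spec$pore_centers[p, 1] + spec$channel_radius,
               spec$pore_centers[p, 2], rr$z_pos)
      u <- outer(tg$states, w)               # [nf x 3] dipole direction
      sep <- 0.5
      a1 <- ai + 1L; a2 <- ai + 2L
      for (d in 1:3) {
        co[, a1, d] <- com[d] + (sep / 2) * u[, d]
        co[, a2, d] <- com[d] - (sep / 2) * u[, d]
      }
      if (spec$thermal_jitter > 0) {
        co[, c(a1, a2), ] <- co[, c(a1, a2), ] +
          stats::rnorm(nf * 2 * 3, sd = spec$thermal_jitter)
      }
      rid <- .res_rid(p, rr$resno)
      label <- paste0(rr$resname, "-", rr$resno)
      truth[[paste(lab, label)]] <- list(
        pore_label = lab, residue = label, residue_id = rid,
        transition_times = tg$times, states = tg$states,
        cos_theta = tg$states * cc, cos_amp = cc,
        s = s, mu_eA = mu_eA,
        k_field = utils::head(seg[seg$t0 < min(spec$field$duration, max(times)), ], 1),
        occupancy_ratio_theory = exp(mu_eA * spec$field$E0 * s / kT))
      ai <- ai + 2L
    }
  }
  top <- .synth_topology(spec, include_residues = TRUE)
  ra <- top$atoms[!top$atoms$is_water, ]
  window <- trajectory_window(times, co, unwrapped = TRUE,
                              box = .synth_box(spec),
                              origin = .synth_origin(spec))
  list(window = window, residue_atoms = ra, truth = truth)
}

# ---------------------------------------------------------------------------
# Full system + injections
# ---------------------------------------------------------------------------

#' Simulate a complete synthetic system (waters + residues)
#'
#' Runs [simulate_channel_waters()] and [simulate_residue_dipoles()] with
#' seeds derived from `spec$seed`, merges them into one topology/trajectory,
#' and applies any scripted rearrangement injections.
#'
#' @param spec `aq_synth_spec`.
#' @return List: `topology`, `window` (wrapped in periodic mode), `truth`
#'   (water and dipole ground truth plus injections), `regions`
#'   (list of four `aq_channel`), `spec`.
#' @export
simulate_system <- function(spec) {
  wat <- simulate_channel_waters(spec)
  has_res <- !is.null(spec$residues) && nrow(spec$residues) > 0
  top <- .synth_topology(spec, include_residues = has_res)
  nf <- length(.synth_times(spec))
  na <- nrow(top$atoms)
  co <- array(0, dim = c(nf, na, 3))
  wat_idx <- which(top$atoms$is_water)
  co[, wat_idx, ] <- wat$window$coords
  dip_truth <- NULL
  if (has_res) {
    dip <- simulate_residue_dipoles(spec)
    co[, which(!top$atoms$is_water), ] <- dip$window$coords
    dip_truth <- dip$truth
  }
  window <- trajectory_window(wat$window$times, co,
                              unwrapped = wat$window$unwrapped,
                              box = .synth_box(spec),
                              origin = .synth_origin(spec))
  if (!is.null(spec$rmsd_injections) && nrow(spec$rmsd_injections) > 0)
    window <- inject_rearrangement(window, top, spec$rmsd_injections)
  list(topology = top, window = window,
       truth = list(waters = wat$truth, dipoles = dip_truth,
                    injections = spec$rmsd_injections),
       regions = synth_regions(spec), spec = spec)
}

#' Inject a scripted heavy-atom rearrangement
#'
#' From the onset time onward, displaces all heavy atoms of the named residue
#' by a fixed vector of the given magnitude (along +x), on top of whatever
#' dynamics the residue already has. Emulates a conformational rearrangement
#' whose downstream heavy-atom RMSD equals the injected magnitude.
#'
#' @param window `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param injections data.frame with columns `pore_label`, `residue`
#'   (label like `"SER-211"`) or `residue_id`, `displacement` (A), `onset`
#'   (ns).
#' @return Modified `aq_trajectory`.
#' @export
inject_rearrangement <- function(window, topology, injections) {
  a <- topology$atoms
  for (k in seq_len(nrow(injections))) {
    inj <- injections[k, ]
    if (!is.null(inj$residue_id) && !is.na(suppressWarnings(inj$residue_id))) {
      sel <- a$residue_id == inj$residue_id
    } else {
      parts <- strsplit(inj$residue, "-")[[1]]
      sel <- a$pore_label == inj$pore_label &
        a$residue_name == parts[1] &
        (a$residue_id %% 1000L - 500L) == as.integer(parts[2])
    }
    sel <- sel & a$is_heavy
    if (!any(sel))
      stop("injection target not found: ",
           paste(inj$pore_label, inj$residue %||% inj$residue_id))
    frames <- which(window$times >= inj$onset)
    window$coords[frames, which(sel), 1] <-
      window$coords[frames, which(sel), 1] + inj$displacement
  }
  window
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Free-rotor Boltzmann sampler (Langevin-function oracle)
# ---------------------------------------------------------------------------

#' Sample free-rotor dipole orientations in a field
#'
#' Draws cos(theta') of a freely rotating dipole in a uniform field by exact
#' inverse-CDF sampling of the Boltzmann density p(u) proportional to
#' exp(x u) on [-1, 1], with x = mu E / kT. The mean alignment is the
#' Langevin function `coth(x) - 1/x`.
#'
#' @param n number of samples.
#' @param x dimensionless field coupling mu E / kT (>= 0).
#' @return Numeric vector of cos(theta') samples in `[-1, 1]`.
#' @export
sample_free_rotor <- function(n, x) {
  U <- stats::runif(n)
  if (x == 0) return(2 * U - 1)
  1 + log(U + (1 - U) * exp(-2 * x)) / x
}

#' Langevin function
#'
#' Mean field alignment `coth(x) - 1/x` of a free dipole at coupling
#' `x = mu E / kT`; the closed-form oracle for [sample_free_rotor()].
#'
#' @param x coupling (may be a vector; `x = 0` returns 0).
#' @return `coth(x) - 1/x`.
#' @export
langevin_function <- function(x) {
  ifelse(x == 0, 0, 1 / tanh(x) - 1 / x)
}
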