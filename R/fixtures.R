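## Fixture sets: a synthetic system serialised to the on-disk formats the
## package reads back (PDB + charge table + DCD + YAML geometry/field config
## + ground-truth JSON sidecar), for round-trip tests and shell workflows.

#' Write a synthetic system as an on-disk fixture set
#'
#' Serialises a simulated system to `system.pdb` (frame 1),
#' `charges.txt`, `traj.dcd`, `config.yaml` (box, origin, frame spacing,
#' channel regions, field protocol) and `truth.json` (ground truth: true
#' water diffusivity, per-residue transition times and occupancies, injected
#' displacements).
#'
#' @param sim list from [simulate_system()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frame1 <- sim$window$coords[1, , ]
  dim(frame1) <- dim(sim$window$coords)[2:3]
  write_topology(sim$topology, frame1,
                 file.path(dir, "system.pdb"), file.path(dir, "charges.txt"))
  write_trajectory(sim$window, file.path(dir, "traj.dcd"))
  spec <- sim$spec
  cfg <- list(
    dt_frame = spec$dt_frame,
    box = as.numeric(sim$window$box[1, ]),
    origin = sim$window$origin,
    unwrapped = sim$window$unwrapped,
    channels = lapply(sim$regions, function(rg)
      list(pore_label = rg$pore_label, center_xy = rg$center_xy,
           radius = rg$radius, z_lo = rg$z_lo, z_hi = rg$z_hi,
           length_mode = rg$length_mode)),
    field = list(direction = spec$field$direction, E0 = spec$field$E0,
                 duration = spec$field$duration,
                 envelope = spec$field$envelope)
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- sim$truth
  truth$waters$z_unwrapped <- NULL  # large; regenerable from spec + seed
  truth$spec_seed <- spec$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read a fixture set back from disk
#'
#' @param dir directory written by [write_fixture_set()].
#' @return List: `topology`, `window`, `regions`, `config`, `truth`.
#' @export
read_fixture_set <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  top <- read_topology(file.path(dir, "system.pdb"),
                       file.path(dir, "charges.txt"))
  win <- read_trajectory(file.path(dir, "traj.dcd"), top,
                         dt = cfg$dt_frame, box = as.numeric(cfg$box),
                         origin = as.numeric(cfg$origin))
  win$unwrapped <- isTRUE(cfg$unwrapped)
  regions <- lapply(cfg$channels, function(ch)
    channel_region(ch$pore_label, as.numeric(ch$center_xy), ch$radius,
                   ch$z_lo, ch$z_hi, ch$length_mode))
  names(regions) <- vapply(regions, function(r) r$pore_label, "")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(topology = top, window = win, regions = regions, config = cfg,
       truth = truth)
}
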