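## trajio: topologies, trajectory windows, channel regions, selections.
## Coordinates are Angstrom, times ns, charges e. z is the membrane normal.

# ---------------------------------------------------------------------------
# Topology
# ---------------------------------------------------------------------------

#' Construct a topology
#'
#' A topology is the static description of the system: one row per atom with
#' residue assignment, pore label, mass and partial charge. It is the object
#' that carries the `q_ia` used both for field forces and for residue dipole
#' vectors.
#'
#' @param atoms data.frame with columns `atom_id` (integer, dense from 0),
#'   `name`, `residue_name`, `residue_id` (integer, unique per residue across
#'   the whole system), `pore_label` (one of `"A".."D"` or `"none"`), `mass`
#'   (amu), `charge` (e), `is_heavy`, `is_water` (logical).
#' @return Object of class `aq_topology`.
#' @details Invariants enforced: atom ids unique and dense from 0; every
#'   water residue has exactly 3 atoms (O, H, H) and net charge 0 within
#'   1e-9 e; pore labels form a disjoint partition by construction.
#' @export
aq_topology <- function(atoms) {
  req <- c("atom_id", "name", "residue_name", "residue_id", "pore_label",
           "mass", "charge", "is_heavy", "is_water")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("topology is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  ids <- sort(atoms$atom_id)
  if (anyDuplicated(atoms$atom_id))
    stop("duplicate atom_id in topology: ",
         paste(unique(atoms$atom_id[duplicated(atoms$atom_id)]), collapse = ", "))
  if (!identical(as.integer(ids), seq_len(nrow(atoms)) - 1L))
    stop("atom_ids must be dense integers starting at 0")
  if (!all(atoms$pore_label %in% c("A", "B", "C", "D", "none")))
    stop("pore_label must be one of A, B, C, D, none")
  wat <- atoms[atoms$is_water, ]
  if (nrow(wat) > 0) {
    cnt <- table(wat$residue_id)
    if (any(cnt != 3L))
      stop("every water must have exactly 3 atoms (O, H, H); offending residue_id: ",
           paste(names(cnt)[cnt != 3L], collapse = ", "))
    qs <- tapply(wat$charge, wat$residue_id, sum)
    if (any(abs(qs) > 1e-9))
      stop("water residues must be net neutral within 1e-9 e")
  }
  structure(list(atoms = atoms), class = "aq_topology")
}

#' @export
print.aq_topology <- function(x, ...) {
  a <- x$atoms
  cat("aq_topology:", nrow(a), "atoms,",
      length(unique(a$residue_id)), "residues,",
      sum(a$is_water) / 3, "waters; pores:",
      paste(sort(unique(a$pore_label[a$pore_label != "none"])), collapse = ""),
      "\n")
  invisible(x)
}

# element mass lookup keyed on the leading element letter of a PDB atom name
.element_mass <- function(name) {
  el <- sub("^[0-9]*", "", name)
  el <- substr(el, 1L, 1L)
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.9994, S = 32.06, P = 30.974)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}

.water_resnames <- c("TIP3", "TIP", "HOH", "WAT", "SPC", "SOL")

#' Read a topology from a PDB file plus a charge table
#'
#' Parses atom records with [bio3d::read.pdb()] and joins partial charges (and
#' optionally masses) by `(residue_name, atom_name)` from a plain-text table.
#' Waters are auto-detected by residue name (`TIP3`, `HOH`, `WAT`, `SPC`, ...);
#' pore labels are taken from the chain identifier (chains A-D; anything else
#' becomes `"none"`).
#'
#' @param pdb_path path to a PDB file.
#' @param charge_table_path whitespace-delimited table with a header and
#'   columns `residue_name atom_name charge` and optionally `mass`.
#' @return `aq_topology`; the coordinates of the PDB frame are attached as
#'   attribute `"coords"` (matrix natoms x 3).
#' @export
read_topology <- function(pdb_path, charge_table_path) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  a <- pdb$atom
  ct <- utils::read.table(charge_table_path, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("residue_name", "atom_name", "charge") %in% names(ct)))
    stop("charge table needs columns residue_name, atom_name, charge")
  key <- paste(a$resid, a$elety)
  idx <- match(key, paste(ct$residue_name, ct$atom_name))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("charge table has no entry for: ", paste(bad, collapse = "; "))
  }
  if (anyDuplicated(a$eleno))
    stop("duplicate atom_id in PDB: ",
         paste(unique(a$eleno[duplicated(a$eleno)]), collapse = ", "))
  mass <- if ("mass" %in% names(ct)) ct$mass[idx] else .element_mass(a$elety)
  # residue_id must be globally unique; keep the PDB resno when it already is
  # (fixture round trips), else number residues densely over (chain, resno)
  key <- paste(a$chain, a$resno)
  rid <- as.integer(factor(key, levels = unique(key))) - 1L
  resno_by_rid <- tapply(a$resno, rid, function(v) v[1])
  if (!anyDuplicated(resno_by_rid)) rid <- a$resno
  atoms <- data.frame(
    atom_id      = seq_len(nrow(a)) - 1L,
    name         = a$elety,
    residue_name = a$resid,
    residue_id   = rid,
    pore_label   = ifelse(a$chain %in% c("A", "B", "C", "D"), a$chain, "none"),
    mass         = mass,
    charge       = ct$charge[idx],
    is_heavy     = !grepl("^[0-9]*H", a$elety),
    is_water     = a$resid %in% .water_resnames,
    stringsAsFactors = FALSE
  )
  top <- aq_topology(atoms)
  attr(top, "coords") <- cbind(a$x, a$y, a$z)
  top
}

#' Write a topology to a PDB file plus a charge table
#'
#' Inverse of [read_topology()]; used by the synthetic-data fixture writer and
#' for round-trip testing.
#'
#' @param topology `aq_topology`.
#' @param coords matrix natoms x 3 (a reference frame, Angstrom).
#' @param pdb_path,charge_table_path output paths.
#' @export
write_topology <- function(topology, coords, pdb_path, charge_table_path) {
  a <- topology$atoms
  coords <- round(coords, 3)  # PDB fixed-format precision
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(coords)),
                   resno = a$residue_id,
                   resid = a$residue_name,
                   eleno = a$atom_id + 1L,
                   elety = a$name,
                   chain = ifelse(a$pore_label == "none", "Z", a$pore_label))
  ct <- unique(data.frame(residue_name = a$residue_name, atom_name = a$name,
                          charge = a$charge, mass = a$mass,
                          stringsAsFactors = FALSE))
  utils::write.table(ct, charge_table_path, row.names = FALSE, quote = FALSE)
  invisible(pdb_path)
}

# ---------------------------------------------------------------------------
# TrajectoryWindow
# ---------------------------------------------------------------------------

#' Construct a trajectory window
#'
#' Time-ordered frames of coordinates with a uniform time step. Displacement
#' based operations (collective coordinate, MSD, RMSD) refuse wrapped input;
#' use [unwrap_trajectory()] first.
#'
#' @param times numeric vector (ns), strictly increasing, uniform spacing
#'   within 1e-6 ns.
#' @param coords array `[n_frames, n_atoms, 3]`, Angstrom.
#' @param unwrapped logical: are coordinates free of periodic jumps?
#' @param box matrix `n_frames x 3` of box lengths (Lx, Ly, Lz) in Angstrom,
#'   or a length-3 vector recycled over frames.
#' @param origin length-3 lower corner of the periodic box (default 0,0,0).
#' @return Object of class `aq_trajectory`.
#' @export
trajectory_window <- function(times, coords, unwrapped = FALSE,
                              box = NULL, origin = c(0, 0, 0)) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an array [n_frames, n_atoms, 3]")
  nf <- dim(coords)[1]
  if (length(times) != nf) stop("length(times) must equal n_frames")
  if (nf > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("non-uniform frame spacing (tolerance 1e-6 ns); resampling is not supported")
  }
  if (is.null(box)) box <- c(Inf, Inf, Inf)
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  structure(list(times = as.numeric(times), coords = coords,
                 unwrapped = isTRUE(unwrapped), box = box,
                 origin = as.numeric(origin)),
            class = "aq_trajectory")
}

#' @export
print.aq_trajectory <- function(x, ...) {
  cat("aq_trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms; dt =", format(.frame_dt(x)), "ns;",
      if (x$unwrapped) "unwrapped" else "wrapped", "\n")
  invisible(x)
}

#' @keywords internal
.frame_dt <- function(window) {
  if (length(window$times) < 2) return(NA_real_)
  mean(diff(window$times))
}

#' @keywords internal
.stop_if_wrapped <- function(window, what) {
  if (!isTRUE(window$unwrapped))
    stop(what, " requires an unwrapped trajectory; call unwrap_trajectory() first")
}

#' Unwrap a periodic trajectory
#'
#' Removes periodic-boundary jumps by minimum-image correction of consecutive
#' per-atom displacements, dimension by dimension. Requires adequate sampling:
#' every physical displacement between stored frames must be below half a box
#' length.
#'
#' @param window `aq_trajectory` (wrapped).
#' @return `aq_trajectory` with `unwrapped = TRUE`.
#' @export
unwrap_trajectory <- function(window) {
  if (isTRUE(window$unwrapped)) return(window)
  co <- window$coords
  nf <- dim(co)[1]
  if (nf < 2) { window$unwrapped <- TRUE; return(window) }
  out <- co
  for (d in 1:3) {
    L <- window$box[, d]
    if (all(!is.finite(L))) next
    z <- co[, , d, drop = FALSE]
    dim(z) <- dim(co)[1:2]
    dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
    dz <- dz - sweep(round(sweep(dz, 1, L[-1], "/")), 1, L[-1], "*")
    if (any(abs(dz) >= L[-1] / 2 - 1e-9))
      stop("per-frame displacement >= box/2 in dimension ", d,
           "; trajectory is undersampled - write frames more densely")
    dzc <- apply(dz, 2, cumsum)
    if (!is.matrix(dzc)) dzc <- matrix(dzc, ncol = ncol(dz))
    out[, , d] <- rbind(z[1, , drop = FALSE], sweep(dzc, 2, z[1, ], "+"))
  }
  window$coords <- out
  window$unwrapped <- TRUE
  window
}

#' Rewrap a trajectory into its periodic box
#'
#' Maps coordinates back into `[origin, origin + box)` per dimension. The
#' inverse of [unwrap_trajectory()] modulo box translations.
#'
#' @param window `aq_trajectory`.
#' @return `aq_trajectory` with `unwrapped = FALSE`.
#' @export
wrap_trajectory <- function(window) {
  co <- window$coords
  for (d in 1:3) {
    L <- window$box[, d]
    if (all(!is.finite(L))) next
    z <- co[, , d, drop = FALSE]
    dim(z) <- dim(co)[1:2]
    zr <- sweep(z, 1, window$origin[d], "-")
    zr <- zr - sweep(floor(sweep(zr, 1, L, "/")), 1, L, "*")
    co[, , d] <- sweep(zr, 1, window$origin[d], "+")
  }
  window$coords <- co
  window$unwrapped <- FALSE
  window
}

# ---------------------------------------------------------------------------
# ChannelRegion
# ---------------------------------------------------------------------------

#' Define a channel (pore) region
#'
#' A per-pore cylinder with axis parallel to z: the region whose water content
#' S(t) enters the collective coordinate, and whose length L divides each
#' water displacement.
#'
#' @param pore_label one of `"A".."D"`.
#' @param center_xy length-2 cylinder axis position (Angstrom).
#' @param radius cylinder radius (Angstrom, > 0).
#' @param z_lo,z_hi channel bounds along z (Angstrom, `z_hi > z_lo`); channel
#'   membership uses the half-open interval `[z_lo, z_hi)`.
#' @param length_mode `"fixed"` (L constant, `z_hi - z_lo`) or `"per_frame"`
#'   (L(t) from the z separation of two anchor atoms).
#' @param anchor_atoms length-2 integer atom ids used when
#'   `length_mode = "per_frame"`.
#' @return Object of class `aq_channel`.
#' @export
channel_region <- function(pore_label, center_xy, radius, z_lo, z_hi,
                           length_mode = c("fixed", "per_frame"),
                           anchor_atoms = NULL) {
  length_mode <- match.arg(length_mode)
  if (z_hi <= z_lo) stop("z_hi must exceed z_lo")
  if (radius <= 0) stop("radius must be positive")
  if (length_mode == "per_frame" && length(anchor_atoms) != 2)
    stop("per_frame length mode needs two anchor atom ids")
  structure(list(pore_label = pore_label, center_xy = as.numeric(center_xy),
                 radius = radius, z_lo = z_lo, z_hi = z_hi,
                 length_mode = length_mode, L_fixed = z_hi - z_lo,
                 anchor_atoms = anchor_atoms),
            class = "aq_channel")
}

#' Channel length per frame
#'
#' @param region `aq_channel`.
#' @param window `aq_trajectory` (needed for `per_frame` mode).
#' @return numeric vector of L(t), one value per frame.
#' @export
channel_length <- function(region, window = NULL) {
  if (region$length_mode == "fixed") {
    nf <- if (is.null(window)) 1L else dim(window$coords)[1]
    return(rep(region$L_fixed, nf))
  }
  if (is.null(window)) stop("per_frame length mode needs a trajectory window")
  a <- region$anchor_atoms + 1L
  abs(window$coords[, a[2], 3] - window$coords[, a[1], 3])
}

# wrapped coordinates of one frame (natoms x 3), regardless of window state
#' @keywords internal
.wrapped_frame <- function(window, frame_index) {
  co <- window$coords[frame_index, , , drop = FALSE]
  dim(co) <- dim(window$coords)[2:3]
  for (d in 1:3) {
    L <- window$box[frame_index, d]
    if (!is.finite(L)) next
    z <- co[, d] - window$origin[d]
    co[, d] <- window$origin[d] + z - L * floor(z / L)
  }
  co
}

#' Select the waters inside a channel at one frame
#'
#' A water belongs to S(t) iff its oxygen satisfies `z_lo <= z < z_hi`
#' (half-open) and its xy distance to the cylinder axis is at most `radius`,
#' evaluated on wrapped coordinates.
#'
#' @param window `aq_trajectory` (wrapped or unwrapped).
#' @param topology `aq_topology`.
#' @param region `aq_channel`.
#' @param frame_index 1-based frame number.
#' @return Sorted integer vector of water `residue_id`s (possibly empty).
#' @export
select_channel_waters <- function(window, topology, region, frame_index) {
  a <- topology$atoms
  ox <- which(a$is_water & grepl("^O", a$name))
  if (length(ox) == 0) return(integer(0))
  co <- .wrapped_frame(window, frame_index)
  z <- co[ox, 3]
  dx <- co[ox, 1] - region$center_xy[1]
  dy <- co[ox, 2] - region$center_xy[2]
  keep <- z >= region$z_lo & z < region$z_hi &
    (dx * dx + dy * dy) <= region$radius^2
  sort(a$residue_id[ox[keep]])
}

# per-frame logical membership matrix [n_frames x n_selected_waters]
# for internal vectorized reuse; columns named by residue_id
#' @keywords internal
.water_membership <- function(window, topology, region) {
  a <- topology$atoms
  ox <- which(a$is_water & grepl("^O", a$name))
  nf <- dim(window$coords)[1]
  if (length(ox) == 0)
    return(matrix(FALSE, nf, 0))
  getdim <- function(d) {
    v <- window$coords[, ox, d, drop = FALSE]
    dim(v) <- c(nf, length(ox))
    L <- window$box[, d]
    if (any(is.finite(L))) {
      Ls <- ifelse(is.finite(L), L, NA_real_)
      v0 <- v - window$origin[d]
      shift <- sweep(floor(sweep(v0, 1, Ls, "/")), 1, Ls, "*")
      shift[is.na(shift)] <- 0
      v <- window$origin[d] + v0 - shift
    }
    v
  }
  x <- getdim(1); y <- getdim(2); z <- getdim(3)
  dx <- x - region$center_xy[1]
  dy <- y - region$center_xy[2]
  m <- z >= region$z_lo & z < region$z_hi &
    (dx * dx + dy * dy) <= region$radius^2
  colnames(m) <- a$residue_id[ox]
  m
}
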