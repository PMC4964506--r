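## CHARMM/NAMD-style DCD trajectory I/O.
## Reading delegates the coordinate payload to bio3d::read.dcd; a small header
## peek recovers the frame count, time step and atom count (which bio3d
## discards) and lets truncated files be rejected before any frame is
## returned. Writing is done here because no installed R package writes DCD;
## the writer is validated against bio3d's reader in the test suite.

# read the fixed-layout header: returns list(natoms, nframes, delta, ntitle)
#' @keywords internal
.dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  len1 <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(len1, 84L)) stop("not a DCD file (bad header block length)")
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a DCD file (missing CORD magic)")
  icntrl1 <- readBin(con, "integer", 9, size = 4, endian = "little")
  delta <- readBin(con, "numeric", 1, size = 4, endian = "little")
  icntrl2 <- readBin(con, "integer", 10, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  tlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  ntitle <- readBin(con, "integer", 1, size = 4, endian = "little")
  readChar(con, 80 * ntitle, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  natoms <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  header_bytes <- 4L + 84L + 4L + 4L + (4L + 80L * ntitle) + 4L + 4L + 4L + 4L
  list(natoms = natoms, nframes = icntrl1[1], delta = delta,
       has_cell = icntrl2[1] == 1L, header_bytes = header_bytes)
}

#' Write a trajectory window to a DCD file
#'
#' Writes a CHARMM-format binary DCD (little endian, no unit-cell records; box
#' and origin travel in the fixture sidecar instead). Coordinates are stored
#' as 32-bit floats, so the round trip is faithful to about 1e-5 A for
#' channel-scale coordinates.
#'
#' @param window `aq_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(window, path) {
  co <- window$coords
  nf <- dim(co)[1]; na <- dim(co)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  blk <- function(nbytes, writer) {
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
  }
  dt <- .frame_dt(window)
  if (is.na(dt)) dt <- 0
  blk(84L, function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L), con, size = 4L, endian = "little")
    writeBin(as.numeric(dt), con, size = 4L, endian = "little")  # dt in ns as float32
    writeBin(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L), con, size = 4L, endian = "little")
  })
  blk(4L + 80L, function() {
    writeBin(1L, con, size = 4L, endian = "little")
    writeChar(formatC("written by aquaflux", width = 80, flag = "-"),
              con, nchars = 80, eos = NULL)
  })
  blk(4L, function() writeBin(as.integer(na), con, size = 4L, endian = "little"))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      blk(4L * na, function()
        writeBin(as.numeric(co[f, , d]), con, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

#' Read a trajectory from a DCD file
#'
#' @param path DCD file.
#' @param topology `aq_topology`; the file's atom count must match.
#' @param dt frame spacing in ns; if `NULL`, taken from the DCD header.
#' @param box per-frame box lengths (length-3 vector or `n_frames x 3`
#'   matrix); DCD files written by [write_trajectory()] carry no cell record,
#'   so the box is supplied here (fixture sidecars store it).
#' @param origin length-3 lower box corner.
#' @return `aq_trajectory` with `unwrapped = FALSE`, frames in file order.
#' @export
read_trajectory <- function(path, topology, dt = NULL, box = NULL,
                            origin = c(0, 0, 0)) {
  hd <- .dcd_header(path)
  na <- nrow(topology$atoms)
  if (hd$natoms != na)
    stop("atom count mismatch: DCD has ", hd$natoms, ", topology has ", na)
  frame_bytes <- 3L * (8L + 4L * hd$natoms) + if (hd$has_cell) 8L + 48L else 0L
  expected <- hd$header_bytes + as.numeric(hd$nframes) * frame_bytes
  if (file.size(path) < expected)
    stop("truncated DCD: expected ", expected, " bytes for ", hd$nframes,
         " frames, found ", file.size(path))
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  co <- array(0, dim = c(nf, na, 3))
  for (d in 1:3) co[, , d] <- xyz[, seq(d, 3 * na, by = 3), drop = FALSE]
  if (is.null(dt)) dt <- hd$delta
  trajectory_window(times = (seq_len(nf) - 1) * dt, coords = co,
                    unwrapped = FALSE, box = box, origin = origin)
}
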