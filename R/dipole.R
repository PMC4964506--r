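## dipole_response: residue dipole vectors, cos(theta) distributions against
## the +z membrane normal, and flip-transition kinetics.

#' Residue dipole vector at one frame
#'
#' `mu = sum_a q_a (r_a - r_com)` over the residue's atoms, with `r_com` the
#' mass-weighted centre of mass as the reference point. For a net-neutral
#' residue the dipole is origin-independent; for charged residues (e.g.
#' arginine) the centre-of-mass reference makes the value well defined and is
#' reported with every output.
#'
#' @param topology `aq_topology`.
#' @param frame matrix natoms x 3 of coordinates (one frame, A).
#' @param residue_id residue to evaluate.
#' @param side_chain_only if `TRUE`, restrict to atoms whose names are not
#'   backbone names (`N`, `CA`, `C`, `O`, and their hydrogens).
#' @return Length-3 dipole vector in e*A.
#' @export
residue_dipole <- function(topology, frame, residue_id,
                           side_chain_only = FALSE) {
  a <- topology$atoms
  sel <- a$residue_id == residue_id
  if (side_chain_only)
    sel <- sel & !(a$name %in% c("N", "CA", "C", "O", "H", "HN", "HA"))
  if (sum(sel) < 2) stop("residue ", residue_id, " has fewer than 2 atoms")
  r <- frame[sel, , drop = FALSE]
  m <- a$mass[sel]; q <- a$charge[sel]
  com <- colSums(r * m) / sum(m)
  colSums(q * sweep(r, 2, com))
}

#' cos(theta) time series of a residue dipole
#'
#' The cosine of the angle between the residue dipole and the +z axis (the
#' membrane normal), per frame: `cos(theta) = mu_z / |mu|`. Frames with a
#' vanishing dipole are flagged as missing (`NA`), not zero.
#'
#' @param window `aq_trajectory` (wrapping does not matter as long as the
#'   residue is not split across the boundary; synthetic residues never are).
#' @param topology `aq_topology`.
#' @param residue_id residue to track.
#' @param side_chain_only passed to [residue_dipole()].
#' @return Object of class `aq_dipole_series`: data.frame with columns
#'   `time` (ns), `mu_x`, `mu_y`, `mu_z` (e*A) and `cos_theta`; attributes
#'   `residue_id`, `pore_label`, `residue_name`, `reference`.
#' @export
cos_theta_series <- function(window, topology, residue_id,
                             side_chain_only = FALSE) {
  a <- topology$atoms
  sel <- which(a$residue_id == residue_id)
  if (length(sel) < 2) stop("residue ", residue_id, " has fewer than 2 atoms")
  nf <- dim(window$coords)[1]
  if (nf < 1) stop("empty trajectory window")
  asel <- a[sel, ]
  if (side_chain_only) {
    keep <- !(asel$name %in% c("N", "CA", "C", "O", "H", "HN", "HA"))
    sel <- sel[keep]; asel <- asel[keep, ]
  }
  m <- asel$mass; q <- asel$charge
  co <- window$coords[, sel, , drop = FALSE]
  mu <- matrix(0, nf, 3)
  for (d in 1:3) {
    r <- co[, , d, drop = FALSE]; dim(r) <- c(nf, length(sel))
    com <- as.vector(r %*% m) / sum(m)
    mu[, d] <- as.vector(r %*% q) - sum(q) * com
  }
  nrm <- sqrt(rowSums(mu^2))
  ct <- ifelse(nrm > 1e-12, mu[, 3] / nrm, NA_real_)
  if (all(is.na(ct)))
    stop("residue ", residue_id, " has zero dipole in every frame; cos(theta) undefined")
  out <- data.frame(time = window$times, mu_x = mu[, 1], mu_y = mu[, 2],
                    mu_z = mu[, 3], cos_theta = ct)
  structure(out, class = c("aq_dipole_series", "data.frame"),
            residue_id = residue_id,
            residue_name = asel$residue_name[1],
            pore_label = asel$pore_label[1],
            reference = "residue centre of mass")
}

#' Normalised orientation histogram over cos(theta)
#'
#' Bins pooled cos(theta) samples on `[-1, 1]` into a probability *density*:
#' the bin integral `sum(density * bin_width)` is exactly 1. Missing samples
#' (`NA`) are excluded.
#'
#' @param series_list one `aq_dipole_series` / numeric vector, or a list of
#'   them (pooled).
#' @param n_bins number of equal bins over `[-1, 1]` (default 40).
#' @return data.frame `(bin_lo, bin_hi, bin_center, density)`.
#' @export
orientation_histogram <- function(series_list, n_bins = 40) {
  if (is.data.frame(series_list) || is.numeric(series_list))
    series_list <- list(series_list)
  vals <- unlist(lapply(series_list, function(s)
    if (is.data.frame(s)) s$cos_theta else as.numeric(s)))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no non-missing cos(theta) samples")
  if (any(vals < -1 - 1e-12 | vals > 1 + 1e-12))
    stop("cos(theta) samples outside [-1, 1]")
  vals <- pmin(pmax(vals, -1), 1)
  br <- seq(-1, 1, length.out = n_bins + 1)
  w <- 2 / n_bins
  cnt <- tabulate(pmin(findInterval(vals, br, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  data.frame(bin_lo = br[-(n_bins + 1)], bin_hi = br[-1],
             bin_center = (br[-(n_bins + 1)] + br[-1]) / 2,
             density = cnt / (sum(cnt) * w))
}

#' Mean of an orientation histogram
#'
#' `sum(density * bin_center * bin_width)` — the histogram estimate of the
#' mean alignment, comparable to the Langevin function for free rotors.
#'
#' @param hist data.frame from [orientation_histogram()].
#' @return Scalar mean.
#' @export
histogram_mean <- function(hist) {
  sum(hist$density * hist$bin_center * (hist$bin_hi - hist$bin_lo))
}

#' Detect dipolar flip transitions in a cos(theta) series
#'
#' A transition is a crossing of `crossing_level` followed by at least
#' `dwell_threshold` of continuous residence on the new side; chatter shorter
#' than the dwell window is ignored (collapses into the surrounding state).
#' Missing frames are dropped before analysis and excluded from the rate
#' denominator.
#'
#' @param series `aq_dipole_series`, or a numeric vector (then `times` is
#'   required).
#' @param times time stamps (ns) when `series` is a bare vector.
#' @param crossing_level level whose crossings define transitions
#'   (default 0).
#' @param dwell_threshold minimum residence time (ns) confirming a
#'   transition; must be at least 2 frame intervals (default 0.1 ns).
#' @return Object of class `aq_transitions`: list with `events`
#'   (data.frame `time`, `direction` in up/down), `rate` (events/ns over the
#'   analysed span), `n_events`, `span`, `dwell_threshold`, `crossing_level`.
#' @export
detect_transitions <- function(series, times = NULL, crossing_level = 0,
                               dwell_threshold = 0.1) {
  if (is.data.frame(series)) {
    x <- series$cos_theta
    times <- series$time
  } else x <- as.numeric(series)
  if (is.null(times)) stop("times required for a bare numeric series")
  ok <- !is.na(x)
  x <- x[ok]; times <- times[ok]
  if (length(x) < 2) stop("series too short")
  dt <- mean(diff(times))
  if (dwell_threshold < 2 * dt - 1e-9)
    stop("dwell_threshold must be at least 2 frame intervals (",
         signif(2 * dt, 3), " ns)")
  span <- times[length(times)] - times[1]
  side <- sign(x - crossing_level)
  # frames exactly at the level inherit the previous side
  if (any(side == 0)) {
    for (i in seq_along(side)) if (side[i] == 0) side[i] <- if (i > 1) side[i - 1] else 1
  }
  r <- rle(side)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  durs <- times[ends] - times[starts] + dt
  cur <- r$values[1]
  ev_t <- numeric(0); ev_dir <- character(0)
  if (length(r$values) > 1) {
    for (i in 2:length(r$values)) {
      if (r$values[i] == cur) next
      if (durs[i] >= dwell_threshold - 1e-9) {
        ev_t <- c(ev_t, times[starts[i]])
        ev_dir <- c(ev_dir, if (r$values[i] > cur) "up" else "down")
        cur <- r$values[i]
      }
    }
  }
  structure(list(events = data.frame(time = ev_t, direction = ev_dir,
                                     stringsAsFactors = FALSE),
                 rate = length(ev_t) / span, n_events = length(ev_t),
                 span = span, dwell_threshold = dwell_threshold,
                 crossing_level = crossing_level),
            class = "aq_transitions")
}

#' @export
print.aq_transitions <- function(x, ...) {
  cat(sprintf("aq_transitions: %d events over %.3g ns (rate %.4g /ns; dwell >= %.3g ns)\n",
              x$n_events, x$span, x$rate, x$dwell_threshold))
  invisible(x)
}
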