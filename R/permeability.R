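## permeability: collective coordinate n(t), its diffusion constant D_n, the
## osmotic permeability p_f = v_w * D_n, in-channel water self-diffusivity
## with the non-Fickian log-log exponent, and discrete permeation events.

# unwrapped z matrix [n_frames x n_waters] of water oxygens, columns named by
# residue_id, in topology order
#' @keywords internal
.water_z <- function(window, topology) {
  a <- topology$atoms
  ox <- which(a$is_water & grepl("^O", a$name))
  z <- window$coords[, ox, 3, drop = FALSE]
  dim(z) <- c(dim(window$coords)[1], length(ox))
  colnames(z) <- a$residue_id[ox]
  z
}

#' Collective water coordinate n(t) of a channel
#'
#' The dimensionless collective coordinate of the collective diffusion model:
#' starting from n(0) = 0, each frame step adds
#' `dn = sum_i dz_i / L` over the waters present in the channel S(t) at
#' *both* endpoints of the step, with `dz_i = z_i(t) - z_i(t - dt)`. One full
#' permeation shifts n by +/-1.
#'
#' @param window unwrapped `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param region `aq_channel`; in `per_frame` length mode each step's dn is
#'   divided by the current frame's L(t).
#' @return data.frame with columns `time` (ns) and `n`.
#' @export
collective_coordinate <- function(window, topology, region) {
  .stop_if_wrapped(window, "collective_coordinate")
  nf <- dim(window$coords)[1]
  if (nf < 2) stop("need at least 2 frames")
  M <- .water_membership(window, topology, region)
  z <- .water_z(window, topology)
  dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
  both <- M[-1, , drop = FALSE] & M[-nf, , drop = FALSE]
  L <- channel_length(region, window)[-1]
  dn <- rowSums(dz * both) / L
  data.frame(time = window$times, n = c(0, cumsum(dn)))
}

#' Mean square displacement with overlapping time origins
#'
#' `MSD(tau) = < [x(t0 + tau) - x(t0)]^2 >` averaged over every valid origin
#' t0 (all overlapping origins, the variance-minimising standard choice).
#'
#' @param x numeric series sampled uniformly.
#' @param times time stamps (ns) of `x`.
#' @param max_lag largest lag (ns); must not exceed half the span.
#' @return data.frame with columns `lag` (ns), `msd`, `n_origins`.
#' @export
msd_multi_origin <- function(x, times, max_lag) {
  n <- length(x)
  if (n < 2) stop("series too short")
  dt <- mean(diff(times))
  span <- times[n] - times[1]
  if (max_lag > span / 2 + 1e-9)
    stop("max_lag (", max_lag, " ns) exceeds half the series span (",
         span / 2, " ns)")
  kmax <- max(1L, floor(max_lag / dt + 1e-9))
  msd <- numeric(kmax); nor <- integer(kmax)
  for (k in seq_len(kmax)) {
    d <- x[(1 + k):n] - x[1:(n - k)]
    msd[k] <- mean(d * d)
    nor[k] <- n - k
  }
  data.frame(lag = seq_len(kmax) * dt, msd = msd, n_origins = nor)
}

#' Fit the diffusion constant of the collective coordinate
#'
#' Least-squares slope of MSD(n) versus lag over the fit window, divided
#' by 2 (1D Einstein relation). A negative fitted slope is clamped to 0 and
#' flagged (attribute `"clamped"`).
#'
#' @param msd_n data.frame from [msd_multi_origin()].
#' @param fit_window length-2 lag range (ns); default the 10%-50% span of
#'   the computed lags.
#' @return D_n in 1/ns (attributes: `fit_window`, `slope`, `clamped`).
#' @export
fit_Dn <- function(msd_n, fit_window = NULL) {
  if (is.null(fit_window))
    fit_window <- c(0.1, 0.5) * max(msd_n$lag)
  sel <- msd_n$lag >= fit_window[1] - 1e-9 & msd_n$lag <= fit_window[2] + 1e-9
  if (sum(sel) < 4)
    stop("fewer than 4 MSD points in the fit window [",
         fit_window[1], ", ", fit_window[2], "] ns")
  fit <- stats::lm(msd ~ lag, data = msd_n[sel, ])
  slope <- unname(stats::coef(fit)[2])
  Dn <- slope / 2
  clamped <- FALSE
  if (Dn < 0) { Dn <- 0; clamped <- TRUE; warning("negative MSD slope clamped to D_n = 0") }
  structure(Dn, fit_window = fit_window, slope = slope, clamped = clamped)
}

#' Osmotic permeability from the collective diffusion constant
#'
#' `p_f = v_w * D_n`, with D_n converted from 1/ns to 1/s.
#'
#' @param D_n collective diffusion constant (1/ns, >= 0).
#' @param v_w average volume of a water molecule (cm^3); default
#'   3.0e-23 cm^3 (bulk water).
#' @return p_f in cm^3/s.
#' @export
osmotic_permeability <- function(D_n, v_w = aq_constants()$v_w_cm3) {
  if (any(D_n < 0)) stop("D_n must be non-negative")
  v_w * as.numeric(D_n) * 1e9
}

#' Count complete permeation events through a channel
#'
#' An event is scored when a water oxygen travels from below `z_lo` to above
#' `z_hi` (+z event; the reverse for -z) while staying within the cylinder
#' radius whenever its z lies inside `[z_lo, z_hi]`. After a completed or
#' invalidated passage the water must re-enter from a reservoir before it can
#' score again (full reset).
#'
#' @param window unwrapped `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param region `aq_channel`.
#' @param per_water if `TRUE`, return the per-water event table instead of
#'   the totals.
#' @return Named numeric `c(up, down)`, or with `per_water = TRUE` a
#'   data.frame `(residue_id, up, down)`.
#' @export
permeation_events <- function(window, topology, region, per_water = FALSE) {
  .stop_if_wrapped(window, "permeation_events")
  a <- topology$atoms
  ox <- which(a$is_water & grepl("^O", a$name))
  nf <- dim(window$coords)[1]
  res <- data.frame(residue_id = a$residue_id[ox], up = 0L, down = 0L)
  for (j in seq_along(ox)) {
    z <- window$coords[, ox[j], 3]
    dx <- window$coords[, ox[j], 1] - region$center_xy[1]
    dy <- window$coords[, ox[j], 2] - region$center_xy[2]
    rok <- (dx * dx + dy * dy) <= region$radius^2
    zone <- ifelse(z < region$z_lo, -1L, ifelse(z >= region$z_hi, 1L, 0L))
    r <- rle(zone)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    resv <- which(r$values != 0L)
    if (length(resv) < 2) next
    for (k in seq_len(length(resv) - 1L)) {
      i <- resv[k]; jj <- resv[k + 1L]
      if (r$values[i] == r$values[jj]) next
      gap <- if (jj == i + 1L) TRUE else all(rok[(ends[i] + 1L):(starts[jj] - 1L)])
      if (!gap) next
      if (r$values[jj] > r$values[i]) res$up[j] <- res$up[j] + 1L
      else res$down[j] <- res$down[j] + 1L
    }
  }
  if (per_water) return(res)
  c(up = sum(res$up), down = sum(res$down))
}

#' In-channel self-diffusivity of permeating waters
#'
#' Einstein-relation z self-diffusivity restricted to the in-channel segments
#' of waters that complete at least one passage: pooled multi-origin z-MSD
#' over contiguous in-channel stretches, fitted over `fit_window`; the
#' Fickian exponent is the log-log slope of the same MSD over the same
#' window (1 = Fickian, <1 subdiffusive as is typical of confined water,
#' 2 = ballistic).
#'
#' @param window unwrapped `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param region `aq_channel`.
#' @param max_lag largest MSD lag (ns); default half the longest in-channel
#'   segment.
#' @param fit_window lag range (ns); default the 10%-50% span of the lags.
#' @return List `(D_self [A^2/ps], fickian_exponent, msd, n_waters, empty)`.
#'   If no water completes a passage the result is flagged `empty = TRUE`
#'   (no exception).
#' @export
self_diffusivity_z <- function(window, topology, region,
                               max_lag = NULL, fit_window = NULL) {
  .stop_if_wrapped(window, "self_diffusivity_z")
  ev <- permeation_events(window, topology, region, per_water = TRUE)
  keep_ids <- ev$residue_id[ev$up + ev$down >= 1L]
  if (length(keep_ids) == 0)
    return(list(D_self = NA_real_, fickian_exponent = NA_real_,
                msd = NULL, n_waters = 0L, empty = TRUE))
  M <- .water_membership(window, topology, region)
  z <- .water_z(window, topology)
  dt <- .frame_dt(window)
  cols <- match(as.character(keep_ids), colnames(z))
  # collect contiguous in-channel runs per water
  runs <- list()
  for (cix in cols) {
    r <- rle(as.vector(M[, cix]))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= 2L))
      runs[[length(runs) + 1L]] <- z[starts[q]:ends[q], cix]
  }
  if (length(runs) == 0)
    return(list(D_self = NA_real_, fickian_exponent = NA_real_,
                msd = NULL, n_waters = length(keep_ids), empty = TRUE))
  longest <- max(lengths(runs))
  if (is.null(max_lag)) max_lag <- (longest - 1) * dt / 2
  kmax <- max(1L, floor(max_lag / dt + 1e-9))
  ssum <- numeric(kmax); cnt <- numeric(kmax)
  for (seg in runs) {
    n <- length(seg)
    for (k in seq_len(min(kmax, n - 1L))) {
      d <- seg[(1 + k):n] - seg[1:(n - k)]
      ssum[k] <- ssum[k] + sum(d * d)
      cnt[k] <- cnt[k] + (n - k)
    }
  }
  ok <- cnt > 0
  msd <- data.frame(lag = seq_len(kmax)[ok] * dt, msd = ssum[ok] / cnt[ok],
                    n_origins = cnt[ok])
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * max(msd$lag)
  sel <- msd$lag >= fit_window[1] - 1e-9 & msd$lag <= fit_window[2] + 1e-9
  if (sum(sel) < 2)
    return(list(D_self = NA_real_, fickian_exponent = NA_real_, msd = msd,
                n_waters = length(keep_ids), empty = TRUE))
  fit <- stats::lm(msd ~ lag, data = msd[sel, ])
  D_self <- unname(stats::coef(fit)[2]) / 2 / 1000  # A^2/ns -> A^2/ps
  pos <- sel & msd$msd > 0
  expo <- if (sum(pos) >= 2) {
    unname(stats::coef(stats::lm(log(msd) ~ log(lag), data = msd[pos, ]))[2])
  } else NA_real_
  list(D_self = D_self, fickian_exponent = expo, msd = msd,
       n_waters = length(keep_ids), empty = FALSE)
}

#' Full per-pore permeability analysis
#'
#' Computes the collective coordinate, its multi-origin MSD, D_n, p_f,
#' self-diffusivity of permeating waters with the Fickian exponent, and
#' permeation-event counts for one channel.
#'
#' @param window unwrapped `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param region `aq_channel`.
#' @param max_lag MSD lag cap (ns); default half the trajectory span.
#' @param fit_window D_n fit range (ns); default 10%-50% of `max_lag`
#'   (echoed in the result).
#' @param v_w water molecular volume (cm^3).
#' @param include_self also run the per-water self-diffusivity analysis
#'   (default `TRUE`; it is the expensive part on long windows).
#' @param self_max_lag lag cap (ns) for the self-diffusivity MSD.
#' @return Object of class `aq_perm`: `pore_label`, `n_series`, `msd_n`,
#'   `D_n` (1/ns), `p_f` (cm^3/s, exactly `v_w * D_n` after unit
#'   conversion), `v_w`, `D_self` (A^2/ps), `fickian_exponent`,
#'   `n_permeation_events` (up/down), `fit_window`.
#' @export
pore_permeability <- function(window, topology, region,
                              max_lag = NULL, fit_window = NULL,
                              v_w = aq_constants()$v_w_cm3,
                              include_self = TRUE, self_max_lag = NULL) {
  ns <- collective_coordinate(window, topology, region)
  span <- max(ns$time) - min(ns$time)
  if (is.null(max_lag)) max_lag <- span / 2
  msd_n <- msd_multi_origin(ns$n, ns$time, max_lag)
  D_n <- fit_Dn(msd_n, fit_window)
  selfd <- if (include_self)
    self_diffusivity_z(window, topology, region, max_lag = self_max_lag)
  else list(D_self = NA_real_, fickian_exponent = NA_real_)
  ev <- permeation_events(window, topology, region)
  structure(list(
    pore_label = region$pore_label,
    n_series = ns, msd_n = msd_n,
    D_n = as.numeric(D_n), p_f = osmotic_permeability(as.numeric(D_n), v_w),
    v_w = v_w,
    D_self = selfd$D_self, fickian_exponent = selfd$fickian_exponent,
    n_permeation_events = ev,
    fit_window = attr(D_n, "fit_window"),
    Dn_clamped = attr(D_n, "clamped")
  ), class = "aq_perm")
}

#' @export
print.aq_perm <- function(x, ...) {
  cat(sprintf("pore %s: D_n = %.4g /ns, p_f = %.4g cm^3/s, D_self = %.4g A^2/ps, exponent = %.3g, events +%d/-%d\n",
              x$pore_label, x$D_n, x$p_f,
              ifelse(is.na(x$D_self), NA, x$D_self),
              ifelse(is.na(x$fickian_exponent), NA, x$fickian_exponent),
              x$n_permeation_events["up"], x$n_permeation_events["down"]))
  invisible(x)
}
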