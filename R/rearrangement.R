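## rearrangement: per-residue heavy-atom RMSD against the initial
## configuration and the pore-by-condition rearrangement matrix.

#' Heavy-atom RMSD series of one residue
#'
#' `RMSD(t) = sqrt(mean_a |r_a(t) - r_a(0)|^2)` over the residue's heavy
#' atoms, with no rotational superposition (deviation is measured against
#' the initial *position*). By default the per-frame displacement of the
#' whole system's heavy-atom centroid is subtracted first, removing global
#' drift; set `remove_drift = FALSE` to skip that step.
#'
#' @param window unwrapped `aq_trajectory`.
#' @param topology `aq_topology`.
#' @param residue_id residue to track.
#' @param remove_drift subtract the global heavy-atom centroid displacement
#'   (default `TRUE`).
#' @return data.frame `(time, rmsd)` in ns / A.
#' @export
residue_rmsd_series <- function(window, topology, residue_id,
                                remove_drift = TRUE) {
  .stop_if_wrapped(window, "residue_rmsd_series")
  a <- topology$atoms
  sel <- which(a$residue_id == residue_id & a$is_heavy)
  if (length(sel) == 0) stop("residue ", residue_id, " has no heavy atoms")
  nf <- dim(window$coords)[1]
  drift <- matrix(0, nf, 3)
  if (remove_drift) {
    # global drift = displacement of the protein (tetramer) heavy-atom
    # centroid; waters are excluded (they diffuse, the protein does not)
    heavy <- which(a$is_heavy & !a$is_water)
    if (length(heavy) == 0) heavy <- which(a$is_heavy)
    for (d in 1:3) {
      hco <- window$coords[, heavy, d, drop = FALSE]
      dim(hco) <- c(nf, length(heavy))
      cm <- rowMeans(hco)
      drift[, d] <- cm - cm[1]
    }
  }
  ss <- matrix(0, nf, length(sel))
  for (d in 1:3) {
    r <- window$coords[, sel, d, drop = FALSE]
    dim(r) <- c(nf, length(sel))
    disp <- sweep(r, 2, r[1, ]) - drift[, d]
    ss <- ss + disp^2
  }
  data.frame(time = window$times, rmsd = sqrt(rowMeans(ss)))
}

#' Flag a residue as rearranged
#'
#' The rearrangement criterion: the summary statistic (median by default) of
#' the RMSD over frames later than `settle_time` strictly exceeds
#' `threshold`. Defaults implement "heavy-atom RMSD of more than 1 A with
#' respect to the initial configuration, after 1 ns"; the median is used for
#' robustness against transient spikes (mean and max are available).
#'
#' @param rmsd_series data.frame from [residue_rmsd_series()].
#' @param threshold A (default 1.0); strict inequality, so a displacement of
#'   exactly 1 A is not flagged.
#' @param settle_time ns (default 1.0); frames with `t > settle_time` enter
#'   the statistic.
#' @param stat `"median"`, `"mean"` or `"max"`.
#' @return Logical flag (attribute `"stat_value"` carries the statistic).
#' @export
flag_rearranged <- function(rmsd_series, threshold = 1.0, settle_time = 1.0,
                            stat = c("median", "mean", "max")) {
  stat <- match.arg(stat)
  if (max(rmsd_series$time) <= settle_time)
    stop("series must span beyond settle_time = ", settle_time, " ns")
  v <- rmsd_series$rmsd[rmsd_series$time > settle_time]
  sv <- switch(stat, median = stats::median(v), mean = mean(v), max = max(v))
  structure(sv > threshold, stat_value = sv)
}

#' Build a rearrangement matrix (residues x field conditions)
#'
#' Collects per-residue / per-pore / per-condition rearrangement flags into
#' the pore-by-condition overview: each cell holds the set of pore labels
#' flagged for that residue under that condition. Conditions absent from the
#' input are marked missing (`NA`), distinct from an empty cell.
#'
#' @param flags data.frame with columns `residue`, `condition` (signed field
#'   intensity, V/A), `pore_label`, `flagged` (logical).
#' @param residues row order; default the residues present, in input order.
#' @param conditions column order; default sorted unique conditions.
#' @return Object of class `aq_rearr_matrix`: a character matrix whose cells
#'   are comma-joined sorted pore labels (`""` = none flagged, `NA` =
#'   condition not evaluated).
#' @export
build_rearrangement_matrix <- function(flags, residues = NULL,
                                       conditions = NULL) {
  if (is.null(residues)) residues <- unique(flags$residue)
  if (is.null(conditions)) conditions <- sort(unique(flags$condition))
  m <- matrix(NA_character_, length(residues), length(conditions),
              dimnames = list(residues,
                              vapply(conditions, function(x) format(x), "")))
  for (i in seq_along(residues)) {
    for (j in seq_along(conditions)) {
      sub <- flags[flags$residue == residues[i] &
                     flags$condition == conditions[j], ]
      if (nrow(sub) == 0) next
      m[i, j] <- paste(sort(unique(sub$pore_label[sub$flagged])),
                       collapse = ",")
    }
  }
  structure(m, class = c("aq_rearr_matrix", class(m)),
            threshold = attr(flags, "threshold") %||% 1.0,
            settle_time = attr(flags, "settle_time") %||% 1.0)
}

#' @export
print.aq_rearr_matrix <- function(x, ...) {
  cat("Rearrangement matrix (cells: pores flagged; threshold",
      attr(x, "threshold"), "A after", attr(x, "settle_time"), "ns)\n")
  print(unclass(x))
  invisible(x)
}

#' Write a rearrangement matrix as TSV
#'
#' @param x `aq_rearr_matrix`.
#' @param path output file.
#' @export
write_rearrangement_tsv <- function(x, path) {
  df <- data.frame(residue = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "absent")
  invisible(path)
}
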