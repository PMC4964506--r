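## stats_pipeline (orchestration): run the full analysis over a set of field
## conditions (zero field plus +/- intensities), aggregate per pore, and
## apply the statistical layer.

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Defaults reproduce the
#' study design: static 10 ns pulses along +/-y at 0.012, 0.02, 0.035, 0.05
#' and 0.065 V/A plus the zero-field reference, three replicas per
#' condition, four pores, and the five gating residues
#' (SER-211, HSD-201, ARG-216 at the extracellular mouth; HSD-95, CYS-178 at
#' the cytoplasmic mouth).
#'
#' @param intensities unsigned field intensities (V/A); each is applied
#'   along both +y and -y.
#' @param replicas independent replicas per condition (default 3).
#' @param duration,dt_frame trajectory length and frame spacing (ns).
#' @param envelope `"static"` or `"gaussian"`. Gaussian-envelope runs are
#'   supported but, mirroring their null outcome, are not part of the
#'   default condition set.
#' @param waters_per_pore,water_D,thermal_jitter,gating,confinement
#'   passed to [synth_spec()].
#' @param residues residue table as [default_gating_residues()].
#' @param v_w water molecular volume (cm^3).
#' @param max_lag,fit_window D_n MSD settings (ns). The default caps the
#'   n(t) MSD at 0.2 ns with the standard 10%-50% fit window: for Brownian
#'   collective coordinates the short-lag slope is unbiased and the slope
#'   standard error grows as sqrt(lag / span), so short windows are the
#'   low-variance choice (widen past any correlated regime for real MD).
#' @param self_max_lag lag cap (ns) for the per-water self-diffusivity MSD.
#' @param dwell_threshold transition dwell filter (ns).
#' @param n_bins orientation histogram bins.
#' @param rmsd_threshold,settle_time rearrangement criterion (A, ns).
#' @param alpha_perm,alpha_rates significance levels for permeability and
#'   transition-rate tests (0.05 / 0.10).
#' @param t_direction direction of the permeability t-test against zero
#'   field (default `"less"`: decreased permeability under field).
#' @param seed master seed; every per-run seed derives from it.
#' @return Named list of class `aq_config`.
#' @export
pipeline_config <- function(intensities = c(0.012, 0.02, 0.035, 0.05, 0.065),
                            replicas = 3, duration = 10, dt_frame = 0.01,
                            envelope = "static",
                            waters_per_pore = 10, water_D = 0.2,
                            thermal_jitter = 0,
                            gating = list(enabled = FALSE, scale = 0.5,
                                          threshold = 0.035),
                            confinement = "periodic",
                            residues = default_gating_residues(),
                            v_w = aq_constants()$v_w_cm3,
                            max_lag = 0.2, fit_window = NULL,
                            self_max_lag = 1,
                            dwell_threshold = 0.1, n_bins = 40,
                            rmsd_threshold = 1.0, settle_time = 1.0,
                            alpha_perm = 0.05, alpha_rates = 0.10,
                            t_direction = "less", seed = 1) {
  structure(as.list(environment()), class = "aq_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [pipeline_config()];
#' unspecified keys keep their defaults.
#'
#' @param path YAML file.
#' @return `aq_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()  # empty file: all defaults
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$residues)) y$residues <- as.data.frame(y$residues)
  do.call(pipeline_config, y)
}

#' @keywords internal
.condition_table <- function(config) {
  conds <- data.frame(condition = 0, sign = 1)
  for (E in config$intensities)
    conds <- rbind(conds, data.frame(condition = c(-E, E), sign = c(-1, 1)))
  conds[order(conds$condition), ]
}

#' Run the full analysis pipeline
#'
#' For every condition (zero field and each signed intensity) and replica,
#' generates a synthetic system, then computes per-pore permeability
#' (collective coordinate, D_n, p_f, self-diffusivity, permeation events),
#' residue cos(theta) series, orientation histograms, transition rates, and
#' rearrangement flags. Aggregates to condition summaries (mean +/- sd
#' across the four channels), paired one-tailed t-tests of p_f against zero
#' field, one-way ANOVA on per-pore permeability ratios, per-condition
#' transition-rate tests, and the rearrangement matrix.
#'
#' @param config `aq_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param output_dir if non-`NULL`, the report is also written there as
#'   JSON + TSV via [write_report()].
#' @return Report list with elements `permeability` (long data.frame),
#'   `summaries`, `tests_pf`, `anova_ratio`, `rates`, `tests_rates`,
#'   `histograms`, `rearrangement`, `gaps`, `status` (`"ok"` or
#'   `"partial"`), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  conds <- .condition_table(config)
  labels <- c("A", "B", "C", "D")
  res_labels <- if (nrow(config$residues) > 0)
    paste0(config$residues$resname, "-", config$residues$resno) else character(0)

  perm <- list(); rates <- list(); flags <- list(); hsamp <- list()
  gaps <- character(0)
  for (ci in seq_len(nrow(conds))) {
    E <- conds$condition[ci]
    for (rep_i in seq_len(config$replicas)) {
      run_seed <- .derive_seed(config$seed, 131 * ci + rep_i)
      out <- tryCatch(
        .analyse_one_run(config, E, rep_i, run_seed, labels, res_labels),
        error = function(e) e)
      if (inherits(out, "error")) {
        gaps <- c(gaps, sprintf("condition %+g replica %d: %s", E, rep_i,
                                conditionMessage(out)))
        next
      }
      perm[[length(perm) + 1L]] <- out$perm
      if (!is.null(out$rates)) rates[[length(rates) + 1L]] <- out$rates
      if (!is.null(out$flags)) flags[[length(flags) + 1L]] <- out$flags
      for (nm in names(out$hsamp)) {
        key <- paste(format(E), nm)
        hsamp[[key]] <- c(hsamp[[key]], out$hsamp[[nm]])
      }
    }
  }
  perm <- do.call(rbind, perm)
  rates <- if (length(rates) > 0) do.call(rbind, rates) else NULL
  flags <- if (length(flags) > 0) do.call(rbind, flags) else NULL

  report <- .aggregate_report(config, conds, perm, rates, flags, hsamp,
                              gaps, res_labels)
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# one condition x replica: simulate and measure everything
#' @keywords internal
.analyse_one_run <- function(config, E, rep_i, run_seed, labels, res_labels) {
  spec <- synth_spec(
    waters_per_pore = config$waters_per_pore, water_D = config$water_D,
    residues = config$residues,
    field = field_protocol(direction = c(0, sign(E + (E == 0)), 0),
                           E0 = abs(E), duration = config$duration,
                           envelope = config$envelope),
    duration = config$duration, dt_frame = config$dt_frame, seed = run_seed,
    confinement = config$confinement, thermal_jitter = config$thermal_jitter,
    gating = config$gating)
  sim <- simulate_system(spec)
  win <- unwrap_trajectory(sim$window)

  perm <- do.call(rbind, lapply(labels, function(lab) {
    pr <- pore_permeability(win, sim$topology, sim$regions[[lab]],
                            max_lag = config$max_lag,
                            fit_window = config$fit_window,
                            v_w = config$v_w,
                            self_max_lag = config$self_max_lag)
    data.frame(condition = E, replica = rep_i, pore_label = lab,
               D_n = pr$D_n, p_f = pr$p_f, D_self = pr$D_self,
               fickian_exponent = pr$fickian_exponent,
               events_up = pr$n_permeation_events["up"],
               events_down = pr$n_permeation_events["down"],
               row.names = NULL)
  }))

  rates <- NULL; flags <- NULL; hs <- list()
  if (length(res_labels) > 0) {
    rows_r <- list(); rows_f <- list()
    for (lab in labels) {
      for (r in seq_len(nrow(config$residues))) {
        rl <- res_labels[r]
        rid <- .res_rid(match(lab, labels), config$residues$resno[r])
        cs <- cos_theta_series(win, sim$topology, rid)
        tr <- detect_transitions(cs, dwell_threshold = config$dwell_threshold)
        rows_r[[length(rows_r) + 1L]] <- data.frame(
          condition = E, replica = rep_i, pore_label = lab, residue = rl,
          rate = tr$rate, n_events = tr$n_events)
        rs <- residue_rmsd_series(win, sim$topology, rid)
        fl <- flag_rearranged(rs, threshold = config$rmsd_threshold,
                              settle_time = config$settle_time)
        rows_f[[length(rows_f) + 1L]] <- data.frame(
          condition = E, replica = rep_i, pore_label = lab, residue = rl,
          flagged = as.logical(fl), stat_value = attr(fl, "stat_value"))
        hs[[rl]] <- c(hs[[rl]], cs$cos_theta)
      }
    }
    rates <- do.call(rbind, rows_r)
    flags <- do.call(rbind, rows_f)
  }
  list(perm = perm, rates = rates, flags = flags, hsamp = hs)
}

#' @keywords internal
.aggregate_report <- function(config, conds, perm, rates, flags, hsamp,
                              gaps, res_labels) {
  labels <- c("A", "B", "C", "D")
  has_zero <- !is.null(perm) && any(perm$condition == 0)

  # pore-level p_f averaged over replicas, per condition
  pore_pf <- function(E) {
    sub <- perm[perm$condition == E, ]
    if (nrow(sub) == 0) return(NULL)
    vapply(labels, function(l) mean(sub$p_f[sub$pore_label == l]), 0)
  }
  summaries <- list(); tests_pf <- list(); ratio_groups <- list()
  zero_pf <- if (has_zero) pore_pf(0) else NULL
  for (E in conds$condition) {
    pp <- pore_pf(E)
    if (is.null(pp)) next
    summaries[[format(E)]] <- condition_summary(E, pp, config$replicas)
    if (has_zero) {
      sub <- perm[perm$condition == E, ]
      ratio_groups[[format(E)]] <-
        sub$p_f / zero_pf[match(sub$pore_label, labels)]
      if (E != 0)
        tests_pf[[format(E)]] <- paired_one_tailed_t(
          pp, zero_pf, direction = config$t_direction,
          alpha = config$alpha_perm)
    }
  }
  summary_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$condition, mean_pf = s$mean_pf,
               sd_pf = s$sd_pf, replicas = s$replicas)))
  anova_ratio <- if (length(ratio_groups) >= 2)
    one_way_anova(ratio_groups, alpha = config$alpha_perm) else NULL

  tests_rates <- list()
  if (!is.null(rates) && has_zero) {
    pore_rate <- function(E) {
      sub <- rates[rates$condition == E, ]
      if (nrow(sub) == 0) return(NULL)
      vapply(labels, function(l) mean(sub$rate[sub$pore_label == l]), 0)
    }
    rz <- pore_rate(0)
    for (E in setdiff(conds$condition, 0)) {
      rf <- pore_rate(E)
      if (is.null(rf) || is.null(rz)) next
      tests_rates[[format(E)]] <- compare_transition_rates(
        rf, rz, alpha = config$alpha_rates)
    }
  }

  # histograms pooled over pores and replicas, per condition x residue
  histograms <- NULL
  if (length(hsamp) > 0) {
    histograms <- do.call(rbind, lapply(names(hsamp), function(key) {
      parts <- strsplit(key, " ")[[1]]
      h <- orientation_histogram(hsamp[[key]], n_bins = config$n_bins)
      cbind(condition = as.numeric(parts[1]), residue = parts[2], h)
    }))
  }

  # rearrangement: flagged if flagged in the majority of replicas
  rearr <- NULL
  if (!is.null(flags)) {
    agg <- stats::aggregate(flagged ~ condition + pore_label + residue,
                            data = flags, FUN = function(v) mean(v) > 0.5)
    rearr <- build_rearrangement_matrix(
      data.frame(residue = agg$residue, condition = agg$condition,
                 pore_label = agg$pore_label, flagged = agg$flagged),
      residues = res_labels)
  }

  list(
    permeability = perm,
    summaries = summary_df,
    tests_pf = tests_pf,
    anova_ratio = anova_ratio,
    rates = rates,
    tests_rates = tests_rates,
    histograms = histograms,
    rearrangement = rearr,
    gaps = gaps,
    status = if (length(gaps) == 0) "ok" else "partial",
    provenance = list(
      package = "aquaflux",
      version = as.character(utils::packageVersion("aquaflux")),
      seed = config$seed,
      config = config[setdiff(names(config), "residues")],
      residues = config$residues,
      pairing_unit = "pore (n = 4); replicas averaged within pore before testing",
      ratio_normalisation = "per pore against that pore's zero-field mean",
      dipole_reference = "residue centre of mass"
    )
  )
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (full report) plus flat TSV tables
#' (`permeability.tsv`, `summaries.tsv`, `rates.tsv`, `histograms.tsv`,
#' `rearrangement.tsv`, `tests.tsv`) into `dir`.
#'
#' @param report list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  tsv(report$permeability, "permeability.tsv")
  tsv(report$summaries, "summaries.tsv")
  tsv(report$rates, "rates.tsv")
  tsv(report$histograms, "histograms.tsv")
  if (!is.null(report$rearrangement))
    write_rearrangement_tsv(report$rearrangement,
                            file.path(dir, "rearrangement.tsv"))
  test_row <- function(name, t)
    data.frame(comparison = name, test = t$test, statistic = t$statistic,
               dof = paste(t$dof, collapse = ","), p_value = t$p_value,
               alpha = t$alpha, significant = t$significant,
               direction = t$direction)
  tests <- rbind(
    do.call(rbind, lapply(names(report$tests_pf), function(n)
      test_row(paste("pf", n, "vs zero"), report$tests_pf[[n]]))),
    do.call(rbind, lapply(names(report$tests_rates), function(n)
      test_row(paste("rates", n, "vs zero"), report$tests_rates[[n]]))),
    if (!is.null(report$anova_ratio))
      test_row("anova pf ratio across conditions", report$anova_ratio))
  tsv(tests, "tests.tsv")
  json <- report
  json$rearrangement <- if (!is.null(report$rearrangement))
    as.data.frame(unclass(report$rearrangement)) else NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(dir)
}
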