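## stats_pipeline (statistical layer): paired one-tailed t-tests against the
## zero-field case, one-way ANOVA across conditions, transition-rate
## comparisons. Pairing unit is the pore (n = 4), matching the error bars
## reported across the four channels; replicas are averaged within pore
## before testing.

#' @keywords internal
.aq_test <- function(test, statistic, dof, p_value, alpha, direction) {
  structure(list(test = test, statistic = statistic, dof = dof,
                 p_value = p_value, alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha,
                 direction = direction),
            class = "aq_test")
}

#' @export
print.aq_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, dof = %s, p = %.4g (%ssignificant at alpha = %.2g)\n",
              x$test, x$direction, x$statistic,
              paste(x$dof, collapse = ","), x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Paired one-tailed Student's t-test
#'
#' t-test on the paired differences `d = x - y` (pairing by pore label):
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' one-tailed p-value in the stated direction. Delegates to
#' [stats::t.test()] except for the degenerate zero-variance branches, which
#' follow the documented contract: zero variance with nonzero mean gives
#' p = 0 or 1 according to direction; all-zero differences give p = 0.5.
#'
#' @param x,y paired samples (equal length >= 2).
#' @param direction `"greater"` (mean difference > 0), `"less"`, or
#'   `"two_sided"`.
#' @param alpha significance level (default 0.05).
#' @return Object of class `aq_test`.
#' @export
paired_one_tailed_t <- function(x, y, direction = c("greater", "less",
                                                    "two_sided"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("incomplete pairing: NA values present")
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    p <- if (md == 0) 0.5
    else switch(direction,
                greater = if (md > 0) 0 else 1,
                less = if (md < 0) 0 else 1,
                two_sided = 0)
    return(.aq_test("one_tailed_paired_t", if (md == 0) 0 else sign(md) * Inf,
                    n - 1L, p, alpha, direction))
  }
  alt <- switch(direction, greater = "greater", less = "less",
                two_sided = "two.sided")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  .aq_test("one_tailed_paired_t", unname(tt$statistic),
           unname(tt$parameter), tt$p.value, alpha, direction)
}

#' One-way ANOVA across conditions
#'
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom,
#' via [stats::aov()]. The degenerate case of zero within-group variance
#' with unequal group means returns F = Inf, p = 0; identical values
#' everywhere return F = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return Object of class `aq_test` with `dof = c(between, within)`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  k <- length(groups)
  N <- sum(lengths(groups))
  y <- unlist(groups)
  g <- factor(rep(seq_len(k), lengths(groups)))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  means <- vapply(groups, mean, 0)
  if (within_ss == 0) {
    if (max(means) - min(means) == 0)
      return(.aq_test("one_way_anova", 0, c(k - 1L, N - k), 1, alpha,
                      "two_sided"))
    return(.aq_test("one_way_anova", Inf, c(k - 1L, N - k), 0, alpha,
                    "two_sided"))
  }
  tab <- summary(stats::aov(y ~ g))[[1]]
  .aq_test("one_way_anova", tab[["F value"]][1],
           c(tab[["Df"]][1], tab[["Df"]][2]), tab[["Pr(>F)"]][1], alpha,
           "two_sided")
}

#' Compare dipolar transition rates against the zero-field case
#'
#' One-tailed paired t-test (direction `greater`) on per-pore transition
#' rates at the 90% level, the criterion used for reporting accelerated
#' flipping kinetics under field pulses.
#'
#' @param rates_field,rates_zero per-pore rates (1/ns), paired by pore;
#'   both must be complete (no missing pores).
#' @param alpha significance level (default 0.10).
#' @return Object of class `aq_test`.
#' @export
compare_transition_rates <- function(rates_field, rates_zero, alpha = 0.10) {
  if (length(rates_field) != length(rates_zero) ||
      anyNA(rates_field) || anyNA(rates_zero))
    stop("transition-rate comparison requires complete per-pore pairing")
  paired_one_tailed_t(rates_field, rates_zero, direction = "greater",
                      alpha = alpha)
}

#' Summarise one field condition across the four pores
#'
#' @param condition signed field intensity (V/A; 0 = zero field).
#' @param per_pore_pf named length-4 vector of per-pore p_f (cm^3/s),
#'   averaged over replicas.
#' @param replicas replica count behind each value.
#' @return Object of class `aq_condition_summary` with the mean and the
#'   standard deviation across the four channels (the error bar).
#' @export
condition_summary <- function(condition, per_pore_pf, replicas = 1L) {
  if (length(per_pore_pf) != 4) stop("per_pore_pf must have 4 values (pores A-D)")
  structure(list(condition = condition, per_pore_pf = per_pore_pf,
                 mean_pf = mean(per_pore_pf),
                 sd_pf = stats::sd(per_pore_pf),
                 replicas = as.integer(replicas)),
            class = "aq_condition_summary")
}
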