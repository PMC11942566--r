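#' Potency fold-shift
#'
#' The ratio of linear-scale potencies implied by two pEC50 values:
#' `10^(pec50_treated - pec50_vehicle)`. A value above 1 is a leftward
#' (potentiating) shift.
#'
#' @param pec50_treated,pec50_vehicle pEC50 values (-log10 M).
#' @return Dimensionless fold shift.
#' @examples
#' fold_shift(3.81, 3.55)  # 1.8-fold
#' fold_shift(3.94, 3.06)  # 7.6-fold
#' @export
fold_shift <- function(pec50_treated, pec50_vehicle) {
  stopifnot(is.finite(pec50_treated), is.finite(pec50_vehicle))
  10^(pec50_treated - pec50_vehicle)
}

#' One-way ANOVA with Dunnett many-to-one comparisons across a compound panel
#'
#' For each allosteric parameter, runs a one-way ANOVA over compounds on
#' per-experiment estimates and compares every compound to the designated
#' reference with Dunnett's test, which controls the familywise error rate at
#' `alpha` over the many-to-one family via the multivariate-t distribution of
#' the comparison statistics. Each parameter is its own family. For unequal
#' group sizes the correlation structure uses the exact per-group n.
#'
#' @param estimates long data frame with columns `compound`, `parameter`,
#'   `value` - one row per independent experiment per parameter (the
#'   `per_experiment` table of [fit_operational_per_experiment()] reshaped by
#'   [panel_estimates()]).
#' @param reference compound id compared against (must be present).
#' @param alpha familywise significance level.
#' @param seed seed for the quasi-Monte-Carlo multivariate-t evaluation, so
#'   adjusted p-values are reproducible (accurate to ~1e-4).
#' @return An object of class `panel_comparison` with elements `summaries`
#'   (mean, SEM, n per compound x parameter), `anova` (F and p per
#'   parameter), `comparisons` (Dunnett-adjusted p and significance flags),
#'   `reference` and `alpha`.
#' @export
anova_dunnett <- function(estimates, reference, alpha = 0.05, seed = 1) {
  stopifnot(all(c("compound", "parameter", "value") %in% names(estimates)))
  estimates <- estimates[is.finite(estimates$value), , drop = FALSE]
  if (!reference %in% estimates$compound)
    stop(sprintf("reference compound '%s' not found", reference))
  params <- unique(estimates$parameter)
  summaries <- anova_tab <- comps <- list()
  for (pm in params) {
    d <- estimates[estimates$parameter == pm, , drop = FALSE]
    counts <- table(d$compound)
    d <- d[d$compound %in% names(counts)[counts >= 2], , drop = FALSE]
    grp <- stats::aggregate(value ~ compound, d, function(v)
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
        n = length(v)))
    summaries[[pm]] <- data.frame(parameter = pm,
                                  compound = grp$compound,
                                  mean = grp$value[, "mean"],
                                  sem = grp$value[, "sem"],
                                  n = grp$value[, "n"])
    if (length(unique(d$compound)) < 2 || !reference %in% d$compound) next
    d$compound <- stats::relevel(factor(d$compound), ref = reference)
    fit <- stats::aov(value ~ compound, data = d)
    an <- summary(fit)[[1]]
    anova_tab[[pm]] <- data.frame(parameter = pm,
                                  F = an$`F value`[1],
                                  p = an$`Pr(>F)`[1])
    gl <- multcomp::glht(fit,
                         linfct = multcomp::mcp(compound = "Dunnett"))
    sm <- with_seed(seed, summary(gl))
    cf <- sm$test
    nm <- sub(" - .*$", "", names(cf$coefficients))
    comps[[pm]] <- data.frame(parameter = pm, compound = nm,
                              diff = unname(cf$coefficients),
                              se = unname(cf$sigma),
                              t = unname(cf$tstat),
                              p_adj = unname(as.numeric(cf$pvalues)),
                              significant = unname(
                                as.numeric(cf$pvalues) < alpha))
  }
  structure(list(summaries = do.call(rbind, c(summaries,
                                              make.row.names = FALSE)),
                 anova = do.call(rbind, c(anova_tab,
                                          make.row.names = FALSE)),
                 comparisons = do.call(rbind, c(comps,
                                                make.row.names = FALSE)),
                 reference = reference, alpha = alpha),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat(sprintf("Panel comparison vs reference '%s' (alpha = %g)\n",
              x$reference, x$alpha))
  if (!is.null(x$anova)) {
    cat("One-way ANOVA per parameter:\n")
    print(transform(x$anova, F = round(F, 2), p = signif(p, 3)))
  }
  if (!is.null(x$comparisons)) {
    cat("Dunnett comparisons vs reference:\n")
    print(transform(x$comparisons, diff = round(diff, 3),
                    se = round(se, 3), t = round(t, 2),
                    p_adj = signif(p_adj, 3)))
  }
  invisible(x)
}

#' Reshape per-compound fits into the long estimate table for ANOVA/Dunnett
#'
#' @param fits named list of `op_fit` objects with
#'   `mode = "per_experiment"`.
#' @param parameters which parameters to extract.
#' @return Long data frame `compound, parameter, experiment, value`, restricted
#'   to converged per-experiment fits.
#' @export
panel_estimates <- function(fits,
                            parameters = c("pkb", "log_alpha_beta",
                                           "log_tau_b")) {
  rows <- list()
  for (id in names(fits)) {
    per <- fits[[id]]$per_experiment
    if (is.null(per)) next
    per <- per[per$status == "converged", , drop = FALSE]
    if (!nrow(per)) next
    for (pm in parameters) {
      if (!pm %in% names(per)) next
      rows[[length(rows) + 1L]] <- data.frame(
        compound = id, parameter = pm, experiment = per$experiment,
        value = per[[pm]])
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Pharmacological profile classification
#'
#' Labels a fitted compound as `ago-PAM` (positive cooperativity plus
#' detectable intrinsic agonism), `pure PAM` (positive cooperativity, agonism
#' absent or not determined), `NAM-or-neutral` (no significant positive
#' cooperativity) or `ND` (ambiguous/failed fit). Positive cooperativity
#' requires the lower confidence bound of `log_alpha_beta` to exceed 0;
#' intrinsic agonism requires the `log_tau_b` confidence interval to exclude
#' the no-agonism region `log_tau_b <= tau_null` (default -1, i.e. tauB <=
#' 0.1, under 9% of the system maximum attainable without agonist).
#' Confidence intervals use the t distribution with `n - 1` degrees of
#' freedom for per-experiment summaries, or the residual degrees of freedom
#' for a global fit.
#'
#' @param fit an `op_fit` (or a list with `estimates`, `se`, and `n` or
#'   `dof`).
#' @param alpha two-sided significance level for the intervals.
#' @param tau_null upper edge (log10 scale) of the no-agonism region.
#' @return One of `"ago-PAM"`, `"pure PAM"`, `"NAM-or-neutral"`, `"ND"`.
#' @export
classify_profile <- function(fit, alpha = 0.05, tau_null = -1) {
  if (!is.null(fit$status) && !identical(fit$status, "converged"))
    return("ND")
  est <- fit$estimates; se <- fit$se
  df <- if (!is.null(fit$n) && is.finite(fit$n) && fit$n > 1) fit$n - 1
  else if (!is.null(fit$dof) && is.finite(fit$dof)) fit$dof else Inf
  crit <- stats::qt(1 - alpha / 2, df)
  lo <- function(par) est[[par]] - crit * (if (is.na(se[[par]])) Inf
                                           else se[[par]])
  coop_pos <- is.finite(est[["log_alpha_beta"]]) &&
    lo("log_alpha_beta") > 0
  agonism <- is.finite(est[["log_tau_b"]]) && !is.na(se[["log_tau_b"]]) &&
    lo("log_tau_b") > tau_null
  if (coop_pos && agonism) "ago-PAM"
  else if (coop_pos) "pure PAM"
  else "NAM-or-neutral"
}

format_log_entry <- function(est, se, linear) {
  if (is.na(est)) return("ND")
  sprintf("%.2f ± %.2f (%s)", est, se, format_linear(linear))
}

#' Reference-style panel summary table
#'
#' Renders per-compound parameter summaries the way PAM panels are reported:
#' log-scale estimate +/- SEM to two decimals with the linear-scale value in
#' parentheses (affinity as KB in uM), plus n and the pharmacological profile
#' label. Not-determined (ambiguous) fits propagate as "ND".
#'
#' @param fits named list of `op_fit` objects (any mode).
#' @param alpha significance level for profile classification.
#' @param tau_null no-agonism boundary passed to [classify_profile()].
#' @return A data frame with one row per compound and columns
#'   `compound, pKB, log_alpha_beta, log_tau_b, n, profile`.
#' @export
summarize_panel <- function(fits, alpha = 0.05, tau_null = -1) {
  if (!length(fits))
    return(data.frame(compound = character(), pKB = character(),
                      log_alpha_beta = character(),
                      log_tau_b = character(), n = integer(),
                      profile = character()))
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    ok <- identical(f$status, "converged")
    est <- if (ok) f$estimates else NULL
    se <- if (ok) f$se else NULL
    cell <- function(par, linear) {
      if (!ok || is.na(est[[par]])) "ND"
      else format_log_entry(est[[par]], se[[par]], linear)
    }
    data.frame(
      compound = id,
      pKB = if (ok) cell("pkb", kb_micromolar(est[["pkb"]])) else "ND",
      log_alpha_beta = if (ok)
        cell("log_alpha_beta", to_linear(est[["log_alpha_beta"]])) else "ND",
      log_tau_b = if (ok)
        cell("log_tau_b", to_linear(est[["log_tau_b"]])) else "ND",
      n = if (!is.null(f$n)) f$n else NA_integer_,
      profile = classify_profile(f, alpha = alpha, tau_null = tau_null))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
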