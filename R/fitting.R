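#' Fitting configuration
#'
#' Bounds, multi-start grid, convergence control and identifiability
#' thresholds for the global operational-model fit. Affinity, cooperativity,
#' efficacy and potency are estimated as logarithms; the system maximum and
#' binding slope are estimated on the linear scale within bounds bracketing
#' plausible assay behaviour. The multi-start grid covers the log-scale
#' allosteric parameters because the least-squares surface is multimodal for
#' weak modulators.
#'
#' @param lower,upper named bounds on the estimation scale for
#'   `em, pec50, nb, pkb, log_alpha_beta, log_tau_b`.
#' @param start_pkb,start_log_ab,start_log_tau deterministic multi-start grid
#'   values for the allosteric parameters (crossed; best final SSR wins, ties
#'   broken by grid order).
#' @param start_nb,start_pec50 starting values for the shared curve shape.
#' @param se_threshold identifiability rule (i): an ambiguous fit is declared
#'   when any log-scale parameter SE exceeds this (log units).
#' @param flat_delta identifiability rule (iii): relative SSR increase below
#'   which a +/-`flat_step` perturbation of a parameter counts as flat.
#' @param flat_step size of the profile perturbation (log units).
#' @param bound_tol relative distance to a bound that triggers rule (ii).
#' @param ftol relative SSR convergence tolerance.
#' @param maxiter maximum optimizer iterations per start.
#' @param n_best_starts if smaller than the full grid, only this many starts
#'   (ranked by initial SSR) are polished by the optimizer; the ranking is
#'   deterministic.
#' @param min_experiments minimum converged experiments for per-experiment
#'   summaries.
#' @param ambient_c fallback ambient agonist concentration (M) when the
#'   dataset does not carry a design.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(em = 1e-3, pec50 = 1, nb = 0.3, pkb = 2,
                                 log_alpha_beta = -2, log_tau_b = -5),
                       upper = c(em = 150, pec50 = 6, nb = 6, pkb = 9,
                                 log_alpha_beta = 4, log_tau_b = 3),
                       start_pkb = c(4, 5, 6),
                       start_log_ab = c(0, 1, 2),
                       start_log_tau = c(-1, 0, 1),
                       start_nb = 2.5, start_pec50 = 3.3,
                       se_threshold = 1.0, flat_delta = 0.01, flat_step = 1.0,
                       bound_tol = 1e-4, ftol = 1e-10, maxiter = 1000,
                       n_best_starts = 27L, min_experiments = 3L,
                       ambient_c = 1e-4) {
  structure(list(lower = lower, upper = upper, start_pkb = start_pkb,
                 start_log_ab = start_log_ab, start_log_tau = start_log_tau,
                 start_nb = start_nb, start_pec50 = start_pec50,
                 se_threshold = se_threshold, flat_delta = flat_delta,
                 flat_step = flat_step, bound_tol = bound_tol, ftol = ftol,
                 maxiter = maxiter, n_best_starts = as.integer(n_best_starts),
                 min_experiments = as.integer(min_experiments),
                 ambient_c = ambient_c),
            class = "fit_config")
}

.op_par_names <- c("em", "pec50", "nb", "pkb", "log_alpha_beta", "log_tau_b")

# model mean for a parameter vector on the estimation scale
.op_mu <- function(theta, A, B, ambient_c) {
  p <- list(em = theta[["em"]], pec50 = theta[["pec50"]], nb = theta[["nb"]],
            nt = 1, pkb = theta[["pkb"]],
            log_alpha_beta = theta[["log_alpha_beta"]],
            log_tau_b = theta[["log_tau_b"]], ambient_c = ambient_c,
            nt_fixed = TRUE)
  operational_response(A, B, p)
}

.nlslm <- function(par, fn, lower, upper, ftol, maxiter) {
  minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                     control = minpack.lm::nls.lm.control(
                       ftol = ftol, maxiter = min(maxiter, 1024)))
}

.se_from_fit <- function(fit) {
  tryCatch({
    sm <- summary(fit)
    se <- stats::coef(sm)[, "Std. Error"]
    names(se) <- names(fit$par)
    se
  }, error = function(e) {
    stats::setNames(rep(NA_real_, length(fit$par)), names(fit$par))
  })
}

#' Global fit of the operational model to an interaction dataset
#'
#' Minimises the summed squared residuals over all curves of the dataset
#' simultaneously, with the system maximum (`em`), agonist potency (`pec50`),
#' binding slope (`nb`), allosteric affinity (`pkb`), cooperativity
#' (`log_alpha_beta`) and intrinsic efficacy (`log_tau_b`) shared across every
#' experiment, and the transducer slope fixed at unity. Optimisation is
#' Levenberg-Marquardt with box bounds from a deterministic multi-start grid
#' over the allosteric parameters; asymptotic standard errors come from the
#' curvature at the optimum. The fit status is then set by
#' [assess_identifiability()].
#'
#' @param data an `interaction_dataset` containing a vehicle (`conc_B_M = 0`)
#'   curve and at least two non-zero modulator concentrations.
#' @param config a [fit_config()].
#' @param assess run identifiability diagnostics (profile refits); disable for
#'   bulk simulation studies where only point estimates are needed.
#' @return An object of class `op_fit` with elements `estimates`, `se`,
#'   `status` (`converged`, `ambiguous` or `failed`), `mode`
#'   (`"global_collated"`), `fixed`, `rss`, `residual_sd`, `dof`, `nobs`,
#'   `identifiability` and `starts`.
#' @export
fit_operational_global <- function(data, config = fit_config(),
                                   assess = TRUE) {
  if (!inherits(data, "interaction_dataset"))
    data <- new_interaction_dataset(as.data.frame(data))
  B_levels <- sort(unique(data$conc_B_M))
  if (!any(B_levels == 0))
    stop("dataset must contain a vehicle (conc_B_M = 0) curve")
  if (sum(B_levels > 0) < 2)
    stop("dataset must contain at least two non-zero modulator concentrations")
  design <- attr(data, "design")
  ambient_c <- if (!is.null(design)) design$ambient_c else config$ambient_c

  A <- data$conc_A_M; B <- data$conc_B_M; y <- data$response_pct
  resid_fn <- function(theta) {
    names(theta) <- .op_par_names
    y - .op_mu(theta, A, B, ambient_c)
  }

  em0 <- min(max(y) * 1.05 + 1e-6, config$upper[["em"]])
  starts <- expand.grid(pkb = config$start_pkb,
                        log_alpha_beta = config$start_log_ab,
                        log_tau_b = config$start_log_tau,
                        KEEP.OUT.ATTRS = FALSE)
  start_list <- lapply(seq_len(nrow(starts)), function(i)
    c(em = em0, pec50 = config$start_pec50, nb = config$start_nb,
      pkb = starts$pkb[i], log_alpha_beta = starts$log_alpha_beta[i],
      log_tau_b = starts$log_tau_b[i]))

  # deterministic pre-screen: rank starts by initial SSR, polish the best
  if (config$n_best_starts < length(start_list)) {
    ssr0 <- vapply(start_list, function(th) sum(resid_fn(th)^2), numeric(1))
    keep <- order(ssr0)[seq_len(config$n_best_starts)]
    start_list <- start_list[sort(keep)]
  }

  fits <- vector("list", length(start_list))
  log <- data.frame(start = seq_along(start_list), ssr = NA_real_,
                    converged = FALSE)
  for (i in seq_along(start_list)) {
    fits[[i]] <- tryCatch(
      .nlslm(start_list[[i]], resid_fn, config$lower, config$upper,
             config$ftol, config$maxiter),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) {
      log$ssr[i] <- fits[[i]]$deviance
      log$converged[i] <- TRUE
    }
  }
  ok <- which(log$converged)
  if (!length(ok)) {
    return(new_op_fit(status = "failed", mode = "global_collated",
                      nobs = length(y), ambient_c = ambient_c,
                      compound = unique(data$compound), starts = log))
  }
  best <- fits[[ok[which.min(log$ssr[ok])]]]
  theta <- best$par; names(theta) <- .op_par_names
  se <- .se_from_fit(best)
  dof <- length(y) - length(theta)
  # "no apparent agonism": if pinning tauB at its floor (tauB ~ 0) leaves the
  # SSR essentially unchanged, the data carry no information on intrinsic
  # efficacy and it is reported as not determined while the other parameters
  # stand. Detected by a one-sided zero-agonism refit.
  tau_nd <- theta[["log_tau_b"]] <= config$lower[["log_tau_b"]] + 0.01
  if (!tau_nd) {
    free <- setdiff(.op_par_names, "log_tau_b")
    rf0 <- function(sub) {
      full <- theta
      full[free] <- sub
      full[["log_tau_b"]] <- config$lower[["log_tau_b"]]
      y - .op_mu(full, A, B, ambient_c)
    }
    ref0 <- tryCatch(
      .nlslm(theta[free], rf0, config$lower[free], config$upper[free],
             config$ftol, config$maxiter),
      error = function(e) NULL)
    if (!is.null(ref0)) {
      rel <- (ref0$deviance - best$deviance) /
        max(best$deviance, 1e-6 * length(y))
      tau_nd <- rel < config$flat_delta
    }
  }
  if (tau_nd) {
    theta[["log_tau_b"]] <- NA_real_
    se[["log_tau_b"]] <- NA_real_
  }
  fit <- new_op_fit(
    estimates = theta, se = se, status = "converged",
    mode = "global_collated", fixed = c(nt = 1),
    rss = best$deviance, residual_sd = sqrt(best$deviance / dof),
    dof = dof, nobs = length(y), ambient_c = ambient_c,
    compound = unique(data$compound), starts = log,
    data = data, config = config)
  if (assess) {
    st <- assess_identifiability(fit, config)
    fit$identifiability <- list(flags = attr(st, "diagnostics"))
    fit$status <- as.character(st)
  }
  fit
}

new_op_fit <- function(estimates = NULL, se = NULL, status, mode,
                       fixed = c(nt = 1), rss = NA_real_,
                       residual_sd = NA_real_, dof = NA_integer_, nobs,
                       ambient_c = NA_real_, compound = NA_character_,
                       n = NULL, per_experiment = NULL, starts = NULL,
                       data = NULL, config = NULL,
                       identifiability = NULL) {
  structure(list(estimates = estimates, se = se, status = status, mode = mode,
                 fixed = fixed, rss = rss, residual_sd = residual_sd,
                 dof = dof, nobs = nobs, ambient_c = ambient_c,
                 compound = compound, n = n, per_experiment = per_experiment,
                 starts = starts, data = data, config = config,
                 identifiability = identifiability),
            class = "op_fit")
}

#' @export
print.op_fit <- function(x, ...) {
  cat(sprintf("Operational model fit (%s), status: %s\n", x$mode, x$status))
  if (!is.null(x$estimates)) {
    tab <- data.frame(estimate = round(x$estimates, 3),
                      se = round(x$se, 3))
    print(tab)
    cat(sprintf("  residual SD %.3g on %d dof (%d obs); nT fixed at %g\n",
                x$residual_sd, x$dof, x$nobs, x$fixed[["nt"]]))
  }
  if (x$status != "converged" && !is.null(x$identifiability))
    cat("  flags:", paste(x$identifiability$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.op_fit <- function(object, ...) {
  if (identical(object$status, "converged")) object$estimates
  else stats::setNames(rep(NA_real_, length(.op_par_names)), .op_par_names)
}

#' Identifiability diagnostics for an operational-model fit
#'
#' Classifies a completed optimisation as `converged` or `ambiguous` by three
#' rules, a proxy for the flat / unbounded fits that practitioners report as
#' "not determined": (i) the standard error of any log-scale parameter
#' (`pkb`, `log_alpha_beta`, `log_tau_b`, `pec50`) exceeds
#' `config$se_threshold` (or is not computable); (ii) any estimate sits at a
#' box bound; (iii) profile flatness - refitting with one allosteric parameter
#' fixed 1 log unit away from its optimum raises the SSR by less than
#' `config$flat_delta` of its minimum, in at least one direction.
#'
#' @param fit an `op_fit` from [fit_operational_global()].
#' @param config a [fit_config()]; thresholds are taken from it.
#' @return The status string, with a `diagnostics` attribute listing the
#'   fired rules.
#' @export
assess_identifiability <- function(fit, config = fit_config()) {
  stopifnot(inherits(fit, "op_fit"))
  if (identical(fit$status, "failed")) return("failed")
  flags <- character(0)
  # a tauB reported as not determined (no apparent agonism) is excluded from
  # the rules: the rest of the fit can be perfectly identified without it
  determined <- names(fit$estimates)[!is.na(fit$estimates)]
  log_pars <- intersect(c("pkb", "log_alpha_beta", "log_tau_b", "pec50"),
                        determined)

  se <- fit$se[log_pars]
  if (any(is.na(se)) || any(se > config$se_threshold))
    flags <- c(flags, sprintf(
      "large or undefined SE: %s",
      paste(log_pars[is.na(se) | se > config$se_threshold], collapse = ",")))

  th <- fit$estimates[determined]
  rng <- (config$upper - config$lower)[determined]
  at_bound <- names(th)[th <= config$lower[determined] +
                          config$bound_tol * rng |
                          th >= config$upper[determined] -
                          config$bound_tol * rng]
  if (length(at_bound))
    flags <- c(flags, sprintf("estimate at bound: %s",
                              paste(at_bound, collapse = ",")))

  # profile flatness; only needed when rules (i)-(ii) have not already fired
  if (!length(flags) && !is.null(fit$data)) {
    A <- fit$data$conc_A_M; B <- fit$data$conc_B_M
    y <- fit$data$response_pct
    th0 <- fit$estimates   # full vector; an ND tauB re-enters at its floor
    th0[is.na(th0)] <- config$lower[names(th0)][is.na(th0)]
    for (par in intersect(c("pkb", "log_alpha_beta", "log_tau_b"),
                          determined)) {
      free <- setdiff(.op_par_names, par)
      for (dir in c(-1, 1)) {
        fixed_val <- th0[[par]] + dir * config$flat_step
        fixed_val <- min(max(fixed_val, config$lower[[par]]),
                         config$upper[[par]])
        if (abs(fixed_val - th0[[par]]) < 0.5 * config$flat_step) next
        rf <- function(sub) {
          full <- th0
          full[free] <- sub
          full[[par]] <- fixed_val
          y - .op_mu(full, A, B, fit$ambient_c)
        }
        ref <- tryCatch(
          .nlslm(th0[free], rf, config$lower[free], config$upper[free],
                 config$ftol, config$maxiter),
          error = function(e) NULL)
        if (!is.null(ref) &&
            (ref$deviance - fit$rss) / fit$rss < config$flat_delta) {
          flags <- c(flags, sprintf("flat profile: %s (%+d log unit)",
                                    par, dir))
          break
        }
      }
      if (length(flags)) break
    }
  }

  status <- if (length(flags)) "ambiguous" else "converged"
  attr(status, "diagnostics") <- flags
  status
}

#' Per-experiment operational-model fits with across-experiment summaries
#'
#' Fits each independent experiment separately with
#' [fit_operational_global()] and summarises each parameter as mean +/- SEM
#' across the converged experiments, the form in which panel values are
#' reported and the input expected by [anova_dunnett()].
#'
#' @param data an `interaction_dataset` with at least
#'   `config$min_experiments` experiments.
#' @param config a [fit_config()].
#' @param assess run identifiability diagnostics on each experiment's fit.
#' @return An `op_fit` with `mode = "per_experiment"`, `estimates` the means,
#'   `se` the SEMs, `n` the number of converged experiments, and
#'   `per_experiment` the per-experiment estimate table.
#' @export
fit_operational_per_experiment <- function(data, config = fit_config(),
                                           assess = TRUE) {
  if (!inherits(data, "interaction_dataset"))
    data <- new_interaction_dataset(as.data.frame(data))
  exps <- sort(unique(data$experiment))
  if (length(exps) < config$min_experiments)
    stop(sprintf("need at least %d experiments, got %d",
                 config$min_experiments, length(exps)))
  design <- attr(data, "design")
  rows <- vector("list", length(exps))
  for (i in seq_along(exps)) {
    sub <- data[data$experiment == exps[i], , drop = FALSE]
    sub <- new_interaction_dataset(as.data.frame(sub), design = design)
    f <- fit_operational_global(sub, config, assess = assess)
    est <- if (is.null(f$estimates))
      stats::setNames(rep(NA_real_, 6), .op_par_names) else f$estimates
    rows[[i]] <- data.frame(experiment = exps[i], status = f$status,
                            t(est))
  }
  per <- do.call(rbind, rows)
  ok <- per$status == "converged"
  if (sum(ok) < config$min_experiments) {
    return(new_op_fit(status = "failed", mode = "per_experiment",
                      nobs = nrow(data), per_experiment = per,
                      compound = unique(data$compound),
                      n = sum(ok)))
  }
  # tauB may be ND (no apparent agonism) in some experiments; summaries use
  # the experiments where it was determined, and stay ND if it never was
  est_mat <- as.matrix(per[ok, .op_par_names, drop = FALSE])
  means <- colMeans(est_mat, na.rm = TRUE)
  kper <- colSums(!is.na(est_mat))
  sems <- apply(est_mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(kper, 1))
  means[kper == 0] <- NA_real_
  sems[kper == 0] <- NA_real_
  new_op_fit(estimates = means, se = sems, status = "converged",
             mode = "per_experiment", fixed = c(nt = 1),
             nobs = nrow(data), n = sum(ok), per_experiment = per,
             compound = unique(data$compound),
             ambient_c = if (!is.null(design)) design$ambient_c
             else config$ambient_c)
}

#' Joint four-parameter sigmoid fit with one shared Hill slope
#'
#' The empirical fallback analysis when the operational model is ambiguous:
#' each modulator concentration's agonist curve gets its own floor, ceiling
#' and pEC50, while a single Hill slope is shared across all curves; all
#' parameters are estimated jointly by least squares. Per-curve pEC50 values
#' feed potency fold-shift comparisons.
#'
#' @param data an `interaction_dataset`; curves are defined by `conc_B_M`
#'   (>= 2 distinct values required).
#' @param ftol,maxiter optimizer control.
#' @return An object of class `hill_fit`: `shared_slope` +/- SE, a `curves`
#'   data frame (`conc_B_M, bottom, top, pec50, pec50_se`), `rss`,
#'   `residual_sd`, `dof` and `status`.
#' @export
fit_hill_shared_slope <- function(data, ftol = 1e-10, maxiter = 1000) {
  if (!inherits(data, "interaction_dataset"))
    data <- new_interaction_dataset(as.data.frame(data))
  B_levels <- sort(unique(data$conc_B_M))
  k <- length(B_levels)
  if (k < 2) stop("need at least two curves (distinct conc_B_M values)")
  curve <- match(data$conc_B_M, B_levels)
  A <- data$conc_A_M; y <- data$response_pct

  # starts: per-curve range and a crude half-max crossing
  b0 <- t0 <- e0 <- numeric(k)
  for (j in seq_len(k)) {
    idx <- curve == j
    b0[j] <- min(y[idx]); t0[j] <- max(y[idx])
    mid <- (b0[j] + t0[j]) / 2
    nz <- idx & A > 0
    e0[j] <- if (any(nz)) -log10(A[nz][which.min(abs(y[nz] - mid))]) else 3
  }
  theta0 <- c(slope = 3, bottom = b0, top = t0, pec50 = e0)
  lower <- c(0.2, rep(-50, k), rep(0, k), rep(0.5, k))
  upper <- c(10, rep(150, k), rep(200, k), rep(8, k))

  unpack <- function(theta) list(slope = theta[1],
                                 bottom = theta[1 + seq_len(k)],
                                 top = theta[1 + k + seq_len(k)],
                                 pec50 = theta[1 + 2 * k + seq_len(k)])
  resid_fn <- function(theta) {
    q <- unpack(theta)
    frac <- 1 / (1 + 10^(q$slope * (-q$pec50[curve] - log10(A))))
    frac[A == 0] <- 0
    y - (q$bottom[curve] + (q$top[curve] - q$bottom[curve]) * frac)
  }
  fit <- tryCatch(
    .nlslm(theta0, resid_fn, lower, upper, ftol, maxiter),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(status = "failed"), class = "hill_fit"))
  se <- .se_from_fit(fit)
  q <- unpack(fit$par)
  qse <- unpack(se)
  dof <- length(y) - length(fit$par)
  structure(list(
    shared_slope = unname(q$slope), shared_slope_se = unname(qse$slope),
    curves = data.frame(conc_B_M = B_levels, bottom = q$bottom, top = q$top,
                        pec50 = q$pec50, pec50_se = qse$pec50),
    rss = fit$deviance, residual_sd = sqrt(fit$deviance / dof), dof = dof,
    nobs = length(y), status = "converged"), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Shared-slope sigmoid fit, status: %s\n", x$status))
  if (identical(x$status, "converged")) {
    cat(sprintf("  shared Hill slope %.2f +/- %.2f; residual SD %.3g\n",
                x$shared_slope, x$shared_slope_se, x$residual_sd))
    print(transform(x$curves, bottom = round(bottom, 1),
                    top = round(top, 1), pec50 = round(pec50, 2),
                    pec50_se = round(pec50_se, 2)))
  }
  invisible(x)
}
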