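#' allofit: operational-model pharmacology for allosteric modulator assays
#'
#' Quantitative tools for calcium-mobilisation interaction experiments at the
#' calcium-sensing receptor (CaSR) and similar GPCRs: the operational model of
#' cooperative agonism and allosteric modulation (with an ambient-agonist
#' correction), global nonlinear estimation of allosteric affinity, cooperativity
#' and intrinsic efficacy, a shared-slope sigmoid fallback, synthetic interaction
#' data generation, and panel statistics (ANOVA + Dunnett, profile
#' classification).
#'
#' @keywords internal
"_PACKAGE"

#' Operational-model parameter set
#'
#' Bundles every parameter of the operational model of cooperative agonism and
#' allosteric modulation. Affinity, cooperativity and intrinsic efficacy are
#' carried on the log10 scale, matching how they are estimated and reported;
#' linear-scale counterparts are `10^x` (affinity: `KB = 10^(-pKB)` M).
#' Cooperativity is carried as the combined product `alpha*beta` because the
#' two factors are not separately identifiable in a single functional assay;
#' if `log_alpha` and `log_beta` are supplied they are summed immediately.
#'
#' @param pkb -log10 of the allosteric ligand dissociation constant KB (M).
#' @param log_alpha_beta log10 of combined cooperativity alpha*beta.
#'   `> 0` means positive modulation. Ignored if `log_alpha`/`log_beta` given.
#' @param log_tau_b log10 of the allosteric ligand's operational intrinsic
#'   efficacy tauB. Use `-Inf` for a ligand with no intrinsic agonism.
#' @param em maximal system response (% ionomycin).
#' @param pec50 -log10 of the orthosteric agonist EC50 (M).
#' @param nb binding slope linking agonist concentration to occupancy.
#' @param nt transducer slope; fixed at unity in the standard analysis.
#' @param ambient_c ambient orthosteric agonist concentration (M) already in
#'   the assay buffer, added to every applied agonist concentration.
#' @param log_alpha,log_beta optional separate cooperativity components,
#'   combined into `log_alpha_beta` on construction.
#'
#' @return An object of class `operational_params`. The element `nt_fixed`
#'   records whether the transducer slope is constrained to unity.
#' @examples
#' p <- operational_params(pkb = 5.47, log_alpha_beta = 1.63, log_tau_b = 0.12)
#' operational_response(1e-3, 1e-5, p)
#' @export
operational_params <- function(pkb, log_alpha_beta, log_tau_b,
                               em = 100, pec50 = 3.3, nb = 3, nt = 1,
                               ambient_c = 1e-4,
                               log_alpha = NULL, log_beta = NULL) {
  if (!is.null(log_alpha) || !is.null(log_beta)) {
    if (is.null(log_alpha) || is.null(log_beta))
      stop("supply both 'log_alpha' and 'log_beta', or 'log_alpha_beta' alone")
    log_alpha_beta <- log_alpha + log_beta
  }
  p <- list(em = em, pec50 = pec50, nb = nb, nt = nt, pkb = pkb,
            log_alpha_beta = log_alpha_beta, log_tau_b = log_tau_b,
            ambient_c = ambient_c, nt_fixed = isTRUE(all.equal(nt, 1)))
  validate_operational_params(p)
  class(p) <- "operational_params"
  p
}

validate_operational_params <- function(p) {
  num1 <- function(x, what, allow_inf = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x)))
      stop(sprintf("'%s' must be a single finite number", what))
  }
  num1(p$em, "em"); num1(p$pec50, "pec50"); num1(p$nb, "nb")
  num1(p$nt, "nt"); num1(p$pkb, "pkb"); num1(p$log_alpha_beta, "log_alpha_beta")
  num1(p$log_tau_b, "log_tau_b", allow_inf = TRUE)
  num1(p$ambient_c, "ambient_c")
  if (p$em <= 0) stop("'em' must be > 0")
  if (p$nb <= 0) stop("'nb' must be > 0")
  if (p$nt <= 0) stop("'nt' must be > 0")
  if (p$ambient_c < 0) stop("'ambient_c' must be >= 0")
  if (p$log_tau_b == Inf) stop("'log_tau_b' must be < Inf")
  invisible(p)
}

#' @export
print.operational_params <- function(x, ...) {
  cat("Operational model parameters\n")
  cat(sprintf("  Em %.4g %% ionomycin | pEC50 %.4g | nB %.4g | nT %.4g%s\n",
              x$em, x$pec50, x$nb, x$nt,
              if (x$nt_fixed) " (fixed)" else ""))
  cat(sprintf("  pKB %.4g (KB %.3g uM) | log(alpha*beta) %.4g (%.3g) | log(tauB) %.4g (%.3g)\n",
              x$pkb, kb_micromolar(x$pkb), x$log_alpha_beta,
              to_linear(x$log_alpha_beta), x$log_tau_b, to_linear(x$log_tau_b)))
  cat(sprintf("  ambient agonist %.3g M\n", x$ambient_c))
  invisible(x)
}

#' Four-parameter sigmoid parameters
#'
#' @param bottom,top response floor and ceiling (% ionomycin); `top > bottom`.
#' @param pec50 -log10 EC50 (M).
#' @param hill_slope Hill slope (> 0).
#' @return An object of class `hill_params`.
#' @examples
#' hill_response(10^-3.55, hill_params(0, 100, 3.55, 3.5))
#' @export
hill_params <- function(bottom, top, pec50, hill_slope) {
  stopifnot(is.numeric(bottom), is.numeric(top), is.numeric(pec50),
            is.numeric(hill_slope))
  if (!all(is.finite(c(bottom, top, pec50, hill_slope))))
    stop("hill parameters must be finite")
  if (top <= bottom) stop("'top' must exceed 'bottom'")
  if (hill_slope <= 0) stop("'hill_slope' must be > 0")
  structure(list(bottom = bottom, top = top, pec50 = pec50,
                 hill_slope = hill_slope), class = "hill_params")
}

.check_conc <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", what))
}

# pairwise log-sum-exp on natural-log scale; handles -Inf cleanly
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Operational model of cooperative agonism and allosteric modulation
#'
#' Response of a receptor system to orthosteric agonist `A` in the presence of
#' allosteric ligand `B`, with an ambient-agonist correction: the applied
#' agonist adds to the concentration `ambient_c` already present in the buffer.
#' With `Phi = (A + C)^nB * (KB + alpha*beta*B) + tauB * B * EC50^nB`,
#'
#' \deqn{E = \frac{E_m \Phi^{n_T}}{EC_{50}^{n_B n_T}(K_B+B)^{n_T} + \Phi^{n_T}}}
#'
#' Evaluation is carried out on the log scale so that steep slopes
#' (`nb * nt` powers) at extreme concentrations cannot overflow. At `B = 0`
#' and `nt = 1` the expression reduces exactly to the Hill function
#' `em * (A+C)^nb / (EC50^nb + (A+C)^nb)`.
#'
#' @param A applied orthosteric agonist concentration(s), M.
#' @param B allosteric ligand concentration(s), M. Recycled against `A`.
#' @param p an [operational_params()] object.
#' @return Response(s) in % ionomycin, in `[0, em)`.
#' @examples
#' p <- operational_params(5.47, 1.63, 0.12, em = 100, pec50 = 3.06, nb = 2)
#' operational_response(c(0, 1e-3), 1e-5, p)
#' @export
operational_response <- function(A, B, p) {
  validate_operational_params(p)
  .check_conc(A, "A"); .check_conc(B, "B")
  n <- max(length(A), length(B))
  A <- rep_len(A, n); B <- rep_len(B, n)
  kb <- 10^(-p$pkb)
  log_ec50 <- -p$pec50 * log(10)           # natural log of EC50
  ab <- 10^p$log_alpha_beta
  tau <- 10^p$log_tau_b

  # log Phi = logaddexp( nb*log(A+C) + log(kb + ab*B), log(tau*B) + nb*log(EC50) )
  t1 <- p$nb * log(A + p$ambient_c) + log(kb + ab * B)
  t2 <- log(tau * B) + p$nb * log_ec50
  log_phi <- .logaddexp(t1, t2)

  log_den1 <- p$nb * p$nt * log_ec50 + p$nt * log(kb + B)
  log_num <- p$nt * log_phi
  resp <- p$em * exp(log_num - .logaddexp(log_num, log_den1))
  resp[is.infinite(log_phi) & log_phi < 0] <- 0
  resp
}

#' Four-parameter sigmoidal concentration-response curve
#'
#' `bottom + (top - bottom) * A^slope / (EC50^slope + A^slope)`, the empirical
#' fallback used when an interaction cannot reliably be described by the
#' operational model.
#'
#' @param A agonist concentration(s), M (>= 0).
#' @param h a [hill_params()] object.
#' @return Response(s) in % ionomycin.
#' @export
hill_response <- function(A, h) {
  stopifnot(inherits(h, "hill_params"))
  .check_conc(A, "A")
  # fraction = 1 / (1 + 10^(slope * (logEC50 - logA))); A = 0 -> 0
  frac <- 1 / (1 + 10^(h$hill_slope * (-h$pec50 - log10(A))))
  frac[A == 0] <- 0
  h$bottom + (h$top - h$bottom) * frac
}

#' Log10 / linear parameter transforms
#'
#' Affinity, cooperativity and efficacy parameters are estimated and reported
#' as logarithms; `to_linear()` recovers the linear-scale value and `to_log()`
#' inverts it. For affinities the micromolar convention is
#' `KB (uM) = 10^(-pKB) * 1e6`, see [kb_micromolar()].
#'
#' @param log_value,linear_value numeric vectors.
#' @return `to_linear()` returns `10^log_value`; `to_log()` returns
#'   `log10(linear_value)` and errors on non-positive input.
#' @examples
#' to_linear(1.63)        # cooperativity alpha*beta = 43 (2 s.f.)
#' kb_micromolar(5.47)    # KB = 3.4 uM (2 s.f.)
#' @export
to_linear <- function(log_value) 10^log_value

#' @rdname to_linear
#' @export
to_log <- function(linear_value) {
  if (any(!is.finite(linear_value)) || any(linear_value <= 0))
    stop("'linear_value' must be positive and finite")
  log10(linear_value)
}

#' @rdname to_linear
#' @param pkb -log10 affinity in M.
#' @export
kb_micromolar <- function(pkb) 10^(-pkb) * 1e6

# Display rounding that reproduces the conventional printed table entries:
# >= 100 -> 3 significant digits (whole numbers), 1-100 -> 2 s.f., < 1 -> 1 d.p.
format_linear <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("ND")
    if (v >= 100) sprintf("%.0f", signif(v, 3))
    else if (v >= 10) sprintf("%.0f", signif(v, 2))
    else if (v >= 1) sprintf("%.1f", signif(v, 2))
    else sprintf("%.1f", v)
  }, character(1))
}

#' Observed potency of the composite agonist curve at a fixed modulator level
#'
#' Numerically locates the agonist concentration at which the operational
#' response reaches half of its span over `A` in `[0, Inf)` at fixed `B`, and
#' returns its -log10. The span runs from the response at `A = 0` (which
#' includes any allosteric agonism and the ambient-agonist contribution) up to
#' the system maximum `em`. Root finding is by bracketing bisection on log10
#' concentration to a relative tolerance of 1e-10.
#'
#' @param p an [operational_params()] object.
#' @param B modulator concentration, M (scalar).
#' @return The composite curve's pEC50 (-log10 M).
#' @export
observed_ec50 <- function(p, B) {
  validate_operational_params(p)
  .check_conc(B, "B")
  stopifnot(length(B) == 1L)
  r0 <- operational_response(0, B, p)
  span <- p$em - r0
  if (span < 1e-9 * p$em)
    stop("curve is flat at this modulator concentration; no EC50 exists")
  target <- r0 + span / 2
  f <- function(la) operational_response(10^la, B, p) - target
  lo <- -15; hi <- 3
  while (f(hi) < 0 && hi < 12) hi <- hi + 3   # defensive; em limit guarantees sign
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-11)$root
  -root
}

#' Maximal fold-shift in agonist potency produced by a modulator
#'
#' The saturating-modulator limit of the potency shift for a ligand with no
#' intrinsic efficacy (tauB = 0): the observed EC50 moves leftward by a factor
#' `(alpha*beta)^(1/nb)` as `B` grows without bound.
#'
#' @param p an [operational_params()] object.
#' @return Dimensionless fold shift.
#' @examples
#' max_fold_shift(operational_params(5.47, log10(43), -Inf, nb = 1))  # 43
#' @export
max_fold_shift <- function(p) {
  validate_operational_params(p)
  10^(p$log_alpha_beta / p$nb)
}
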