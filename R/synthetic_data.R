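#' Assay design for a simulated interaction experiment
#'
#' Describes the concentration grid and replication structure of an
#' extracellular-calcium x modulator interaction experiment, the layout in
#' which each modulator concentration is co-added with a full agonist titration
#' and every point is read in technical duplicate across several independent
#' experiments.
#'
#' @param agonist_concs added agonist (Ca2+) concentrations, M, sorted,
#'   non-negative; `0` means the ambient-only read.
#' @param modulator_concs modulator concentrations, M, sorted, non-negative,
#'   including the vehicle (`0`) column.
#' @param ambient_c ambient agonist concentration in the assay buffer, M.
#' @param replicates_per_point technical replicates per concentration pair.
#' @param n_experiments independent experiments.
#' @param noise_sd response noise SD on the normalised scale (% ionomycin).
#' @param experiment_scale_sd SD of an optional per-experiment multiplicative
#'   scale factor (0 disables inter-experiment jitter).
#' @param seed integer seed used by [simulate_dataset()] unless overridden.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(agonist_concs, modulator_concs, ambient_c = 1e-4,
                         replicates_per_point = 2, n_experiments = 5,
                         noise_sd = 4, experiment_scale_sd = 0, seed = 1) {
  .check_conc(agonist_concs, "agonist_concs")
  .check_conc(modulator_concs, "modulator_concs")
  if (is.unsorted(agonist_concs) || is.unsorted(modulator_concs))
    stop("concentration series must be sorted increasing")
  if (replicates_per_point < 1) stop("'replicates_per_point' must be >= 1")
  if (n_experiments < 1) stop("'n_experiments' must be >= 1")
  if (noise_sd < 0 || experiment_scale_sd < 0) stop("noise SDs must be >= 0")
  if (ambient_c < 0) stop("'ambient_c' must be >= 0")
  structure(list(agonist_concs = agonist_concs,
                 modulator_concs = modulator_concs,
                 ambient_c = ambient_c,
                 replicates_per_point = as.integer(replicates_per_point),
                 n_experiments = as.integer(n_experiments),
                 noise_sd = noise_sd,
                 experiment_scale_sd = experiment_scale_sd,
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' Default interaction assay design
#'
#' The standard layout: modulator at 0, 0.03, 0.1, 0.3, 1, 3, 10 and 30 uM
#' crossed with an 11-point agonist series (zero-added plus ten half-log-spaced
#' concentrations from 10 uM to ~32 mM added Ca2+), 0.1 mM ambient Ca2+ in the
#' buffer, duplicate technical replicates and five independent experiments,
#' with Gaussian response noise of SD 4 % ionomycin.
#'
#' @return An `assay_design`.
#' @examples
#' d <- default_design()
#' length(d$modulator_concs)  # 8, including vehicle
#' @export
default_design <- function() {
  assay_design(
    agonist_concs = c(0, 10^seq(-5, -1.5, length.out = 10)),
    modulator_concs = c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30) * 1e-6,
    ambient_c = 1e-4,
    replicates_per_point = 2,
    n_experiments = 5,
    noise_sd = 4,
    experiment_scale_sd = 0,
    seed = 1
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf(
    "Interaction assay design: %d agonist x %d modulator concentrations,\n  %d experiment(s) x %d replicate(s); ambient %.3g M; noise SD %.3g%%\n",
    length(x$agonist_concs), length(x$modulator_concs), x$n_experiments,
    x$replicates_per_point, x$ambient_c, x$noise_sd))
  invisible(x)
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate an interaction dataset from the operational model
#'
#' Generates replicated responses on the design's agonist x modulator grid:
#' the operational-model mean, an optional per-experiment multiplicative scale
#' factor, additive Gaussian noise on the normalised (% ionomycin) scale, and
#' truncation at zero from below (fluorescence responses are non-negative
#' fractions of the ionomycin control). Deterministic given the seed.
#'
#' @param design an [assay_design()].
#' @param p generating [operational_params()]; its `ambient_c` is overridden
#'   by the design's.
#' @param compound_id label recorded in the `compound` column.
#' @param seed integer; defaults to `design$seed`.
#' @return An `interaction_dataset`: a data frame with columns
#'   `compound, experiment, conc_A_M, conc_B_M, replicate, response_pct` and
#'   attributes `design` and `gen_params`.
#' @examples
#' d <- default_design()
#' p <- operational_params(5.47, 1.63, 0.12)
#' nrow(simulate_dataset(d, p, "cmpd1"))  # 5*11*8*2 = 880
#' @export
simulate_dataset <- function(design, p, compound_id = "compound",
                             seed = design$seed) {
  if (!inherits(design, "assay_design")) stop("'design' must be an assay_design")
  validate_operational_params(p)
  p$ambient_c <- design$ambient_c
  grid <- expand.grid(
    replicate = seq_len(design$replicates_per_point),
    conc_A_M = design$agonist_concs,
    conc_B_M = design$modulator_concs,
    experiment = seq_len(design$n_experiments),
    KEEP.OUT.ATTRS = FALSE
  )
  mu <- operational_response(grid$conc_A_M, grid$conc_B_M, p)
  resp <- with_seed(seed, {
    scale <- if (design$experiment_scale_sd > 0)
      stats::rnorm(design$n_experiments, 1, design$experiment_scale_sd)
    else rep(1, design$n_experiments)
    pmax(0, mu * scale[grid$experiment] +
           stats::rnorm(nrow(grid), 0, design$noise_sd))
  })
  out <- data.frame(compound = compound_id,
                    experiment = grid$experiment,
                    conc_A_M = grid$conc_A_M,
                    conc_B_M = grid$conc_B_M,
                    replicate = grid$replicate,
                    response_pct = resp)
  new_interaction_dataset(out, design = design, gen_params = p)
}

new_interaction_dataset <- function(df, design = NULL, gen_params = NULL) {
  required <- c("compound", "experiment", "conc_A_M", "conc_B_M",
                "replicate", "response_pct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("interaction dataset is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(df$response_pct)))
    stop("responses must be finite")
  .check_conc(df$conc_A_M, "conc_A_M"); .check_conc(df$conc_B_M, "conc_B_M")
  structure(df, design = design, gen_params = gen_params,
            class = c("interaction_dataset", "data.frame"))
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "Interaction dataset '%s': %d records, %d experiment(s), %d agonist x %d modulator concentrations\n",
    paste(unique(x$compound), collapse = ","), nrow(x),
    length(unique(x$experiment)), length(unique(x$conc_A_M)),
    length(unique(x$conc_B_M))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Generating parameters for the synthetic reference panel. Affinity,
# cooperativity and agonism per compound follow the reported reference panel;
# ND agonism entries are encoded as log_tau_b = -5 (tauB ~ 0). Compound "8"
# is a deliberately near-neutral synthetic stand-in (cooperativity ~ 1, no
# agonism) emulating an interaction the operational model cannot pin down.
fixture_params_table <- function() {
  data.frame(
    compound = c("1", "5", "6", "7", "7b", "8", "9"),
    pkb = c(5.47, 5.30, 4.54, 3.91, 5.09, 5.00, 4.98),
    log_alpha_beta = c(1.63, 0.94, 1.45, 1.95, 2.24, 0.02, 1.59),
    log_tau_b = c(0.12, 0.53, -5, -0.29, 0.58, -5, -0.43),
    n_experiments = c(5L, 5L, 5L, 5L, 4L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Synthetic reference compound panel
#'
#' Simulates one interaction dataset per compound of the reference PAM panel
#' (compounds 1, 5, 6, 7, 7b, 8, 9), using each compound's reported affinity,
#' cooperativity and intrinsic-agonism values as generating parameters and the
#' reported number of independent experiments per compound. Compound 8 is a
#' synthetic near-neutral stand-in (alpha*beta ~ 1, tauB ~ 0) for an
#' interaction that defeats the operational model. Shared generating values:
#' Em 100, pEC50 3.3, nB 3, ambient 0.1 mM.
#'
#' @param seed integer; per-compound seeds are derived deterministically.
#' @param design base [assay_design()]; `n_experiments` is set per compound.
#' @return Named list of `interaction_dataset`s.
#' @export
fixture_panel <- function(seed = 1, design = default_design()) {
  tab <- fixture_params_table()
  out <- vector("list", nrow(tab))
  names(out) <- tab$compound
  for (i in seq_len(nrow(tab))) {
    d <- design
    d$n_experiments <- tab$n_experiments[i]
    d$seed <- as.integer(seed * 100 + i)
    p <- operational_params(tab$pkb[i], tab$log_alpha_beta[i],
                            tab$log_tau_b[i], em = 100, pec50 = 3.3,
                            nb = 3, ambient_c = d$ambient_c)
    out[[i]] <- simulate_dataset(d, p, compound_id = tab$compound[i])
  }
  out
}

#' Simulate a family of sigmoid curves sharing one Hill slope
#'
#' Generates one agonist curve per modulator concentration directly from the
#' four-parameter sigmoid with a common Hill slope, emulating the empirical
#' fallback situation: a modulator that shifts potency without a usable
#' operational-model description. Default potencies follow a saturating
#' leftward shift from pEC50 3.55 reaching ~1.8-fold at 10 uM modulator.
#'
#' @param pec50 per-curve pEC50 values, one per modulator concentration.
#' @param hill_slope shared generating Hill slope.
#' @param bottom,top per-curve floor/ceiling (recycled).
#' @param modulator_concs modulator series labelling the curves, M.
#' @param agonist_concs agonist series, M.
#' @param n_experiments,replicates replication structure.
#' @param noise_sd Gaussian noise SD (% ionomycin).
#' @param seed integer seed.
#' @return An `interaction_dataset` whose curves are indexed by `conc_B_M`.
#' @export
simulate_hill_family <- function(pec50 = 3.55 + 0.30 * .default_mods /
                                   (.default_mods + 1.5e-6),
                                 hill_slope = 3.5, bottom = 0, top = 100,
                                 modulator_concs = .default_mods,
                                 agonist_concs = c(0, 10^seq(-5, -1.5,
                                                             length.out = 10)),
                                 n_experiments = 3, replicates = 2,
                                 noise_sd = 4, seed = 1) {
  k <- length(modulator_concs)
  stopifnot(length(pec50) == k)
  bottom <- rep_len(bottom, k); top <- rep_len(top, k)
  grid <- expand.grid(replicate = seq_len(replicates),
                      conc_A_M = agonist_concs,
                      curve = seq_len(k),
                      experiment = seq_len(n_experiments),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- numeric(nrow(grid))
  for (j in seq_len(k)) {
    idx <- grid$curve == j
    mu[idx] <- hill_response(grid$conc_A_M[idx],
                             hill_params(bottom[j], top[j], pec50[j],
                                         hill_slope))
  }
  resp <- with_seed(seed, pmax(0, mu + stats::rnorm(nrow(grid), 0, noise_sd)))
  out <- data.frame(compound = "hill_family",
                    experiment = grid$experiment,
                    conc_A_M = grid$conc_A_M,
                    conc_B_M = modulator_concs[grid$curve],
                    replicate = grid$replicate,
                    response_pct = resp)
  new_interaction_dataset(out)
}

.default_mods <- c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30) * 1e-6
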