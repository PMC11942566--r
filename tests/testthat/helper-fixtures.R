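# shared fixtures: compact designs keep the nonlinear fits fast while
# preserving the structure of the full assay (vehicle column, ambient agonist,
# duplicate reads)

cmpd1_params <- function(...) {
  operational_params(pkb = 5.47, log_alpha_beta = 1.63, log_tau_b = 0.12,
                     em = 100, pec50 = 3.3, nb = 3, ambient_c = 1e-4, ...)
}

small_design <- function(n_experiments = 3, noise_sd = 4, seed = 1) {
  assay_design(
    agonist_concs = c(0, 10^seq(-4.5, -2, length.out = 6)),
    modulator_concs = c(0, 0.1, 1, 10) * 1e-6,
    ambient_c = 1e-4,
    replicates_per_point = 2,
    n_experiments = n_experiments,
    noise_sd = noise_sd,
    seed = seed
  )
}

noiseless_design <- function(n_experiments = 1) {
  d <- small_design(n_experiments = n_experiments, noise_sd = 0)
  d
}

# plain-arithmetic evaluation of the operational model, independent of the
# package's log-space implementation (nt = 1)
naive_operational <- function(A, B, em, pec50, nb, pkb, log_ab, log_tau, C) {
  kb <- 10^(-pkb); ab <- 10^log_ab; tau <- 10^log_tau; ec50 <- 10^(-pec50)
  phi <- (A + C)^nb * (kb + ab * B) + tau * B * ec50^nb
  em * phi / (ec50^nb * (kb + B) + phi)
}
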