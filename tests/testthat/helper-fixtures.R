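# Shared fixtures built in code.

# A plain-Monod strain (no substrate inhibition, inert Luong terms at the
# concentrations used) for exact-recovery checks.
toy_monod <- function(mu_m = 0.2, Ks = 2) {
  strain_kinetics("toy", "xylose", mu_m = mu_m, Ks = Ks, Pm = 1000,
                  beta = 1, m = 0.01, Yps = 0.4, Yxs = 0.4,
                  vm = 0.4, Ksp = 10, Pmp = 1000, gamma = 1)
}

# EJ2 kinetics with maintenance off and unit yield amendments, for exact
# yield-bookkeeping conservation.
ej2_no_maintenance <- function() {
  k <- ej2_kinetics()
  k$m <- 0
  coferm:::validate_strain_kinetics(k)
}

# Mirror-image co-culture: the same kinetics on both sugars with unit
# weighing factors, so everything is symmetric under strain exchange.
symmetric_coculture <- function(S0 = 40, X0 = 0.45) {
  kE <- ej2_kinetics()
  kS <- strain_kinetics("EJ2x", "xylose", mu_m = kE$mu_m, Ks = kE$Ks,
                        Ki = kE$Ki, Pm = kE$Pm, beta = kE$beta, m = kE$m,
                        Yps = kE$Yps, Yxs = kE$Yxs, b1 = kE$b1, b2 = kE$b2,
                        vm = kE$vm, Ksp = kE$Ksp, Kip = kE$Kip,
                        Pmp = kE$Pmp, gamma = kE$gamma, a_s0 = kE$a_s0)
  coculture_params(kE, kS, r1 = 1, r2 = 1, r3 = 1, r4 = 1, r5 = 1, r6 = 1,
                   S0_c = S0, S0_x = S0, X0_E = X0, X0_S = X0)
}

# Noiseless synthetic monoculture datasets over several sugar loads.
noiseless_dataset <- function(k, S0_levels, times = seq(0, 48, by = 3)) {
  lapply(S0_levels, function(S0) {
    sp <- synthetic_spec(k, times = times, replicates = 1, cv = 0,
                         floor_sd = 0, seed = 1)
    generate_trajectory(sp, S0 = S0)[[1]]
  })
}
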