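# Synthetic fermentation data with the statistical structure the
# estimation stage assumes: duplicate batch runs sampled every few hours,
# multiplicative (HPLC-like) measurement noise with a small additive
# detection floor.

#' Specification of a synthetic fermentation dataset
#'
#' Describes how to emulate the batch experimental design: the generating
#' kinetics, sampling times, replication and the measurement noise model.
#' Observations are perturbed as `y * (1 + cv * z) + floor_sd * z'` with
#' independent standard normal `z`, `z'`, truncated at zero. Relative
#' error dominates at high concentrations and the additive floor mimics
#' detection noise near zero.
#'
#' @param kinetics generating [strain_kinetics()] (monoculture designs).
#' @param times sampling times (h); every 3 h to 48 h matches the sampling
#'   density of typical batch runs.
#' @param replicates independent replicates per condition (batch
#'   fermentations are run in duplicate).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param floor_sd standard deviation (g/L) of the additive floor.
#' @param seed integer seed recorded in the output provenance.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kinetics, times = seq(0, 48, by = 3),
                           replicates = 2, cv = 0.05, floor_sd = 0.1,
                           seed = 1) {
  stopifnot(inherits(kinetics, "strain_kinetics"))
  if (cv < 0 || floor_sd < 0) stop("synthetic_spec: cv and floor_sd >= 0")
  if (replicates < 1) stop("synthetic_spec: replicates >= 1")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("synthetic_spec: times must be nonnegative and increasing")
  structure(list(kinetics = kinetics, times = times,
                 replicates = as.integer(replicates), cv = cv,
                 floor_sd = floor_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

add_noise <- function(y, cv, floor_sd) {
  n <- length(y)
  out <- y * (1 + cv * stats::rnorm(n)) + floor_sd * stats::rnorm(n)
  pmax(out, 0)
}

#' Generate noisy replicate trajectories for one batch condition
#'
#' Simulates the noiseless model trajectory, samples it at the spec's
#' times and applies the measurement noise model independently per
#' replicate and observation. The same spec and seed give bit-identical
#' output; the generating conditions and seed are recorded in each
#' trajectory's metadata.
#'
#' @param spec a [synthetic_spec()].
#' @param S0 initial sugar (g/L).
#' @param X0 initial biomass (g DCW/L).
#' @return List of [fermentation_trajectory()] objects (one per
#'   replicate), provenance `"synthetic"`.
#' @export
generate_trajectory <- function(spec, S0, X0 = 0.45) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$kinetics
  opts <- sim_options(t_end = max(spec$times),
                      dt_out = min(0.25, min(diff(spec$times))))
  sim <- simulate_monoculture(k, S0 = S0, X0 = X0, opts = opts)
  sc <- sugar_column(k$sugar)
  base <- data.frame(
    time_h = spec$times,
    biomass_gdcw_L = traj_interp(sim, "biomass_gdcw_L", spec$times),
    cellobiose_g_L = 0, xylose_g_L = 0,
    ethanol_g_L = traj_interp(sim, "ethanol_g_L", spec$times))
  base[[sc]] <- traj_interp(sim, sc, spec$times)
  set.seed(spec$seed)
  lapply(seq_len(spec$replicates), function(r) {
    df <- base
    for (cc in c("biomass_gdcw_L", sc, "ethanol_g_L"))
      df[[cc]] <- add_noise(df[[cc]], spec$cv, spec$floor_sd)
    fermentation_trajectory(df, "synthetic", replicate = r,
                            info = list(strain = k$name, sugar = k$sugar,
                                        S0 = S0, X0 = X0, P0 = 0,
                                        cv = spec$cv,
                                        floor_sd = spec$floor_sd,
                                        seed = spec$seed))
  })
}

#' Generate noisy specific-growth-rate observations
#'
#' Evaluates the growth rate law at `P = 0` on a grid of substrate levels
#' and applies multiplicative noise; feeds the Lineweaver-Burk stage.
#'
#' @param k generating [strain_kinetics()].
#' @param S_grid substrate levels (g/L), strictly positive.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return Data frame with columns `S` and `mu`.
#' @export
generate_growth_points <- function(k, S_grid, cv = 0.05, seed = 1) {
  stopifnot(inherits(k, "strain_kinetics"))
  if (length(S_grid) == 0L) stop("generate_growth_points: empty grid")
  if (any(S_grid <= 0)) stop("generate_growth_points: S_grid must be > 0")
  mu <- vapply(S_grid, function(s) growth_rate(k, s, 0), numeric(1))
  set.seed(seed)
  data.frame(S = S_grid, mu = pmax(mu * (1 + cv * stats::rnorm(length(mu))),
                                   .Machine$double.eps))
}
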