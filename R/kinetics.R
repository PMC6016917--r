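# Pointwise rate laws for batch ethanol fermentation: Monod growth with
# optional Haldane (Andrews) substrate inhibition and Luong product
# inhibition, plus the yield-based substrate balance.

#' Kinetic parameter set for one specialist strain
#'
#' Bundles all rate-law parameters describing batch fermentation of a single
#' sugar by one strain: Monod/Haldane growth kinetics, Luong ethanol
#' inhibition of growth and of ethanol production, yield coefficients with
#' optional amendment constants, and an empirical exponential dependence of
#' the specific production rate on the initial sugar load.
#'
#' @param name strain label, e.g. `"EJ2"`.
#' @param sugar which sugar the strain consumes, `"cellobiose"` or
#'   `"xylose"`.
#' @param mu_m maximum specific growth rate (/h).
#' @param Ks Monod constant for growth (g/L).
#' @param Ki substrate-inhibition constant for growth (g/L), or `NA` to omit
#'   the Haldane term entirely.
#' @param Pm ethanol concentration at which growth stops (g/L).
#' @param beta Luong exponent for growth inhibition (dimensionless).
#' @param m maintenance coefficient (/h, zero allowed): substrate consumed per unit
#'   biomass per hour independent of growth and production.
#' @param Yps ethanol yield on substrate (g/g); cannot exceed 0.538, the
#'   stoichiometric maximum per gram of sugar.
#' @param Yxs biomass yield on substrate (g/g).
#' @param b1,b2 dimensionless amendment constants on `Yps` and `Yxs` in the
#'   substrate balance (both 1 when no amendment is needed).
#' @param vm maximum specific ethanol production rate (/h).
#' @param Ksp Monod constant for ethanol production (g/L).
#' @param Kip substrate-inhibition constant for production (g/L), or `NA`.
#' @param Pmp ethanol concentration at which production stops (g/L).
#' @param gamma Luong exponent for production inhibition (dimensionless).
#' @param a_s0 coefficient (per g/L) of the empirical `exp(a_s0 * S0)`
#'   correction multiplying the specific production rate, where `S0` is the
#'   initial sugar concentration; 0 disables the correction.
#'
#' @return An object of class `strain_kinetics` (a named list).
#' @seealso [ej2_kinetics()], [sr8_kinetics()] for the fitted defaults.
#' @export
#' @examples
#' k <- strain_kinetics("toy", "xylose", mu_m = 0.2, Ks = 2, Pm = 50,
#'                      Yps = 0.45, Yxs = 0.4, vm = 0.4, Ksp = 10, Pmp = 60)
#' growth_rate(k, S = 10, P = 0)
strain_kinetics <- function(name, sugar = c("cellobiose", "xylose"),
                            mu_m, Ks, Ki = NA_real_, Pm, beta = 1, m = 0.01,
                            Yps, Yxs, b1 = 1, b2 = 1,
                            vm, Ksp, Kip = NA_real_, Pmp, gamma = 1,
                            a_s0 = 0) {
  sugar <- match.arg(sugar)
  Ki <- as.numeric(Ki); Kip <- as.numeric(Kip)
  k <- list(name = as.character(name), sugar = sugar,
            mu_m = mu_m, Ks = Ks, Ki = Ki, Pm = Pm, beta = beta, m = m,
            Yps = Yps, Yxs = Yxs, b1 = b1, b2 = b2,
            vm = vm, Ksp = Ksp, Kip = Kip, Pmp = Pmp, gamma = gamma,
            a_s0 = a_s0)
  class(k) <- "strain_kinetics"
  validate_strain_kinetics(k)
}

validate_strain_kinetics <- function(k) {
  num <- c("mu_m", "Ks", "Ki", "Pm", "beta", "m", "Yps", "Yxs",
           "b1", "b2", "vm", "Ksp", "Kip", "Pmp", "gamma", "a_s0")
  for (f in num) {
    v <- k[[f]]
    if (length(v) != 1L || !is.numeric(v))
      stop("strain_kinetics: field '", f, "' must be a single number",
           call. = FALSE)
  }
  strict_pos <- c("mu_m", "Ks", "Pm", "beta", "Yps", "Yxs",
                  "b1", "b2", "vm", "Ksp", "Pmp", "gamma")
  for (f in strict_pos)
    if (!is.finite(k[[f]]) || k[[f]] <= 0)
      stop("strain_kinetics: field '", f, "' must be strictly positive",
           call. = FALSE)
  if (!is.finite(k$m) || k$m < 0)
    stop("strain_kinetics: 'm' must be zero or positive", call. = FALSE)
  for (f in c("Ki", "Kip"))
    if (!is.na(k[[f]]) && k[[f]] <= 0)
      stop("strain_kinetics: '", f, "' must be strictly positive or NA",
           call. = FALSE)
  if (is.na(k$a_s0) || k$a_s0 < 0)
    stop("strain_kinetics: 'a_s0' must be zero or positive", call. = FALSE)
  if (k$Yps > 0.538)
    stop("strain_kinetics: 'Yps' exceeds the stoichiometric maximum ",
         "0.538 g ethanol per g sugar", call. = FALSE)
  k
}

#' @export
print.strain_kinetics <- function(x, ...) {
  cat("<strain_kinetics> ", x$name, " (", x$sugar, ")\n", sep = "")
  cat(sprintf("  growth:     mu_m=%g /h, Ks=%g g/L, Ki=%s, Pm=%g g/L, beta=%g\n",
              x$mu_m, x$Ks, ifelse(is.na(x$Ki), "none", format(x$Ki)),
              x$Pm, x$beta))
  cat(sprintf("  substrate:  Yps=%g, Yxs=%g, b1=%g, b2=%g, m=%g /h\n",
              x$Yps, x$Yxs, x$b1, x$b2, x$m))
  cat(sprintf("  production: vm=%g /h, Ksp=%g g/L, Kip=%s, Pmp=%g g/L, gamma=%g, a_s0=%g\n",
              x$vm, x$Ksp, ifelse(is.na(x$Kip), "none", format(x$Kip)),
              x$Pmp, x$gamma, x$a_s0))
  invisible(x)
}

#' Fitted kinetic parameters for the cellobiose strain EJ2
#'
#' Default parameter set for batch cellobiose fermentation by the
#' engineered cellobiose-consuming strain: Haldane substrate inhibition on
#' growth and production, Luong ethanol inhibition, and the exponential
#' initial-sugar correction on the specific production rate
#' (`a_s0 = 0.011` per g/L).
#'
#' @return A [strain_kinetics()] object.
#' @export
ej2_kinetics <- function() {
  strain_kinetics("EJ2", "cellobiose",
                  mu_m = 0.154, Ks = 0.568, Ki = 204, Pm = 69, beta = 1.1,
                  m = 0.01, Yps = 0.5, Yxs = 0.48, b1 = 1, b2 = 1,
                  vm = 0.416, Ksp = 5, Kip = 52, Pmp = 100, gamma = 1.1,
                  a_s0 = 0.011)
}

#' Fitted kinetic parameters for the xylose strain SR8
#'
#' Default parameter set for batch xylose fermentation by the engineered
#' xylose-consuming strain. Substrate inhibition terms are structurally
#' omitted (`Ki`, `Kip` absent), and the yield coefficients carry the
#' amendment constants `b1`, `b2` that absorb ethanol re-assimilation not
#' modeled explicitly.
#'
#' @return A [strain_kinetics()] object.
#' @export
sr8_kinetics <- function() {
  strain_kinetics("SR8", "xylose",
                  mu_m = 0.154, Ks = 1.31, Ki = NA, Pm = 25.33, beta = 0.742,
                  m = 0.01, Yps = 0.4, Yxs = 0.35, b1 = 1.12, b2 = 1.32,
                  vm = 0.401, Ksp = 13.32, Kip = NA, Pmp = 27, gamma = 1.04,
                  a_s0 = 0)
}

# Luong inhibition factor 1 - (P/Pc)^a, clamped at 0 for P >= Pc.  The
# clamp both prevents biologically meaningless negative rates and avoids
# non-integer powers of negative ratios.
luong_factor <- function(P, Pc, a) {
  f <- 1 - (P / Pc)^a
  if (f < 0) 0 else f
}

#' Specific growth rate
#'
#' Monod kinetics with an optional Haldane substrate-inhibition term
#' (`S^2/Ki` in the denominator, omitted when `Ki` is `NA`) and a Luong
#' ethanol-inhibition factor `1 - (P/Pm)^beta`, clamped at zero for
#' `P >= Pm`:
#' \deqn{\mu = \mu_m \frac{S}{K_s + S + S^2/K_i}
#'       \left\{1 - (P/P_m)^\beta\right\}}
#'
#' @param k a [strain_kinetics()] object.
#' @param S substrate concentration (g/L), nonnegative.
#' @param P ethanol concentration (g/L), nonnegative.
#' @return Specific growth rate (/h), in `[0, mu_m]`.
#' @export
#' @examples
#' growth_rate(ej2_kinetics(), S = 10, P = 0)   # ~0.139 /h
growth_rate <- function(k, S, P) {
  stopifnot(inherits(k, "strain_kinetics"))
  if (!is.finite(S) || S < 0) stop("growth_rate: S must be >= 0")
  if (!is.finite(P) || P < 0) stop("growth_rate: P must be >= 0")
  den <- k$Ks + S + if (is.na(k$Ki)) 0 else S^2 / k$Ki
  k$mu_m * S / den * luong_factor(P, k$Pm, k$beta)
}

#' Specific ethanol production rate
#'
#' Monod-type production kinetics with optional substrate inhibition
#' (`S^2/Kip`), a Luong factor `1 - (P/Pmp)^gamma` clamped at zero, and an
#' empirical exponential dependence on the initial sugar load:
#' \deqn{v = e^{a_{S_0} S_0}\, v_m \frac{S}{K_s' + S + S^2/K_i'}
#'       \left\{1 - (P/P_m')^\gamma\right\}}
#'
#' @inheritParams growth_rate
#' @param S0 initial concentration (g/L) of this strain's sugar in the
#'   batch; enters only through the `exp(a_s0 * S0)` correction.
#' @return Specific ethanol production rate (/h), nonnegative.
#' @export
#' @examples
#' ethanol_rate(ej2_kinetics(), S = 40, P = 0, S0 = 40)  # ~0.341 /h
ethanol_rate <- function(k, S, P, S0) {
  stopifnot(inherits(k, "strain_kinetics"))
  if (!is.finite(S) || S < 0) stop("ethanol_rate: S must be >= 0")
  if (!is.finite(P) || P < 0) stop("ethanol_rate: P must be >= 0")
  if (!is.finite(S0) || S0 < 0) stop("ethanol_rate: S0 must be >= 0")
  den <- k$Ksp + S + if (is.na(k$Kip)) 0 else S^2 / k$Kip
  exp(k$a_s0 * S0) * k$vm * S / den * luong_factor(P, k$Pmp, k$gamma)
}

#' Substrate consumption rate from the yield balance
#'
#' Sugar is consumed for ethanol production, biomass formation and cell
#' maintenance:
#' \deqn{-\frac{dS}{dt} = \frac{1}{b_1 Y_{P/S}}\frac{dP}{dt}
#'   + \frac{1}{b_2 Y_{X/S}}\frac{dX}{dt} + mX}
#' With `b1 = b2 = 1` this is the plain yield bookkeeping.
#'
#' @inheritParams growth_rate
#' @param dPdt ethanol production rate (g/L/h), nonnegative.
#' @param dXdt biomass accumulation rate (g/L/h), nonnegative.
#' @param X biomass concentration (g DCW/L), nonnegative.
#' @return Substrate consumption rate (g/L/h, nonnegative; the
#'   positive magnitude of `-dS/dt`).
#' @export
substrate_rate <- function(k, dPdt, dXdt, X) {
  stopifnot(inherits(k, "strain_kinetics"))
  if (!is.finite(X) || X < 0) stop("substrate_rate: X must be >= 0")
  if (dPdt < 0 || dXdt < 0)
    stop("substrate_rate: dPdt and dXdt must be >= 0")
  dPdt / (k$b1 * k$Yps) + dXdt / (k$b2 * k$Yxs) + k$m * X
}

# Substrate level below which a sugar counts as exhausted; all terms that
# feed on it are frozen so that maintenance cannot drive S negative.
DEPLETION_EPS <- 1e-6

#' Right-hand side of the monoculture batch model
#'
#' Assembles the three coupled balances: `dX/dt = mu * X`,
#' `dP/dt = v * X`, `dS/dt = -(dP/dt / (b1*Yps) + dX/dt / (b2*Yxs) + m*X)`.
#' Once the sugar falls below the depletion epsilon (`1e-6` g/L), or if
#' biomass is zero, all derivatives are zero.
#'
#' @inheritParams ethanol_rate
#' @param X biomass (g DCW/L).
#' @return Named numeric vector `c(dX, dS, dP)` (g/L/h).
#' @export
monoculture_rhs <- function(k, X, S, P, S0) {
  if (S < DEPLETION_EPS || X <= 0)
    return(c(dX = 0, dS = 0, dP = 0))
  dX <- growth_rate(k, S, P) * X
  dP <- ethanol_rate(k, S, P, S0) * X
  dS <- -substrate_rate(k, dP, dX, X)
  c(dX = dX, dS = dS, dP = dP)
}
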