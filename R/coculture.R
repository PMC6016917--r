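# Coupled two-strain batch model: the cellobiose strain and the xylose
# strain share only the ethanol pool; six empirical weighing factors and
# initial-condition ratio weights couple the two monoculture models.

#' Co-culture scenario parameters
#'
#' Combines the two strain parameter sets with the six dimensionless
#' weighing factors `r1`-`r6` and the scenario initial conditions. The
#' factors play distinct roles: `r1`/`r2` amend the ethanol feedback on the
#' specific production rate of each strain (effective arrest at
#' `Pmp/r1`, `Pmp/r2`), `r3`/`r4` scale biomass accumulation and `r5`/`r6`
#' scale ethanol production of the cellobiose and xylose strain
#' respectively.
#'
#' @param ej2,sr8 [strain_kinetics()] objects for the cellobiose- and
#'   xylose-consuming strain.
#' @param r1,r2,r3,r4,r5,r6 strictly positive weighing factors; the
#'   defaults are the fitted co-culture values (see
#'   [default_weighing_factors()]).
#' @param S0_c,S0_x initial cellobiose and xylose (g/L).
#' @param X0_E,X0_S initial inoculum densities (g DCW/L) of the cellobiose
#'   and xylose strain; their sum must be positive.
#' @return An object of class `coculture_params`.
#' @export
#' @examples
#' p <- coculture_params(S0_c = 40, S0_x = 40, X0_E = 0.45, X0_S = 0.45)
#' coupling_weights(p)
coculture_params <- function(ej2 = ej2_kinetics(), sr8 = sr8_kinetics(),
                             r1 = 3.75, r2 = 1.76, r3 = 1.44, r4 = 2.48,
                             r5 = 1.82, r6 = 4.29,
                             S0_c, S0_x, X0_E, X0_S) {
  stopifnot(inherits(ej2, "strain_kinetics"), inherits(sr8, "strain_kinetics"))
  r <- c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("coculture_params: weighing factors r1..r6 must be > 0")
  for (v in c(S0_c, S0_x, X0_E, X0_S))
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop("coculture_params: initial conditions must be single ",
           "nonnegative numbers")
  if (X0_E + X0_S <= 0)
    stop("coculture_params: at least one inoculum must be positive")
  p <- list(ej2 = ej2, sr8 = sr8,
            r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6,
            S0_c = S0_c, S0_x = S0_x, X0_E = X0_E, X0_S = X0_S)
  class(p) <- "coculture_params"
  p
}

#' Fitted co-culture weighing factors
#'
#' @return Named vector of the six fitted dimensionless weighing factors.
#' @export
default_weighing_factors <- function() {
  c(r1 = 3.75, r2 = 1.76, r3 = 1.44, r4 = 2.48, r5 = 1.82, r6 = 4.29)
}

#' @export
print.coculture_params <- function(x, ...) {
  cat("<coculture_params>\n")
  cat(sprintf("  strains: %s (cellobiose) + %s (xylose)\n",
              x$ej2$name, x$sr8$name))
  cat(sprintf("  weighing factors: r1=%g r2=%g r3=%g r4=%g r5=%g r6=%g\n",
              x$r1, x$r2, x$r3, x$r4, x$r5, x$r6))
  cat(sprintf("  initial: S0_c=%g, S0_x=%g g/L; X0_E=%g, X0_S=%g g DCW/L\n",
              x$S0_c, x$S0_x, x$X0_E, x$X0_S))
  invisible(x)
}

#' Initial-condition coupling weights
#'
#' Each strain's share of the co-culture ethanol production is weighted by
#' the product of its initial sugar load and its inoculum size, normalized
#' so the two weights sum to one:
#' \deqn{\rho_E = \frac{S_{0,c} X_{0,E}}{S_{0,c} X_{0,E} + S_{0,x} X_{0,S}},
#'       \quad \rho_S = 1 - \rho_E}
#'
#' @param p a [coculture_params()] object.
#' @return Named vector `c(rho_E, rho_S)` summing to 1.
#' @export
coupling_weights <- function(p) {
  stopifnot(inherits(p, "coculture_params"))
  wE <- p$S0_c * p$X0_E
  wS <- p$S0_x * p$X0_S
  if (wE + wS <= 0)
    stop("coupling_weights: both initial-condition products are zero")
  rho <- wE / (wE + wS)
  c(rho_E = rho, rho_S = 1 - rho)
}

#' Right-hand side of the co-culture batch model
#'
#' Couples the two monoculture models through the shared ethanol pool.
#' There is no competition for sugar: each strain consumes only its own
#' sugar, so the cellobiose balance is independent of the xylose side
#' except through ethanol. Per strain (shown for the cellobiose strain E;
#' the xylose strain S is symmetric with `r2`, `r4`, `r6`, `rho_S`):
#' \deqn{\mu_E = \mu(k_E; S_c, P), \qquad
#'       \nu_E = v(k_E; S_c, r_1 P, S_{0,c})}
#' \deqn{dX_E/dt = r_3\,\mu_E X_E, \qquad
#'       dP/dt = r_5 \rho_E \nu_E X_E + r_6 \rho_S \nu_S X_S}
#' \deqn{-dS_c/dt = \frac{r_5 \rho_E \nu_E X_E}{b_1 Y_{P/S}}
#'   + \frac{r_3 \mu_E X_E}{b_2 Y_{X/S}} + m X_E}
#' `r1` (resp. `r2`) amplifies the ethanol concentration felt by the
#' production machinery, so production arrest moves down to `Pmp/r1`
#' (`Pmp/r2`); growth arrest stays at the monoculture `Pm`. A depleted
#' sugar (below `1e-6` g/L) freezes all terms on its side.
#'
#' With both weighing factors and `rho` equal to one and one strain absent,
#' the system reduces exactly to the corresponding monoculture model.
#'
#' @param p a [coculture_params()] object.
#' @param X_E,X_S per-strain biomass (g DCW/L).
#' @param S_c,S_x cellobiose and xylose (g/L).
#' @param P ethanol (g/L).
#' @param rho optional fixed coupling weights `c(rho_E, rho_S)`; defaults
#'   to [coupling_weights()] of `p`.
#' @return Named vector `c(dX_E, dX_S, dS_c, dS_x, dP)` (g/L/h).
#' @export
coculture_rhs <- function(p, X_E, X_S, S_c, S_x, P, rho = coupling_weights(p)) {
  stopifnot(inherits(p, "coculture_params"))
  kE <- p$ej2; kS <- p$sr8
  S_c <- max(S_c, 0); S_x <- max(S_x, 0); P <- max(P, 0)
  act_c <- S_c >= DEPLETION_EPS && X_E > 0
  act_x <- S_x >= DEPLETION_EPS && X_S > 0

  mu_E <- if (act_c) growth_rate(kE, S_c, P) else 0
  mu_S <- if (act_x) growth_rate(kS, S_x, P) else 0
  nu_E <- if (act_c) ethanol_rate(kE, S_c, p$r1 * P, p$S0_c) else 0
  nu_S <- if (act_x) ethanol_rate(kS, S_x, p$r2 * P, p$S0_x) else 0

  dX_E <- p$r3 * mu_E * X_E
  dX_S <- p$r4 * mu_S * X_S
  dP_E <- p$r5 * rho[[1]] * nu_E * X_E
  dP_S <- p$r6 * rho[[2]] * nu_S * X_S
  dS_c <- if (act_c) -substrate_rate(kE, dP_E, dX_E, X_E) else 0
  dS_x <- if (act_x) -substrate_rate(kS, dP_S, dX_S, X_S) else 0
  c(dX_E = dX_E, dX_S = dX_S, dS_c = dS_c, dS_x = dS_x, dP = dP_E + dP_S)
}
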