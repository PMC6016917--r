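# Two-stage parameter estimation: Lineweaver-Burk initialization of the
# Monod growth constants, then least-squares refinement of the remaining
# parameters against full fermentation time courses, plus the model-variant
# comparison for the substrate-inhibition terms and two analytic helpers
# for inhibition thresholds and theoretical-yield fractions.

#' Lineweaver-Burk estimate of the Monod growth constants
#'
#' Ordinary least squares of `1/mu` on `1/S` (the double-reciprocal
#' linearization of the Monod equation): the intercept is `1/mu_m` and the
#' slope is `Ks/mu_m`. With exactly two points this is the exact two-point
#' solve.
#'
#' @param points data frame with columns `S` (initial substrate, g/L, > 0)
#'   and `mu` (observed specific growth rate, /h, > 0), at least two rows
#'   with distinct `S`.
#' @return Named vector `c(mu_m, Ks)`.
#' @export
#' @examples
#' lineweaver_burk(data.frame(S = c(10, 40), mu = c(0.136, 0.149)))
lineweaver_burk <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("S", "mu") %in% names(points)))
    stop("lineweaver_burk: need columns 'S' and 'mu'")
  if (nrow(points) < 2L)
    stop("lineweaver_burk: need at least two points")
  if (any(points$S <= 0) || any(points$mu <= 0))
    stop("lineweaver_burk: S and mu must be strictly positive")
  if (length(unique(points$S)) < 2L)
    stop("lineweaver_burk: S values are coincident")
  fit <- stats::lm(I(1 / mu) ~ I(1 / S), data = points)
  intercept <- stats::coef(fit)[[1]]
  slope <- stats::coef(fit)[[2]]
  if (intercept <= 0)
    stop("lineweaver_burk: nonpositive intercept; data inconsistent with ",
         "Monod saturation")
  c(mu_m = 1 / intercept, Ks = slope / intercept)
}

#' Pooled residuals between a model trajectory and observed data
#'
#' Model values are linearly interpolated to the observation times; the
#' residuals (model minus data) for biomass, the observed sugar(s) and
#' ethanol are stacked into one unweighted vector in g/L units.
#'
#' @param model_traj model [fermentation_trajectory()] spanning the data
#'   times.
#' @param data observed [fermentation_trajectory()].
#' @param weights named weights for the pooled variables
#'   (`X`, `S`, `P`); default all 1.
#' @return Numeric residual vector.
#' @export
trajectory_residuals <- function(model_traj, data,
                                 weights = c(X = 1, S = 1, P = 1)) {
  stopifnot(inherits(model_traj, "fermentation_trajectory"),
            inherits(data, "fermentation_trajectory"))
  if (nrow(data) == 0L) stop("trajectory_residuals: empty data")
  t <- data$time_h
  if (min(t) < min(model_traj$time_h) - 1e-9 ||
      max(t) > max(model_traj$time_h) + 1e-9)
    stop("trajectory_residuals: data times outside model trajectory span")
  res <- weights[["X"]] *
    (traj_interp(model_traj, "biomass_gdcw_L", t) - data$biomass_gdcw_L)
  for (cc in c("cellobiose_g_L", "xylose_g_L")) {
    if (any(data[[cc]] > 0))
      res <- c(res, weights[["S"]] * (traj_interp(model_traj, cc, t) -
                                      data[[cc]]))
  }
  c(res, weights[["P"]] *
      (traj_interp(model_traj, "ethanol_g_L", t) - data$ethanol_g_L))
}

rss <- function(res) sum(res^2)
rmse <- function(res) sqrt(sum(res^2) / length(res))

# Initial conditions for refitting a data trajectory: prefer the recorded
# generator metadata, fall back to the first observed row.
traj_init <- function(traj, sugar) {
  info <- attr(traj, "info")
  if (!is.null(info$S0) && !is.null(info$X0))
    return(list(S0 = info$S0, X0 = info$X0,
                P0 = if (is.null(info$P0)) 0 else info$P0))
  list(S0 = traj[[sugar_column(sugar)]][1],
       X0 = traj$biomass_gdcw_L[1], P0 = traj$ethanol_g_L[1])
}

#' Truncate a trajectory at the sugar plateau
#'
#' Cuts off observations after sugar consumption has stalled: the first
#' time the decrease over two consecutive samples is below `delta`.
#' Intended for xylose fermentations, where ethanol re-assimilation after
#' the sugar levels off is outside the model.
#'
#' @param traj a [fermentation_trajectory()].
#' @param sugar which sugar to inspect.
#' @param delta stall threshold (g/L per sampling interval).
#' @return The truncated trajectory.
#' @export
truncate_at_plateau <- function(traj, sugar = c("xylose", "cellobiose"),
                                delta = 0.1) {
  stopifnot(inherits(traj, "fermentation_trajectory"))
  sugar <- match.arg(sugar)
  s <- traj[[sugar_column(sugar)]]
  if (length(s) < 3L) return(traj)
  drop2 <- s[seq_len(length(s) - 2L)] - s[-(1:2)]
  stall <- which(drop2 < delta)
  if (length(stall) == 0L) return(traj)
  keep <- seq_len(min(stall[1] + 1L, length(s)))
  fermentation_trajectory(as.data.frame(traj)[keep, , drop = FALSE],
                          provenance = attr(traj, "provenance"),
                          replicate = attr(traj, "replicate"),
                          info = attr(traj, "info"))
}

#' Least-squares refinement of kinetic parameters
#'
#' Minimizes the pooled residual sum of squares between simulated and
#' observed trajectories over a chosen set of free parameters, starting
#' from `k0`, with a Levenberg-Marquardt trust-region scheme
#' ([minpack.lm::nls.lm()]) and numerically estimated gradients. Fixed
#' parameters keep their `k0` values. Optional multi-start perturbs the
#' starting point to guard against local minima.
#'
#' @param data a list of observed [fermentation_trajectory()] objects
#'   (e.g. replicates and/or several initial sugar loads). Each
#'   trajectory's initial conditions are taken from its recorded metadata
#'   or its first row.
#' @param k0 starting [strain_kinetics()]; also supplies the fixed values.
#' @param free character vector of parameter names to estimate.
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   default positivity bounds.
#' @param weights residual weights, see [trajectory_residuals()].
#' @param truncate_plateau truncate each data trajectory at the sugar
#'   plateau before fitting (see [truncate_at_plateau()]).
#' @param n_starts number of optimizer starts; starts beyond the first
#'   perturb the free parameters log-normally (factor up to ~1.5).
#' @param seed RNG seed for the multi-start perturbations.
#' @param opts [sim_options()] used for the model simulations.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return A `fit_result` list: `kinetics` (refined [strain_kinetics()]),
#'   `estimate`, `fixed`, `rss`, `rmse`, `rmse_by_var`, `n_obs`,
#'   `iterations`, `converged`, `bound_hit`.
#' @export
fit_parameters <- function(data, k0,
                           free = c("vm", "Ksp", "Kip", "Pmp", "gamma"),
                           bounds = list(), weights = c(X = 1, S = 1, P = 1),
                           truncate_plateau = FALSE, n_starts = 1, seed = 1,
                           opts = sim_options(),
                           control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(k0, "strain_kinetics"))
  if (inherits(data, "fermentation_trajectory")) data <- list(data)
  if (length(data) == 0L) stop("fit_parameters: empty data")
  fields <- setdiff(names(k0), c("name", "sugar"))
  if (!all(free %in% fields))
    stop("fit_parameters: unknown free parameters: ",
         paste(setdiff(free, fields), collapse = ", "))
  if (truncate_plateau)
    data <- lapply(data, truncate_at_plateau, sugar = k0$sugar)

  start <- vapply(free, function(f) {
    v <- k0[[f]]
    if (is.na(v))
      stop("fit_parameters: free parameter '", f, "' has no starting ",
           "value in k0 (set it or drop it from `free`)")
    v
  }, numeric(1))
  lower <- vapply(free, function(f)
    if (!is.null(bounds[[f]])) bounds[[f]][1] else 1e-8, numeric(1))
  upper <- vapply(free, function(f)
    if (!is.null(bounds[[f]])) bounds[[f]][2] else Inf, numeric(1))

  inits <- lapply(data, traj_init, sugar = k0$sugar)
  t_max <- max(vapply(data, function(d) max(d$time_h), numeric(1)))
  fit_opts <- opts
  fit_opts$t_end <- max(opts$t_end, t_max)

  n_res <- 3L * sum(vapply(data, nrow, integer(1)))
  resid_fun <- function(par) {
    k <- k0
    for (i in seq_along(free)) k[[free[i]]] <- par[[i]]
    k <- tryCatch(validate_strain_kinetics(k), error = function(e) NULL)
    if (is.null(k)) return(rep(1e6, n_res))
    unlist(lapply(seq_along(data), function(j) {
      m <- simulate_monoculture(k, S0 = inits[[j]]$S0, X0 = inits[[j]]$X0,
                                P0 = inits[[j]]$P0, opts = fit_opts)
      trajectory_residuals(m, data[[j]], weights)
    }), use.names = FALSE)
  }

  run_one <- function(p0) {
    fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                              fn = resid_fun, control = control)
    list(fit = fit, rss = fit$deviance)
  }
  best <- run_one(start)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); function() stats::rnorm(length(start)) })
    for (s in seq_len(n_starts - 1)) {
      p0 <- pmin(pmax(start * exp(0.4 * rng()), lower), upper)
      cand <- tryCatch(run_one(p0), error = function(e) NULL)
      if (!is.null(cand) && cand$rss < best$rss) best <- cand
    }
  }

  fit <- best$fit
  est <- stats::setNames(fit$par, free)
  k_hat <- k0
  for (f in free) k_hat[[f]] <- est[[f]]
  k_hat <- validate_strain_kinetics(k_hat)

  res <- resid_fun(fit$par)
  by_var <- fit_rmse_by_var(data, k_hat, inits, fit_opts, weights)
  structure(list(kinetics = k_hat, estimate = est,
                 fixed = stats::setNames(
                   vapply(setdiff(fields, free), function(f) k0[[f]],
                          numeric(1)), setdiff(fields, free)),
                 rss = rss(res), rmse = rmse(res), rmse_by_var = by_var,
                 n_obs = length(res), iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 bound_hit = stats::setNames(
                   est <= lower * (1 + 1e-6) | est >= upper * (1 - 1e-6),
                   free)),
            class = "fit_result")
}

fit_rmse_by_var <- function(data, k, inits, opts, weights) {
  pieces <- list(X = numeric(0), S = numeric(0), P = numeric(0))
  for (j in seq_along(data)) {
    m <- simulate_monoculture(k, S0 = inits[[j]]$S0, X0 = inits[[j]]$X0,
                              P0 = inits[[j]]$P0, opts = opts)
    t <- data[[j]]$time_h
    pieces$X <- c(pieces$X, traj_interp(m, "biomass_gdcw_L", t) -
                    data[[j]]$biomass_gdcw_L)
    sc <- sugar_column(k$sugar)
    pieces$S <- c(pieces$S, traj_interp(m, sc, t) - data[[j]][[sc]])
    pieces$P <- c(pieces$P, traj_interp(m, "ethanol_g_L", t) -
                    data[[j]]$ethanol_g_L)
  }
  vapply(pieces, rmse, numeric(1))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> RSS =", format(x$rss), " pooled RMSE =",
      format(x$rmse), "g/L\n")
  cat("  converged:", x$converged, " iterations:", x$iterations, "\n")
  cat("  estimates:\n")
  print(round(x$estimate, 5))
  invisible(x)
}

#' Compare substrate-inhibition model variants by fit quality
#'
#' Refits the data under four structural variants of the rate laws -- with
#' both Haldane terms, growth-only (`Ki`), production-only (`Kip`), and
#' with neither -- and reports the pooled RMSE of each, sorted best first.
#' Free parameters are the production-side constants plus whichever
#' inhibition constants the variant retains.
#'
#' @inheritParams fit_parameters
#' @param variants subset of `c("with_both", "without_Ki", "without_Kip",
#'   "without_both")` to evaluate.
#' @param free_base parameters refit in every variant.
#' @param Ki_start,Kip_start starting values for the inhibition constants
#'   when the variant includes them but `k0` does not.
#' @return Data frame with columns `variant` and `rmse`, sorted by `rmse`.
#' @export
compare_variants <- function(data, k0,
                             variants = c("with_both", "without_Ki",
                                          "without_Kip", "without_both"),
                             free_base = c("vm", "Ksp", "Pmp", "gamma"),
                             Ki_start = 100, Kip_start = 100, ...) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (inherits(data, "fermentation_trajectory")) data <- list(data)
  if (length(data) == 0L) stop("compare_variants: empty data")
  one <- function(variant) {
    k <- k0
    use_Ki <- variant %in% c("with_both", "without_Kip")
    use_Kip <- variant %in% c("with_both", "without_Ki")
    k$Ki <- if (use_Ki) { if (is.na(k$Ki)) Ki_start else k$Ki } else NA_real_
    k$Kip <- if (use_Kip) { if (is.na(k$Kip)) Kip_start else k$Kip
             } else NA_real_
    free <- c(free_base, if (use_Ki) "Ki", if (use_Kip) "Kip")
    fit_parameters(data, k, free = free, ...)$rmse
  }
  out <- data.frame(variant = variants,
                    rmse = vapply(variants, one, numeric(1)))
  out <- out[order(out$rmse), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Initial sugar loads at which complete conversion reaches ethanol arrest
#'
#' For a batch started at sugar load `S0` and converted at yield
#' `Yps_basis`, the broth reaches ethanol `S0 * Yps_basis`. The sugar loads
#' whose complete conversion reaches the growth-arrest and
#' production-arrest ethanol concentrations are therefore `Pm_exp /
#' Yps_basis` and `Pmp / Yps_basis`.
#'
#' @param k a [strain_kinetics()] object (supplies `Pmp`).
#' @param Pm_exp experimentally observed ethanol concentration fully
#'   arresting growth (g/L).
#' @param Yps_basis ethanol yield (g/g) used for the conversion.
#' @return Named vector `c(S_growth_stop, S_production_stop)` (g/L);
#'   the production entry is `NA` when `k$Pmp` is absent.
#' @export
#' @examples
#' inhibition_thresholds(ej2_kinetics(), Pm_exp = 69, Yps_basis = 0.5)
inhibition_thresholds <- function(k, Pm_exp, Yps_basis) {
  stopifnot(inherits(k, "strain_kinetics"))
  if (!is.finite(Pm_exp) || Pm_exp <= 0 ||
      !is.finite(Yps_basis) || Yps_basis <= 0)
    stop("inhibition_thresholds: Pm_exp and Yps_basis must be > 0")
  c(S_growth_stop = Pm_exp / Yps_basis,
    S_production_stop = if (is.na(k$Pmp)) NA_real_ else k$Pmp / Yps_basis)
}

#' Yield as a percentage of a theoretical basis
#'
#' @param Yps observed ethanol yield (g/g).
#' @param basis theoretical yield basis (g/g); 0.511 g ethanol per g
#'   glucose equivalent is the conventional stoichiometric basis.
#' @return Percentage `100 * Yps / basis`.
#' @export
theoretical_yield_fraction <- function(Yps, basis = 0.511) {
  if (!is.finite(Yps) || Yps <= 0 || !is.finite(basis) || basis <= 0)
    stop("theoretical_yield_fraction: inputs must be > 0")
  100 * Yps / basis
}
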