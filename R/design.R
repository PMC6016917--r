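# Inoculum-design workflow: scan candidate inoculum compositions of the
# co-culture and pick the one achieving simultaneous sugar depletion or
# maximal overall ethanol productivity.

#' Summarize one co-culture fermentation scenario
#'
#' Simulates the scenario and reports the depletion time of each sugar,
#' their absolute difference, the overall ethanol productivity and the
#' final ethanol titer.
#'
#' @param p a [coculture_params()] object.
#' @param opts a [sim_options()] object; the completion threshold defines
#'   "depleted".
#' @return One-row data frame: `X0_E`, `X0_S`, `ratio`, `t_deplete_c`,
#'   `t_deplete_x`, `dt_abs`, `productivity`, `final_P`. Depletion times
#'   are `NA` if the sugar is not depleted by `t_end` (then `dt_abs` is
#'   `NA` too).
#' @export
evaluate_scenario <- function(p, opts = sim_options()) {
  stopifnot(inherits(p, "coculture_params"))
  traj <- simulate_coculture(p, opts)
  th <- opts$completion_threshold
  tc <- if (p$S0_c > th) depletion_time(traj, "cellobiose", th) else 0
  tx <- if (p$S0_x > th) depletion_time(traj, "xylose", th) else 0
  data.frame(X0_E = p$X0_E, X0_S = p$X0_S,
             ratio = if (p$X0_S > 0) p$X0_E / p$X0_S else Inf,
             t_deplete_c = tc, t_deplete_x = tx,
             dt_abs = abs(tc - tx),
             productivity = ethanol_productivity(traj, th),
             final_P = traj$ethanol_g_L[nrow(traj)])
}

#' Scan candidate inoculum compositions and select the best
#'
#' Evaluates each candidate inoculum pair with [evaluate_scenario()] under
#' fixed sugar loads and selects either the most simultaneous depletion
#' (smallest `|t_deplete_c - t_deplete_x|`, ties broken by higher
#' productivity; candidates that fail to deplete both sugars rank last) or
#' the highest overall ethanol productivity.
#'
#' @param p a [coculture_params()] template; its sugar loads are kept,
#'   its inoculum densities are replaced by each candidate.
#' @param candidates data frame with columns `X0_E` and `X0_S` (g DCW/L),
#'   or a numeric vector of EJ2:SR8 ratios applied to `p$X0_S`.
#' @param selection `"simultaneity"` or `"productivity"`.
#' @param opts a [sim_options()] object.
#' @return List with `best` (selected row) and `table` (all candidates,
#'   one row each, in input order).
#' @export
#' @examples
#' \donttest{
#' p <- coculture_params(S0_c = 60, S0_x = 20, X0_E = 0.45, X0_S = 0.45)
#' find_inoculum_ratio(p, candidates = c(1, 2, 3),
#'                     selection = "productivity")
#' }
find_inoculum_ratio <- function(p, candidates,
                                selection = c("simultaneity",
                                              "productivity"),
                                opts = sim_options()) {
  stopifnot(inherits(p, "coculture_params"))
  selection <- match.arg(selection)
  if (is.numeric(candidates))
    candidates <- data.frame(X0_E = candidates * p$X0_S, X0_S = p$X0_S)
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L)
    stop("find_inoculum_ratio: empty candidate list")
  if (!all(c("X0_E", "X0_S") %in% names(candidates)))
    stop("find_inoculum_ratio: candidates need columns X0_E and X0_S")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    q <- coculture_params(p$ej2, p$sr8, p$r1, p$r2, p$r3, p$r4, p$r5, p$r6,
                          S0_c = p$S0_c, S0_x = p$S0_x,
                          X0_E = candidates$X0_E[i],
                          X0_S = candidates$X0_S[i])
    evaluate_scenario(q, opts)
  })
  tab <- do.call(rbind, rows)
  score <- switch(selection,
    simultaneity = {
      d <- tab$dt_abs
      d[is.na(d)] <- Inf
      order(d, -tab$productivity)
    },
    productivity = order(-tab$productivity))
  list(best = tab[score[1], , drop = FALSE], table = tab)
}
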