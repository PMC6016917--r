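# The trajectory container: a data frame of time-stamped concentrations
# with provenance metadata. Columns follow the package-wide CSV dialect.

TRAJ_COLS <- c("time_h", "biomass_gdcw_L", "cellobiose_g_L",
               "xylose_g_L", "ethanol_g_L")
TRAJ_COLS_CO <- c("biomass_ej2_gdcw_L", "biomass_sr8_gdcw_L")

#' Construct a fermentation trajectory
#'
#' A trajectory is a data frame of states sampled at strictly increasing
#' times, with columns `time_h`, `biomass_gdcw_L`, `cellobiose_g_L`,
#' `xylose_g_L`, `ethanol_g_L` and, for co-cultures, the per-strain biomass
#' columns `biomass_ej2_gdcw_L` and `biomass_sr8_gdcw_L` (observable
#' biomass is their sum). Provenance records how the trajectory was
#' obtained.
#'
#' @param df data frame with the columns above; a missing sugar column is
#'   filled with zeros.
#' @param provenance one of `"simulated"`, `"synthetic"`, `"fitted"`.
#' @param replicate optional replicate index (integer) for experimental
#'   designs run in duplicate.
#' @param info optional named list of free-form metadata (initial
#'   conditions, generator settings, seed) carried as an attribute.
#' @return A data frame of class `fermentation_trajectory`.
#' @export
fermentation_trajectory <- function(df,
                                    provenance = c("simulated", "synthetic",
                                                   "fitted"),
                                    replicate = NA_integer_, info = list()) {
  provenance <- match.arg(provenance)
  df <- as.data.frame(df)
  for (cc in setdiff(TRAJ_COLS, names(df))) {
    if (cc == "time_h" || cc == "biomass_gdcw_L" || cc == "ethanol_g_L")
      stop("fermentation_trajectory: missing required column '", cc, "'")
    df[[cc]] <- 0
  }
  df <- df[, c(TRAJ_COLS, intersect(TRAJ_COLS_CO, names(df))), drop = FALSE]
  if (nrow(df) == 0L) stop("fermentation_trajectory: empty trajectory")
  if (any(!is.finite(as.matrix(df))))
    stop("fermentation_trajectory: non-finite values")
  if (any(diff(df$time_h) <= 0))
    stop("fermentation_trajectory: times must be strictly increasing")
  if (any(as.matrix(df) < 0))
    stop("fermentation_trajectory: negative concentrations or times")
  structure(df,
            class = c("fermentation_trajectory", "data.frame"),
            provenance = provenance,
            replicate = replicate,
            info = info)
}

#' @export
print.fermentation_trajectory <- function(x, ...) {
  cat(sprintf("<fermentation_trajectory> %s, %d states, t = %g..%g h\n",
              attr(x, "provenance"), nrow(x), x$time_h[1],
              x$time_h[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n", sep = "")
  invisible(x)
}

# Linear interpolation of one trajectory column at arbitrary times.
traj_interp <- function(traj, column, t) {
  stats::approx(traj$time_h, traj[[column]], xout = t, rule = 2)$y
}

sugar_column <- function(sugar) {
  switch(sugar,
         cellobiose = "cellobiose_g_L",
         xylose = "xylose_g_L",
         stop("unknown sugar label '", sugar, "'"))
}
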