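# File interfaces: the trajectory CSV dialect and YAML/JSON parameter
# files. Parameter keys follow the nomenclature symbols exactly.

STRAIN_KEYS <- c("name", "sugar", "mu_m", "Ks", "Ki", "Pm", "beta", "m",
                 "Yps", "Yxs", "b1", "b2", "vm", "Ksp", "Kip", "Pmp",
                 "gamma", "a_s0")
COCULTURE_KEYS <- c("ej2", "sr8", "r1", "r2", "r3", "r4", "r5", "r6",
                    "S0_c", "S0_x", "X0_E", "X0_S")

#' Write trajectories to the package CSV dialect
#'
#' Columns: `time_h, biomass_gdcw_L, cellobiose_g_L, xylose_g_L,
#' ethanol_g_L[, biomass_ej2_gdcw_L, biomass_sr8_gdcw_L][, replicate]`.
#' Several trajectories are stacked with their replicate index.
#'
#' @param trajs a [fermentation_trajectory()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajs, path) {
  if (inherits(trajs, "fermentation_trajectory")) trajs <- list(trajs)
  pieces <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    stopifnot(inherits(tr, "fermentation_trajectory"))
    df <- as.data.frame(tr)
    rep_i <- attr(tr, "replicate")
    df$replicate <- if (is.na(rep_i)) i else rep_i
    df
  })
  cols <- Reduce(union, lapply(pieces, names))
  pieces <- lapply(pieces, function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- 0
    df[, cols, drop = FALSE]
  })
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from the package CSV dialect
#'
#' Validates the header and cell types strictly; the replicate column is
#' optional (a single trajectory is assumed when absent). Non-monotone
#' time within a replicate is a parse error naming the offending row.
#'
#' @param path CSV file path.
#' @param provenance provenance tag to attach.
#' @return List of [fermentation_trajectory()] objects, one per replicate.
#' @export
read_trajectory_csv <- function(path, provenance = "synthetic") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJ_COLS, names(df))
  if (length(missing) > 0L)
    stop("read_trajectory_csv: missing columns: ",
         paste(missing, collapse = ", "))
  known <- c(TRAJ_COLS, TRAJ_COLS_CO, "replicate")
  num_cols <- intersect(known, names(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (any(is.na(v)))
      stop("read_trajectory_csv: non-numeric cell in column '", cc,
           "', row ", c(bad, which(is.na(df[[cc]])))[1])
    df[[cc]] <- v
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1
  out <- lapply(split(df, df$replicate), function(d) {
    bad <- which(diff(d$time_h) <= 0)
    if (length(bad) > 0L)
      stop("read_trajectory_csv: non-increasing time at row ",
           rownames(d)[bad[1] + 1L], " (replicate ", d$replicate[1], ")")
    fermentation_trajectory(d[, setdiff(names(d), "replicate"),
                              drop = FALSE],
                            provenance = provenance,
                            replicate = as.integer(d$replicate[1]))
  })
  names(out) <- NULL
  out
}

coerce_num <- function(x, key) {
  if (is.null(x)) return(NA_real_)
  if (is.character(x) && toupper(x) %in% c("NA", "N.A.", "NONE"))
    return(NA_real_)
  if (!is.numeric(x) || length(x) != 1L)
    stop("load_params: key '", key, "' is not a single number")
  as.numeric(x)
}

strain_from_list <- function(cfg, origin = "config") {
  unknown <- setdiff(names(cfg), STRAIN_KEYS)
  if (length(unknown) > 0L)
    stop("load_params: unknown keys in ", origin, ": ",
         paste(unknown, collapse = ", "))
  required <- c("mu_m", "Ks", "Pm", "Yps", "Yxs", "vm", "Ksp", "Pmp")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L)
    stop("load_params: missing keys in ", origin, ": ",
         paste(missing, collapse = ", "))
  get <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) coerce_num(cfg[[key]], key) else default
  }
  strain_kinetics(
    name = if (is.null(cfg$name)) "strain" else cfg$name,
    sugar = if (is.null(cfg$sugar)) "cellobiose" else cfg$sugar,
    mu_m = get("mu_m"), Ks = get("Ks"), Ki = get("Ki", NA_real_),
    Pm = get("Pm"), beta = get("beta", 1), m = get("m", 0.01),
    Yps = get("Yps"), Yxs = get("Yxs"),
    b1 = get("b1", 1), b2 = get("b2", 1),
    vm = get("vm"), Ksp = get("Ksp"), Kip = get("Kip", NA_real_),
    Pmp = get("Pmp"), gamma = get("gamma", 1), a_s0 = get("a_s0", 0))
}

#' Load strain or co-culture parameters from YAML or JSON
#'
#' A strain file holds the flat nomenclature keys (`mu_m`, `Ks`, `Ki`,
#' `Pm`, `beta`, `m`, `Yps`, `Yxs`, `b1`, `b2`, `vm`, `Ksp`, `Kip`, `Pmp`,
#' `gamma`, `a_s0`; `Ki`/`Kip` may be absent or `NA`). A co-culture file
#' holds `ej2` and `sr8` blocks (inline or as file references relative to
#' the config), the weighing factors `r1`..`r6` and the initial conditions
#' `S0_c`, `S0_x`, `X0_E`, `X0_S`. Unknown keys are rejected.
#'
#' The packaged fixtures `ej2.yaml`, `sr8.yaml` and
#' `coculture_default.yaml` (under `system.file("extdata", package =
#' "coferm")`) hold the fitted parameter sets.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return A [strain_kinetics()] or [coculture_params()] object.
#' @export
#' @examples
#' load_params(system.file("extdata", "ej2.yaml", package = "coferm"))
load_params <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("load_params: malformed config")
  if (any(c("r1", "ej2", "sr8") %in% names(cfg))) {
    unknown <- setdiff(names(cfg), COCULTURE_KEYS)
    if (length(unknown) > 0L)
      stop("load_params: unknown keys: ", paste(unknown, collapse = ", "))
    resolve_strain <- function(entry, fallback, label) {
      if (is.null(entry)) return(fallback())
      if (is.character(entry))
        return(load_params(file.path(dirname(path), entry)))
      strain_from_list(entry, origin = label)
    }
    ej2 <- resolve_strain(cfg$ej2, ej2_kinetics, "ej2 block")
    sr8 <- resolve_strain(cfg$sr8, sr8_kinetics, "sr8 block")
    num <- function(key, default = NULL) {
      v <- cfg[[key]]
      if (is.null(v)) {
        if (is.null(default))
          stop("load_params: missing key '", key, "'")
        return(default)
      }
      coerce_num(v, key)
    }
    return(coculture_params(ej2, sr8,
                            r1 = num("r1"), r2 = num("r2"), r3 = num("r3"),
                            r4 = num("r4"), r5 = num("r5"), r6 = num("r6"),
                            S0_c = num("S0_c", 40), S0_x = num("S0_x", 40),
                            X0_E = num("X0_E", 0.45),
                            X0_S = num("X0_S", 0.45)))
  }
  strain_from_list(cfg, origin = path)
}
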