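## File I/O: CSV tables with required-column checks, flat YAML configs, and
## key-value truth sidecars. CSV dialect: comma-separated, header required,
## UTF-8, '.' decimal, times in hours.

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("file '%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) stop(sprintf("file '%s' contains no data rows", path))
  invisible(df)
}

#' Read and write trajectory / assay CSV tables
#'
#' `readTrajectoryCSV()` reads a chemostat- or community-style table (column
#' `time_hr` plus one column per state variable) into a [Trajectory-class];
#' `writeTrajectoryCSV()` is its inverse. `readTimeseriesCSV()` reads the
#' long-format signal table (series_id, time_hr, value) used by the growth
#' assay; `readStandardCurveCSV()` reads calibration points (conc_uM,
#' turbidity).
#'
#' @param path file path
#' @param class trajectory class to construct ("Trajectory",
#'   "ChemostatTrajectory", "CommunityTrajectory")
#' @return `readTrajectoryCSV()`: a [Trajectory-class];
#'   `readTimeseriesCSV()`, `readStandardCurveCSV()`: a data.frame
#' @export
readTrajectoryCSV <- function(path, class = "Trajectory") {
  df <- utils::read.csv(path, check.names = FALSE)
  .requireColumns(df, "time_hr", path)
  if (ncol(df) < 2L)
    stop(sprintf("file '%s' has no state columns besides time_hr", path))
  state <- as.matrix(df[setdiff(names(df), "time_hr")])
  Trajectory(df$time_hr, state, class)
}

#' @rdname readTrajectoryCSV
#' @param traj a [Trajectory-class]
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readTrajectoryCSV
#' @export
readTimeseriesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  .requireColumns(df, c("series_id", "time_hr", "value"), path)
  df
}

#' @rdname readTrajectoryCSV
#' @export
readStandardCurveCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  .requireColumns(df, c("conc_uM", "turbidity"), path)
  df
}

#' @rdname readTrajectoryCSV
#' @export
readCytometryCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  .requireColumns(df, c("sample_id", "fluor_events", "nonfluor_events",
                        "bead_events"), path)
  df
}

#' Read a flat key-value configuration file
#'
#' Reads a flat YAML mapping whose keys carry units in their names
#' (e.g. `release_rate_fmol_per_cell_hr`) and builds the corresponding
#' object. Recognized blocks: strain phenotypes, chemostat and community
#' configurations.
#'
#' @param path YAML file path
#' @return named list of parsed values
#' @export
readConfigFile <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop(sprintf("config '%s' must be a flat key-value mapping", path))
  cfg
}

#' @rdname readConfigFile
#' @param cfg named list from [readConfigFile()]
#' @export
phenotypeFromConfig <- function(cfg) {
  need <- c("release_rate_fmol_per_cell_hr", "consumption_fmol_per_birth",
            "b_max_per_hr", "K_uM")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop(sprintf("phenotype config is missing key(s): %s",
                 paste(missing, collapse = ", ")))
  StrainPhenotype(
    releaseRate = cfg$release_rate_fmol_per_cell_hr,
    consumptionPerBirth = cfg$consumption_fmol_per_birth,
    kinetics = MoserParams(cfg$b_max_per_hr, cfg$K_uM,
                           if (is.null(cfg$moser_n)) 1 else cfg$moser_n),
    deathRate = if (is.null(cfg$death_rate_per_hr)) 0 else
      cfg$death_rate_per_hr)
}

#' @rdname readConfigFile
#' @export
chemostatConfigFromConfig <- function(cfg) {
  ChemostatConfig(
    dilutionRate = cfg$dilution_rate_per_hr,
    doublingTime = cfg$doubling_time_hr,
    inflowConc = if (is.null(cfg$inflow_uM)) 20 else cfg$inflow_uM,
    inoculumLive = if (is.null(cfg$inoculum_live_per_ml)) 1e5 else
      cfg$inoculum_live_per_ml,
    inoculumDead = if (is.null(cfg$inoculum_dead_per_ml)) 0 else
      cfg$inoculum_dead_per_ml,
    initialNutrient = if (is.null(cfg$initial_nutrient_uM)) 0 else
      cfg$initial_nutrient_uM,
    initialProduct = if (is.null(cfg$initial_product_uM)) 0 else
      cfg$initial_product_uM)
}

#' Write / read a flat key-value truth sidecar
#'
#' Truth sidecars accompany synthetic data files so downstream tests read
#' ground truth instead of re-deriving it. Nested lists are flattened with
#' dotted keys.
#'
#' @param truth named list (numeric / character scalars, possibly nested)
#' @param path output path
#' @return `writeTruthSidecar()` the path, invisibly; `readTruthSidecar()`
#'   a named list
#' @export
writeTruthSidecar <- function(truth, path) {
  flat <- .flatten(truth)
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    sprintf("%s: %s", k, if (is.numeric(v)) format(v, digits = 15) else
      as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.flatten <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    v <- x[[k]]
    if (is.list(v)) out <- c(out, .flatten(v, key))
    else if (length(v) > 1L) {
      nm <- if (is.null(names(v))) seq_along(v) else names(v)
      for (i in seq_along(v)) out[[paste0(key, ".", nm[i])]] <- v[i]
    } else if (!is.null(v)) out[[key]] <- v
  }
  out
}

#' @rdname writeTruthSidecar
#' @export
readTruthSidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed sidecar line: '%s'", ln))
    val <- suppressWarnings(as.numeric(kv[2]))
    out[[kv[1]]] <- if (is.na(val)) kv[2] else val
  }
  out
}
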