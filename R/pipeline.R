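## Command-line style pipeline driver. `runPipeline()` takes an argument
## vector of the form c(subcommand, --flag, value, ...), dispatches to the
## package functions, prints results to stdout (or --out), logs to stderr,
## and returns an exit status. A thin Rscript wrapper lives at
## inst/scripts/crossfeed.R.

.parseArgs <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[[i + 1L]]; i <- i + 2L
      }
    } else stop(sprintf("unexpected positional argument '%s'", a))
  }
  opts
}

.num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop(sprintf("missing required option --%s", key))
    return(default)
  }
  as.numeric(opts[[key]])
}

.log <- function(...) message(sprintf(...))

.emit <- function(lines, opts) {
  if (!is.null(opts$out)) writeLines(lines, opts$out) else
    cat(lines, sep = "\n")
}

#' Run a pipeline subcommand
#'
#' Dispatches one of the pipeline subcommands over the package's functions:
#' `simulate-chemostat`, `simulate-community`, `growth-rate`, `fit-moser`,
#' `exchange-ratio`, `community-rate`, `predict`, `compare`, `synth`.
#' Results go to stdout or `--out`; a log line with the package version,
#' seed and parameters goes to stderr. Malformed inputs (missing columns,
#' empty files) produce a clear error and a nonzero status.
#'
#' @param args character vector: subcommand followed by `--key value` pairs
#' @return integer exit status, invisibly (0 on success)
#' @examples
#' runPipeline(c("predict", "--fold", "1.6"))
#' @export
runPipeline <- function(args) {
  status <- tryCatch({
    .runPipeline(args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.runPipeline <- function(args) {
  if (length(args) == 0L)
    stop("usage: <subcommand> [--options]; subcommands: simulate-chemostat, ",
         "simulate-community, growth-rate, fit-moser, exchange-ratio, ",
         "community-rate, predict, compare, synth")
  sub <- args[[1L]]
  opts <- .parseArgs(args[-1L])
  .log("crossfeed %s | subcommand=%s | %s",
       as.character(utils::packageVersion("crossfeed")), sub,
       paste(names(opts), unlist(lapply(opts, as.character)), sep = "=",
             collapse = " "))
  switch(sub,
    "predict" = .cmdPredict(opts),
    "simulate-chemostat" = .cmdSimChemostat(opts),
    "simulate-community" = .cmdSimCommunity(opts),
    "growth-rate" = .cmdGrowthRate(opts),
    "fit-moser" = .cmdFitMoser(opts),
    "exchange-ratio" = .cmdExchangeRatio(opts),
    "community-rate" = .cmdCommunityRate(opts),
    "compare" = .cmdCompare(opts),
    "synth" = .cmdSynth(opts),
    stop(sprintf("unknown subcommand '%s'", sub)))
  invisible(NULL)
}

.readGroupCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  .requireColumns(df, "value", path)
  df$value
}

.cmdPredict <- function(opts) {
  level <- .num(opts, "level", 0.95)
  if (!is.null(opts$fold)) {
    fold <- .num(opts, "fold")
    change <- predictPartnerGrowthChange(fold)
    .emit(sprintf("predicted partner growth-rate change: %+d%%",
                  round(100 * change)), opts)
  } else {
    if (is.null(opts$mutant) || is.null(opts$ancestor))
      stop("predict needs either --fold or --mutant and --ancestor CSVs")
    fc <- foldChangeCI(.readGroupCSV(opts$mutant),
                       .readGroupCSV(opts$ancestor), level = level)
    lo <- predictPartnerGrowthChange(fc@ci[1])
    hi <- predictPartnerGrowthChange(fc@ci[2])
    .emit(c(sprintf("exchange-ratio fold change: %.3f (%.0f%% CI %.3f-%.3f)",
                    fc@point, 100 * level, fc@ci[1], fc@ci[2]),
            sprintf("predicted partner growth-rate change: %+d%% (%.0f%% CI %+d%% to %+d%%)",
                    round(100 * predictPartnerGrowthChange(fc@point)),
                    100 * level, round(100 * lo), round(100 * hi))),
          opts)
  }
}

.phenFromOpts <- function(opts, prefix = "") {
  p <- function(k) paste0(prefix, k)
  StrainPhenotype(
    releaseRate = .num(opts, p("release")),
    consumptionPerBirth = .num(opts, p("consumption")),
    kinetics = MoserParams(.num(opts, p("bmax"), 0.44),
                           .num(opts, p("K"), 1),
                           .num(opts, p("n"), 2)),
    deathRate = .num(opts, p("death"), 0))
}

.cmdSimChemostat <- function(opts) {
  phen <- if (!is.null(opts$config))
    phenotypeFromConfig(readConfigFile(opts$config)) else .phenFromOpts(opts)
  cfg <- ChemostatConfig(
    dilutionRate = if (is.null(opts$dil)) NULL else .num(opts, "dil"),
    doublingTime = if (is.null(opts$doubling)) NULL else
      .num(opts, "doubling"),
    inflowConc = .num(opts, "L0", 20),
    inoculumLive = .num(opts, "inoculum", 1e5))
  tGrid <- seq(0, .num(opts, "hours", 72), by = .num(opts, "dt", 0.5))
  traj <- simulateChemostat(cfg, phen, tGrid)
  out <- if (is.null(opts$out)) stdout() else opts$out
  utils::write.csv(as.data.frame(traj), out, row.names = FALSE, quote = FALSE)
}

.cmdSimCommunity <- function(opts) {
  cfg <- CommunityConfig(
    phenotype1 = syntheticPhenotype("ancestor"),
    phenotype2 = syntheticPhenotype("partner"),
    N1 = .num(opts, "N1", 1e5), N2 = .num(opts, "N2", 1e5))
  tGrid <- seq(0, .num(opts, "hours", 72), by = .num(opts, "dt", 1))
  traj <- simulateCommunity(cfg, tGrid)
  out <- if (is.null(opts$out)) stdout() else opts$out
  utils::write.csv(as.data.frame(traj), out, row.names = FALSE, quote = FALSE)
}

.cmdGrowthRate <- function(opts) {
  if (is.null(opts$input)) stop("growth-rate needs --input CSV")
  df <- readTimeseriesCSV(opts$input)
  window <- .num(opts, "window", 3)
  lines <- unlist(lapply(split(df, df$series_id), function(s) {
    est <- growthRateFromTimeseries(s$time_hr, s$value, window = window)
    sprintf("%s: %.6g /hr%s", s$series_id[1], est@rate,
            if (est@noGrowth) " (no growth)" else "")
  }))
  .emit(lines, opts)
}

.cmdFitMoser <- function(opts) {
  if (is.null(opts$input)) stop("fit-moser needs --input CSV")
  df <- utils::read.csv(opts$input, check.names = FALSE)
  .requireColumns(df, c("conc_uM", "rate_per_hr"), opts$input)
  fit <- fitMoser(df$conc_uM, df$rate_per_hr)
  p <- fit$params
  .emit(c(sprintf("bMax: %.6g /hr (se %.3g)", p@bMax, fit$se["bMax"]),
          sprintf("KL: %.6g uM (se %.3g)", p@KL, fit$se["KL"]),
          sprintf("n: %.6g (se %.3g)", p@n, fit$se["n"]),
          sprintf("rss: %.6g", fit$rss)), opts)
}

.cmdExchangeRatio <- function(opts) {
  if (is.null(opts$input)) stop("exchange-ratio needs --input chemostat CSV")
  traj <- readTrajectoryCSV(opts$input, "ChemostatTrajectory")
  dil <- if (!is.null(opts$dil)) .num(opts, "dil") else
    dilutionFromDoubling(.num(opts, "doubling"))
  L0 <- .num(opts, "L0")
  ss <- detectSteadyState(trajTimes(traj), stateVar(traj, "product_uM"),
                          relTol = .num(opts, "reltol", 0.1))
  if (!ss$reached)
    stop("product concentration has not reached steady state")
  est <- exchangeRatio(dil, ss$mean, L0)
  .emit(c(sprintf("Hss: %.6g uM (steady from t = %.3g hr)", ss$mean,
                  ss$tOnset),
          sprintf("exchange ratio: %.6g /hr", est@value)), opts)
}

.cmdCommunityRate <- function(opts) {
  if (is.null(opts$input)) stop("community-rate needs --input CSV")
  df <- utils::read.csv(opts$input, check.names = FALSE)
  .requireColumns(df, c("time_hr", "total_per_ml"), opts$input)
  res <- communityGrowthRate(df$time_hr, df$total_per_ml)
  .emit(sprintf("community growth rate: %.6g /hr (fit over points %d-%d)",
                res$rate, res$window[1], res$window[length(res$window)]),
        opts)
}

.cmdCompare <- function(opts) {
  if (is.null(opts$x) || is.null(opts$y)) stop("compare needs --x and --y CSVs")
  res <- compareGroups(.readGroupCSV(opts$x), .readGroupCSV(opts$y),
                       alphaVar = .num(opts, "alpha-var", 0.05))
  .emit(sprintf("p = %.4g (%s t-test; variance F-test p = %.4g)", res$p,
                res$method, res$pVar), opts)
}

.cmdSynth <- function(opts) {
  scenario <- opts$scenario
  if (is.null(scenario))
    stop("synth needs --scenario (microscopy|chemostat|community|cytometry|bioassay)")
  seed <- as.integer(.num(opts, "seed", 1))
  dir <- if (is.null(opts$dir)) "." else opts$dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  noise <- NoiseSpec(multiplicativeCV = .num(opts, "cv", 0.05), seed = seed)
  pre <- file.path(dir, scenario)
  switch(scenario,
    microscopy = {
      g <- genMicroscopySeries(.num(opts, "rate", 0.2),
                               lag = .num(opts, "lag", 2), noise = noise)
      utils::write.csv(data.frame(series_id = "s1", time_hr = g$data$time_hr,
                                  value = g$data$intensity),
                       paste0(pre, ".csv"), row.names = FALSE, quote = FALSE)
      writeTruthSidecar(g$truth, paste0(pre, "_truth.txt"))
    },
    chemostat = {
      # inoculate near the expected steady state so the run settles within
      # the sampled day, as a short-term exchange-ratio experiment would
      g <- genChemostatSeries(syntheticPhenotype("ancestor"),
                              ChemostatConfig(doublingTime = 6,
                                              inflowConc = 20,
                                              inoculumLive = 5e6),
                              noise = noise)
      utils::write.csv(g$data, paste0(pre, ".csv"), row.names = FALSE,
                       quote = FALSE)
      writeTruthSidecar(g$truth, paste0(pre, "_truth.txt"))
    },
    community = {
      cfg <- CommunityConfig(syntheticPhenotype("ancestor"),
                             syntheticPhenotype("partner"))
      g <- genCommunitySeries(cfg, noise = noise)
      utils::write.csv(g$data, paste0(pre, ".csv"), row.names = FALSE,
                       quote = FALSE)
      writeTruthSidecar(g$truth, paste0(pre, "_truth.txt"))
    },
    cytometry = {
      g <- genCytometryEvents(.num(opts, "live", 5e6), .num(opts, "dead", 5e5),
                              noise = noise)
      s <- g$sample
      utils::write.csv(data.frame(sample_id = "s1",
                                  fluor_events = s@fluorEvents,
                                  nonfluor_events = s@nonfluorEvents,
                                  bead_events = s@beadEvents),
                       paste0(pre, ".csv"), row.names = FALSE, quote = FALSE)
      writeTruthSidecar(g$truth, paste0(pre, "_truth.txt"))
    },
    bioassay = {
      g <- genBioassayCurve(spiked = c(5, 15, 30), noise = noise)
      utils::write.csv(g$curveData, paste0(pre, ".csv"), row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(g$samples, paste0(pre, "_samples.csv"),
                       row.names = FALSE, quote = FALSE)
      writeTruthSidecar(g$truth, paste0(pre, "_truth.txt"))
    },
    stop(sprintf("unknown scenario '%s'", scenario)))
  .log("wrote %s files to %s (seed %d)", scenario, dir, seed)
}
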