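# Pipeline orchestration: one validated configuration drives
# ingest -> prep -> score -> annualize -> analyze, with deterministic
# outputs and a run manifest recording every option in force.

RUN_CONFIG_KEYS <- c(
  "manifest", "outDir", "language", "lexicon", "window", "mode",
  "outlierZ", "rawTokenWindows", "uniquePositions", "zBeforeFilter",
  "series", "interpolateSeries", "lagMin", "lagMax", "gridStep",
  "offsets", "maxLag", "rollingWindow", "seed", "yearRange")

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected; option values are checked before any stage
#' runs.
#'
#' @param config named list (or path to a JSON file holding one).
#' @return the validated config with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$manifest)) stop("config requires 'manifest'")
  if (is.null(config$outDir)) stop("config requires 'outDir'")
  defaults <- list(language = "english", lexicon = NULL, window = 3L,
                   mode = "all", outlierZ = 3, rawTokenWindows = FALSE,
                   uniquePositions = FALSE, zBeforeFilter = FALSE,
                   series = list(), interpolateSeries = FALSE,
                   lagMin = -20L, lagMax = 20L, gridStep = 1L,
                   offsets = 0L, maxLag = 20L, rollingWindow = 3L,
                   seed = 1L, yearRange = c(1500L, 1900L))
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (config$window < 1L) stop("config: window must be >= 1")
  if (config$outlierZ <= 0) stop("config: outlierZ must be positive")
  if (config$lagMin > config$lagMax) stop("config: lagMin > lagMax")
  if (!config$mode %in% c("all", "tender_passion"))
    stop("config: mode must be 'all' or 'tender_passion'")
  config
}

#' Run the full analysis pipeline
#'
#' Stages: read manifest and plays, preprocess, score against the
#' lexicon, write the score table, annualize, and -- for each configured
#' annual series -- compute play-level correlations, cross-correlation
#' and the lag regression. Outputs land in `config$outDir`; the returned
#' manifest records options, output file checksums and warnings, and two
#' runs on identical inputs produce identical outputs.
#'
#' @param config see [validateRunConfig()].
#' @return run manifest (list): `config`, `files` (path and md5 per
#'   artifact), `nPlays`, `warnings`, and the analysis results.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  set.seed(config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  warns <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  manifest <- readCorpusManifest(config$manifest)
  plays <- readCorpus(manifest, yearRange = config$yearRange)
  tokens <- lapply(plays, prepPlay)
  lex <- if (is.null(config$lexicon)) defaultLexicon(config$language)
         else readLexicon(config$lexicon)
  scores <- scoreCorpus(tokens, lex, manifest,
                        window = config$window, mode = config$mode,
                        outlierZ = config$outlierZ,
                        rawTokenWindows = config$rawTokenWindows,
                        uniquePositions = config$uniquePositions,
                        zBeforeFilter = config$zBeforeFilter)
  scoresPath <- file.path(config$outDir, "scores.csv")
  writeScoresTable(scoreTable(scores), scoresPath)

  love <- annualizeScores(scores)
  lovePath <- file.path(config$outDir, "annual_love.csv")
  write.csv(data.frame(year = seriesYears(love), value = seriesValues(love)),
            lovePath, row.names = FALSE)

  analyses <- list()
  for (nm in names(config$series)) {
    s <- readAnnualSeries(config$series[[nm]], name = nm)
    if (isTRUE(config$interpolateSeries)) s <- interpolateSeries(s)
    corr <- wh(corrReport(scores, setNames(list(s), nm)))
    ccfr <- wh(crossCorrelation(love, s, maxLag = config$maxLag))
    lagr <- tryCatch(
      wh(lagRegression(love, s, lagMin = config$lagMin,
                       lagMax = config$lagMax,
                       gridStep = config$gridStep,
                       offsets = config$offsets)),
      error = function(e) {
        warns <<- c(warns, paste0("lag regression for '", nm,
                                  "' failed: ", conditionMessage(e)))
        NULL
      })
    analyses[[nm]] <- list(
      correlation = corr,
      ccf = list(lags = ccfr$lags, r = ccfr$r, n = ccfr$n),
      lag = if (!is.null(lagr)) list(
        selectedLags = selectedLags(lagr),
        coefficients = lagr@selected, rho = lagr@rho,
        offset = lagr@offset, bic = lagr@bic, n = lagr@n) else NULL)
  }
  resultsPath <- file.path(config$outDir, "analysis.json")
  jsonlite::write_json(analyses, resultsPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  files <- c(scores = scoresPath, annual_love = lovePath,
             analysis = resultsPath)
  list(config = config,
       files = data.frame(name = names(files), path = unname(files),
                          md5 = unname(tools::md5sum(files))),
       nPlays = ncol(scores), nIncluded = sum(includedPlays(scores)),
       warnings = warns, analyses = analyses)
}
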