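#' Run configuration
#'
#' Collects every stage's settings under one top-level seed, which fans out
#' deterministically to per-stage, per-fold seeds.
#'
#' @param fusionMethod similarity integration method, default \code{"SNF"}
#' @param snfK,snfT SNF neighbourhood size (default: chosen per dataset as
#'   \code{min(20, entities - 1)}) and iteration count
#' @param knnK neighbours kept when sparsifying the embedding-input graph,
#'   default 5
#' @param walk a \code{\link{walkConfig}}
#' @param dropFeatures feature columns removed before classification;
#'   default the four D-T-D-T (C6) columns of both graphs
#' @param sampler a \code{\link{samplerConfig}}
#' @param classifier a \code{\link{classifierConfig}}
#' @param nFolds cross-validation folds, default 10
#' @param seed top-level integer seed
#' @param verbose emit per-fold progress messages
#' @return a \code{runConfig} list
#' @export
runConfig <- function(fusionMethod = "SNF", snfK = NULL, snfT = 20,
                      knnK = 5, walk = walkConfig(),
                      dropFeatures = c("G1_C6_Sum", "G1_C6_Max",
                                       "G2_C6_Sum", "G2_C6_Max"),
                      sampler = samplerConfig(),
                      classifier = classifierConfig(),
                      nFolds = 10, seed = 1, verbose = FALSE) {
  stopifnot(nFolds >= 2)
  structure(list(fusionMethod = fusionMethod, snfK = snfK, snfT = snfT,
                 knnK = knnK, walk = walk, dropFeatures = dropFeatures,
                 sampler = sampler, classifier = classifier,
                 nFolds = nFolds, seed = as.integer(seed),
                 verbose = verbose), class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: \code{dataset} (a bundle directory for
#' \code{\link{readDatasetBundle}}) or \code{synth} (arguments of
#' \code{\link{synthConfig}}), plus any argument of \code{\link{runConfig}};
#' \code{walk}, \code{sampler} and \code{classifier} are nested maps passed
#' to their constructors. Unknown keys are an error, reported before any
#' computation starts.
#'
#' @param path YAML file
#' @return list with elements \code{config} (a \code{\link{runConfig}}) and
#'   \code{bundle} (a \linkS4class{DatasetBundle}, when the file names a
#'   data source)
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("dataset", "orientation", "diagonal", "synth",
             names(formals(runConfig)))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  bundle <- NULL
  if (!is.null(y$dataset)) {
    bundle <- readDatasetBundle(y$dataset,
                                orientation = y$orientation %||% "drugs-as-rows",
                                diagonal = y$diagonal %||% "unit")
  } else if (!is.null(y$synth)) {
    bundle <- makeSyntheticBenchmark(do.call(synthConfig, y$synth))
  }
  args <- y[intersect(names(y), names(formals(runConfig)))]
  if (!is.null(args$walk)) args$walk <- do.call(walkConfig, args$walk)
  if (!is.null(args$sampler)) args$sampler <- do.call(samplerConfig, args$sampler)
  if (!is.null(args$classifier))
    args$classifier <- do.call(classifierConfig, args$classifier)
  list(config = do.call(runConfig, args), bundle = bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline stage end to end
#'
#' Dispatches on \code{mode}: \code{"stats"} prints and returns the dataset
#' summary; \code{"cv"} runs the cross-validated pipeline and writes the
#' metrics report as JSON plus per-fold metrics as TSV; \code{"predict"}
#' writes the ranked novel-interaction table; \code{"fss"} runs forward
#' similarity selection with the default link evaluator and writes the
#' selection as JSON. Every invocation with an output directory also writes
#' a \code{config.yaml} snapshot of the resolved configuration, so a run
#' can be reproduced from its artifacts alone.
#'
#' @param bundle a \linkS4class{DatasetBundle}
#' @param config a \code{\link{runConfig}}
#' @param mode one of \code{"cv"}, \code{"predict"}, \code{"fss"},
#'   \code{"stats"}
#' @param outDir optional artifact directory
#' @param topK for \code{mode = "predict"}, rows to report (default 10)
#' @return the mode's primary result (summary list, MetricsReport,
#'   data.frame, or SelectionResult)
#' @export
runPipeline <- function(bundle, config = runConfig(),
                        mode = c("cv", "predict", "fss", "stats"),
                        outDir = NULL, topK = 10) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    snap <- config
    snap$walk <- unclass(snap$walk)
    snap$sampler <- unclass(snap$sampler)
    snap$classifier <- unclass(snap$classifier)
    yaml::write_yaml(unclass(snap), file.path(outDir, "config.yaml"))
  }
  result <- switch(mode,
    stats = datasetStatistics(bundle),
    cv = runCrossValidation(bundle, config),
    predict = predictNovel(bundle, config, topK = topK),
    fss = forwardSimilaritySelection(
      bundle@drugSims, bundle@targetSims,
      makeLinkEvaluator(bundle, seed = .childSeed(config$seed, "evaluator"),
                        snfK = config$snfK, snfT = config$snfT)))
  if (!is.null(outDir)) {
    if (mode == "stats")
      jsonlite::write_json(result, file.path(outDir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    if (mode == "cv") {
      utils::write.table(foldMetrics(result), file.path(outDir, "folds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(metricsSummary(result),
                           file.path(outDir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (mode == "predict")
      utils::write.table(result, file.path(outDir, "novel_dtis.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (mode == "fss")
      jsonlite::write_json(
        list(selectedDrugViews = result@selectedDrugViews,
             selectedTargetViews = result@selectedTargetViews,
             rounds = lapply(result@trace, function(d)
               stats::setNames(as.list(d$score), d$candidate))),
        file.path(outDir, "selection.json"), auto_unbox = TRUE, digits = NA)
  }
  message(sprintf("mode %s finished in %.1fs (seed %d)", mode,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$seed))
  result
}
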