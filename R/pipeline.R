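## Config-driven end-to-end pipelines: quality regression and maturity
## classification, on synthetic data or user-supplied tables/spectra.

#' Default pipeline configuration
#'
#' Returns the default configuration list; `readPipelineConfig` merges
#' a YAML file over these defaults. All algorithm defaults equal the
#' study settings: CARS 50 runs / 5 folds, GA 30 / 0.5 / 0.01 / 100,
#' SPXY 3:1 for regression, stratified Kennard-Stone 2:1 for
#' classification, maturity thresholds 8.33 / 15.41 on a*.
#'
#' @param seed integer seed recorded in every output.
#' @return Named list of configuration values.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    data = list(source = "synthetic", n_samples = 200L,
                stage_proportions = c(0.27, 0.51, 0.22),
                noise_sd = 0.005),
    preprocessing = list(snv = TRUE),
    split = list(method = "SPXY", cal_fraction = 0.75),
    selection = list(method = "CARS"),
    model = list(family = "MLR"),
    target = "ssc",
    visualization = list(compression = 0.5),
    seed = as.integer(seed),
    out_dir = NULL)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [defaultPipelineConfig()]
#'   entries (nested lists merge shallowly per section).
#' @param seed seed used when the file does not set one.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path, seed = 1L) {
  cfg <- defaultPipelineConfig(seed)
  usr <- yaml::read_yaml(path)
  for (k in names(usr)) {
    if (is.list(cfg[[k]]) && is.list(usr[[k]]))
      cfg[[k]][names(usr[[k]])] <- usr[[k]]
    else cfg[[k]] <- usr[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.pipelineInputs <- function(config) {
  d <- config$data
  if (identical(d$source, "synthetic")) {
    params <- synthSpectraParams(noiseSd = d$noise_sd,
                                 stageProportions = d$stage_proportions)
    tab <- simulateQualityTable(d$n_samples, d$stage_proportions,
                                seed = config$seed)
    spec <- simulateSpectra(tab, params, seed = config$seed + 1L)
    list(table = tab, spectra = spec, params = params)
  } else if (identical(d$source, "csv")) {
    tab <- readQualityTable(d$quality_csv)
    m <- as.matrix(utils::read.csv(d$spectra_csv, row.names = 1,
                                   check.names = FALSE))
    spec <- SpectrumMatrix(m, as.numeric(colnames(m)),
                           sampleIds = rownames(m))
    list(table = tab, spectra = spec, params = NULL)
  } else stop("unknown data source: ", d$source)
}

.writeManifest <- function(config, outDir, stageLog) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(package = "loquatHSI",
                   version = as.character(utils::packageVersion("loquatHSI")),
                   seed = config$seed,
                   config = jsonlite::fromJSON(cfgJson),
                   config_md5 = unname(tools::md5sum(tmp)),
                   stages = stageLog)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the quality-regression pipeline
#'
#' Executes spectrum preparation (optional SNV), calibration/prediction
#' splitting, wavelength selection, model fitting and evaluation for
#' one quality target, writing every intermediate (quality table CSV,
#' split CSV, selection JSON, model JSON, evaluation CSV and a manifest
#' recording config, seed and package version) when `out_dir` is set.
#'
#' @param config list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @return List with `selection` ([SelectionResult-class]), `model`
#'   ([RegressionModel-class]), `report` ([EvaluationReport-class]) and
#'   `split`.
#' @export
runQualityPipeline <- function(config = defaultPipelineConfig()) {
  inp <- .pipelineInputs(config)
  target <- match.arg(config$target, c("colour_e", "firmness", "ssc"))
  y <- inp$table[[target]]
  spec <- inp$spectra
  stageLog <- list()
  if (isTRUE(config$preprocessing$snv)) spec <- snv(spec)
  stageLog$prep <- list(snv = isTRUE(config$preprocessing$snv),
                        n = nrow(spec@values), bands = ncol(spec@values))
  split <- if (identical(config$split$method, "SPXY"))
    spxySplit(spec, y, config$split$cal_fraction)
  else kennardStoneSplit(spec, config$split$cal_fraction)
  ci <- split@calIndices; pidx <- split@predIndices
  stageLog$split <- list(method = split@method, cal = length(ci),
                         pred = length(pidx))
  Xc <- spec@values[ci, , drop = FALSE]
  sel <- switch(config$selection$method,
    CARS = carsSelect(Xc, y[ci], carsConfig(seed = config$seed),
                      wavelength = spec@wavelength),
    GA = gaSelect(Xc, y[ci], gaConfig(seed = config$seed),
                  wavelength = spec@wavelength),
    SPA = spaSelect(Xc, y[ci], spaConfig(),
                    wavelength = spec@wavelength),
    none = .selectionResult("SPA", seq_along(spec@wavelength),
                            spec@wavelength, NA_real_, 1L),
    stop("unknown selection method: ", config$selection$method))
  stageLog$selection <- list(method = config$selection$method,
                             n_bands = length(sel@indices))
  model <- fitRegression(config$model$family,
                         spec@values[ci, , drop = FALSE], y[ci],
                         bands = sel@indices, seed = config$seed,
                         wavelength = spec@wavelength)
  model@preprocessing <- spec@preprocessing
  report <- evaluateRegression(y[ci], predict(model, Xc),
                               y[pidx],
                               predict(model,
                                       spec@values[pidx, , drop = FALSE]))
  stageLog$evaluate <- list(r2p = report@r2P, rmsep = report@rmsep,
                            rpd = report@rpd)
  if (!is.null(config$out_dir)) {
    outDir <- config$out_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeQualityTable(inp$table, file.path(outDir, "quality_table.csv"))
    writeSplitCSV(split, sampleIds(inp$spectra),
                  file.path(outDir, "split.csv"))
    writeSelectionJSON(sel, file.path(outDir, "selection.json"))
    writeModelJSON(model, file.path(outDir, "model.json"))
    writeEvaluationCSV(report, file.path(outDir, "evaluation.csv"),
                       label = paste(config$selection$method,
                                     config$model$family, target,
                                     sep = "-"))
    .writeManifest(config, outDir, stageLog)
  }
  list(selection = sel, model = model, report = report, split = split)
}

#' Run the maturity-classification pipeline
#'
#' Stratified Kennard-Stone 2:1 split of the (optionally SNV-treated)
#' full-spectrum data, then fits PLS-DA, SKNN and SVM, computing
#' confusion matrices and a performance table with one row per family
#' (Num / Error / Accuracy for both sets plus total accuracy).
#'
#' @param config configuration list; `data` defaults to 249 synthetic
#'   fruit with stage proportions 60/150/39.
#' @param hyper optional named list of per-family hyperparameter
#'   overrides, e.g. `list(SVM = list(costGrid = 2^(0:4)))`.
#' @return List with `models`, `confusions` (per family: cal and pred
#'   matrices), `accuracy` (data frame, one row per family) and
#'   `split`.
#' @export
runMaturityPipeline <- function(config = NULL, hyper = list()) {
  if (is.null(config)) {
    config <- defaultPipelineConfig()
    config$data$n_samples <- 249L
    config$data$stage_proportions <- c(60, 150, 39) / 249
    config$split <- list(method = "KS", cal_fraction = 2 / 3)
  }
  inp <- .pipelineInputs(config)
  labels <- inp$table$stage
  if (nlevels(droplevels(labels)) < 3L)
    stop("maturity pipeline needs all three stages present")
  spec <- inp$spectra
  if (isTRUE(config$preprocessing$snv)) spec <- snv(spec)
  split <- kennardStoneSplit(spec, config$split$cal_fraction,
                             labels = labels)
  ci <- split@calIndices; pidx <- split@predIndices
  fams <- c("PLSDA", "SKNN", "SVM")
  models <- list(); confusions <- list(); rows <- list()
  for (fam in fams) {
    m <- fitClassifier(fam, spec@values[ci, , drop = FALSE], labels[ci],
                       hyper = if (is.null(hyper[[fam]])) list()
                               else hyper[[fam]],
                       seed = config$seed)
    cmCal <- confusionCounts(labels[ci],
                             predict(m, spec@values[ci, , drop = FALSE]))
    cmPred <- confusionCounts(labels[pidx],
                              predict(m, spec@values[pidx, , drop = FALSE]))
    models[[fam]] <- m
    confusions[[fam]] <- list(cal = cmCal, pred = cmPred)
    rows[[fam]] <- cbind(model = fam, accuracyReport(cmCal, cmPred))
  }
  acc <- do.call(rbind, rows)
  rownames(acc) <- NULL
  if (!is.null(config$out_dir)) {
    outDir <- config$out_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeQualityTable(inp$table, file.path(outDir, "quality_table.csv"))
    writeSplitCSV(split, sampleIds(inp$spectra),
                  file.path(outDir, "split.csv"))
    utils::write.csv(acc, file.path(outDir, "maturity_accuracy.csv"),
                     row.names = FALSE)
    for (fam in fams) {
      utils::write.csv(confusions[[fam]]$pred,
                       file.path(outDir,
                                 paste0("confusion_pred_", fam, ".csv")))
    }
    .writeManifest(config, outDir, list(split = list(
      cal = length(ci), pred = length(pidx))))
  }
  list(models = models, confusions = confusions, accuracy = acc,
       split = split)
}
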