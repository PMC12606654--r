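# Model persistence: weights in a single versioned RDS file, the
# configuration alongside as JSON that round-trips exactly.

SERIAL_VERSION <- "resubinet-model-1"

config_to_list <- function(cfg) {
  sl <- slotNames("ModelConfig")
  stats::setNames(lapply(sl, function(s) slot(cfg, s)), sl)
}

config_from_list <- function(lst) {
  do.call(modelConfig, lst[c("L", "nHeads", "attnKeyDim",
    "transformerDenseUnits", "mkKernelSizes", "mkFiltersPerKernel",
    "convFilters", "convKernelSize", "seRatio", "poolSize",
    "headDenseUnits", "embedDenseUnits", "fusionDenseUnits",
    "dropoutRates", "embeddingDim")])
}

#' Write / read a ModelConfig as JSON
#'
#' The JSON round-trips exactly: `readModelConfig(writeModelConfig(cfg))`
#' reconstructs an identical configuration.
#'
#' @param cfg A [ModelConfig-class].
#' @param file path.
#' @export
writeModelConfig <- function(cfg, file) {
  jsonlite::write_json(config_to_list(cfg), file, digits = NA)
  invisible(file)
}

#' @rdname writeModelConfig
#' @return `readModelConfig` returns a [ModelConfig-class].
#' @export
readModelConfig <- function(file) {
  lst <- jsonlite::read_json(file, simplifyVector = TRUE)
  config_from_list(lst)
}

#' Save / load a trained fold ensemble
#'
#' One versioned file holding the configuration, fold assignments,
#' training histories and every sub-model's weights. Loading rebuilds
#' the networks and restores the weights, so predictions round-trip
#' exactly.
#'
#' @param ensemble A [FoldEnsemble-class].
#' @param file path (RDS).
#' @export
saveEnsemble <- function(ensemble, file) {
  payload <- list(
    version = SERIAL_VERSION,
    config = config_to_list(ensemble@config),
    foldAssignments = ensemble@foldAssignments,
    trainHistory = ensemble@trainHistory,
    weights = lapply(ensemble@subModels, function(m)
      snapshot_params(m@net$params)))
  saveRDS(payload, file)
  invisible(file)
}

#' @rdname saveEnsemble
#' @return `loadEnsemble` returns a [FoldEnsemble-class].
#' @export
loadEnsemble <- function(file) {
  payload <- readRDS(file)
  if (!identical(payload$version, SERIAL_VERSION))
    stop("unsupported model file version: ", payload$version)
  cfg <- config_from_list(payload$config)
  models <- lapply(payload$weights, function(w) {
    m <- buildModel(cfg)
    restore_params(m@net$params, w)
    m
  })
  new("FoldEnsemble", subModels = models,
      foldAssignments = as.integer(payload$foldAssignments),
      trainHistory = payload$trainHistory, config = cfg)
}
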