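#' @import methods
NULL

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
PAD_CHAR <- "-"

#' ProteinSet: protein sequences with annotated ubiquitination sites
#'
#' Container for a set of proteins and their experimentally annotated
#' ubiquitination positions. Sequences are stored as an
#' [Biostrings::AAStringSet]; `ubiqSites` holds, per protein, the 1-based
#' positions of lysines known to be ubiquitinated.
#'
#' @slot sequences An `AAStringSet` of uppercase amino-acid sequences.
#' @slot ubiqSites A named list of integer vectors, parallel to
#'   `sequences`; every position must index a `K` residue.
#'
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(sequences = "ANY", ubiqSites = "list"))

setValidity("ProteinSet", function(object) {
  if (!is(object@sequences, "AAStringSet"))
    return("'sequences' must be an AAStringSet")
  if (length(object@ubiqSites) != length(object@sequences))
    return("'ubiqSites' must be parallel to 'sequences'")
  seqs <- as.character(object@sequences)
  for (i in seq_along(seqs)) {
    sites <- object@ubiqSites[[i]]
    if (length(sites) == 0L) next
    if (any(sites < 1L | sites > nchar(seqs[i])))
      return(sprintf("site out of range in protein '%s'", names(seqs)[i]))
    res <- substring(seqs[i], sites, sites)
    if (any(res != "K"))
      return(sprintf("annotated site without lysine in protein '%s'",
                     names(seqs)[i]))
  }
  TRUE
})

#' SiteWindowSet: lysine-centred sequence windows with labels
#'
#' A set of fixed-length peptide windows, each centred on a candidate
#' lysine, labelled 1 (ubiquitinated) or 0 (non-ubiquitinated). Positions
#' beyond a protein terminus are padded with `-`, which all encoders map
#' to zero rows.
#'
#' @slot windows Character vector of windows, all of length `L`.
#' @slot proteinId Character vector of source protein ids.
#' @slot centerPos Integer vector of 1-based centre positions.
#' @slot label Integer vector in `{0, 1}`.
#' @slot L Odd window length.
#'
#' @exportClass SiteWindowSet
setClass("SiteWindowSet",
  representation(windows = "character", proteinId = "character",
                 centerPos = "integer", label = "integer", L = "integer"))

setValidity("SiteWindowSet", function(object) {
  n <- length(object@windows)
  if (length(object@proteinId) != n || length(object@centerPos) != n ||
      length(object@label) != n)
    return("parallel slots have unequal lengths")
  L <- object@L
  if (length(L) != 1L || L < 3L || L %% 2L == 0L)
    return("'L' must be a single odd integer >= 3")
  if (n > 0L) {
    if (any(nchar(object@windows) != L))
      return("all windows must have length L")
    ctr <- (L + 1L) %/% 2L
    if (any(substring(object@windows, ctr, ctr) != "K"))
      return("every window must have K at its centre")
    if (!all(object@label %in% c(0L, 1L)))
      return("labels must be 0 or 1")
  }
  TRUE
})

#' ModelConfig: ResUbiNet architecture hyperparameters
#'
#' Every tunable dimension of the network in one validated object; see
#' [modelConfig()] for defaults and the meaning of each field.
#'
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(L = "integer", nHeads = "integer", attnKeyDim = "integer",
    transformerDenseUnits = "integer", mkKernelSizes = "integer",
    mkFiltersPerKernel = "integer", convFilters = "integer",
    convKernelSize = "integer", seRatio = "integer", poolSize = "integer",
    headDenseUnits = "integer", embedDenseUnits = "integer",
    fusionDenseUnits = "integer", dropoutRates = "numeric",
    embeddingDim = "integer"))

setValidity("ModelConfig", function(object) {
  ints <- c(object@L, object@nHeads, object@attnKeyDim,
            object@transformerDenseUnits, object@mkKernelSizes,
            object@mkFiltersPerKernel, object@convFilters,
            object@convKernelSize, object@seRatio, object@poolSize,
            object@headDenseUnits, object@embedDenseUnits,
            object@fusionDenseUnits, object@embeddingDim)
  if (any(ints < 1L)) return("all architecture dimensions must be positive")
  if (object@L %% 2L == 0L) return("'L' must be odd")
  if (anyDuplicated(object@mkKernelSizes))
    return("multi-kernel sizes must be distinct")
  if (object@convFilters %% object@seRatio != 0L)
    return("'seRatio' must divide 'convFilters'")
  if (length(object@headDenseUnits) != 2L ||
      length(object@embedDenseUnits) != 2L ||
      length(object@fusionDenseUnits) != 2L)
    return("head/embed/fusion dense units must each have length 2")
  if (any(object@dropoutRates < 0 | object@dropoutRates >= 1))
    return("dropout rates must be in [0, 1)")
  TRUE
})

#' BuiltModel: a constructed, trainable ResUbiNet network
#'
#' Wraps the layer graph (an opaque environment with forward/backward
#' closures), its configuration and the trainable parameter count.
#' Use [paramCount()], [predictProb()] and [trainFold()] rather than
#' touching slots.
#'
#' @exportClass BuiltModel
setClass("BuiltModel",
  representation(net = "environment", config = "ModelConfig",
                 paramCount = "integer"))

#' FoldEnsemble: 5-fold cross-validation model ensemble
#'
#' The k sub-models from stratified cross-validation, the per-sample fold
#' assignment they were validated on, and per-fold training histories.
#' Ensemble prediction is the arithmetic mean of the sub-model
#' probabilities.
#'
#' @exportClass FoldEnsemble
setClass("FoldEnsemble",
  representation(subModels = "list", foldAssignments = "integer",
                 trainHistory = "list", config = "ModelConfig"))

setValidity("FoldEnsemble", function(object) {
  if (!all(vapply(object@subModels, is, TRUE, class2 = "BuiltModel")))
    return("'subModels' must all be BuiltModel objects")
  k <- length(object@subModels)
  if (k > 0L && length(object@foldAssignments) > 0L &&
      !all(object@foldAssignments %in% seq_len(k)))
    return("fold assignments must index the sub-models")
  TRUE
})

#' EvalReport: binary-classification evaluation summary
#'
#' Confusion counts at a fixed threshold plus the eight evaluation
#' statistics: accuracy, sensitivity, specificity, precision, F1,
#' Matthews correlation coefficient, ROC AUC and precision-recall AUC.
#' Metrics whose denominator is zero are reported as `NA`, never as a
#' silent zero.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(counts = "integer", metrics = "numeric",
                 threshold = "numeric"))

setMethod("show", "ProteinSet", function(object) {
  n <- length(object@sequences)
  ns <- sum(lengths(object@ubiqSites))
  cat("ProteinSet with", n, "proteins and", ns, "annotated sites\n")
})

setMethod("show", "SiteWindowSet", function(object) {
  cat(sprintf("SiteWindowSet: %d windows (L=%d), %d positive / %d negative\n",
      length(object@windows), object@L,
      sum(object@label == 1L), sum(object@label == 0L)))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: L=%d, %d heads (key dim %d), kernels {%s} x %d, %d conv filters, SE ratio %d\n",
    object@L, object@nHeads, object@attnKeyDim,
    paste(object@mkKernelSizes, collapse = ","),
    object@mkFiltersPerKernel, object@convFilters, object@seRatio))
})

setMethod("show", "BuiltModel", function(object) {
  cat(sprintf("BuiltModel (ResUbiNet): %s trainable parameters, L=%d\n",
      format(object@paramCount, big.mark = ","), object@config@L))
})

setMethod("show", "FoldEnsemble", function(object) {
  cat(sprintf("FoldEnsemble: %d sub-models, %d assigned samples\n",
      length(object@subModels), length(object@foldAssignments)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (threshold %.3g): TP=%d TN=%d FP=%d FN=%d\n",
      object@threshold, object@counts["TP"], object@counts["TN"],
      object@counts["FP"], object@counts["FN"]))
  print(round(object@metrics, 4))
})

#' @describeIn SiteWindowSet-class number of windows
#' @param x a `SiteWindowSet`
#' @export
setMethod("length", "SiteWindowSet", function(x) length(x@windows))

#' Subset a SiteWindowSet
#' @param x a `SiteWindowSet`
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "SiteWindowSet", function(x, i, j, ..., drop = FALSE) {
  new("SiteWindowSet", windows = x@windows[i], proteinId = x@proteinId[i],
      centerPos = x@centerPos[i], label = x@label[i], L = x@L)
})

#' Window labels
#' @param object a `SiteWindowSet`
#' @return integer vector of 0/1 labels
#' @export
windowLabels <- function(object) object@label

#' Window strings
#' @param object a `SiteWindowSet`
#' @return character vector of window sequences
#' @export
windowStrings <- function(object) object@windows

#' Window length L
#' @param object a `SiteWindowSet` or `ModelConfig`
#' @return the odd window length
#' @export
windowLength <- function(object) object@L
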