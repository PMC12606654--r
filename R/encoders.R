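# Three feature channels per window: L x 31 normalized AAindex properties,
# L x 20 normalized BLOSUM62 rows, and a 1024-d embedding from a pluggable
# provider. Pad and nonstandard residues encode as all-zero rows.

window_char_matrix <- function(windows) {
  do.call(rbind, strsplit(windowStrings(windows), "", fixed = TRUE))
}

encode_lookup <- function(windows, table) {
  chars <- window_char_matrix(windows)
  n <- nrow(chars); L <- ncol(chars); d <- ncol(table)
  idx <- match(chars, rownames(table))          # NA for pad / nonstandard
  flat <- table[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  flat[is.na(idx), ] <- 0
  out <- array(0, dim = c(n, L, d))
  for (j in seq_len(d)) out[, , j] <- matrix(flat[, j], nrow = n)
  dimnames(out) <- list(NULL, NULL, colnames(table))
  out
}

#' Encode windows against the amino-acid property table
#'
#' Row `i` of each window's matrix is the 31-vector of normalized
#' properties of residue `i`; pad (`-`) and nonstandard residues give
#' all-zero rows.
#'
#' @param windows A [SiteWindowSet-class].
#' @param table normalized property table, default [propertyTable()].
#' @return Numeric array `N x L x 31`.
#' @export
encodeAAIndex <- function(windows, table = propertyTable()) {
  encode_lookup(windows, table)
}

#' Encode windows against the normalized BLOSUM62 table
#'
#' Row `i` is the normalized 20-vector of substitution scores of residue
#' `i`; pad and nonstandard residues give all-zero rows.
#'
#' @param windows A [SiteWindowSet-class].
#' @param table normalized substitution table, default [blosumTable()].
#' @return Numeric array `N x L x 20`.
#' @export
encodeBlosum <- function(windows, table = blosumTable()) {
  encode_lookup(windows, table)
}

#' Embedding providers
#'
#' A provider turns a [SiteWindowSet-class] into one numeric vector per
#' window. Three providers are available:
#' \describe{
#'   \item{`table`}{looks vectors up by `protein_id:center_pos` key from a
#'     matrix or an embedding TSV written by [writeEmbeddingTable()] - the
#'     route for precomputed real protein-language-model output.}
#'   \item{`synthetic`}{generates label-correlated Gaussian vectors via
#'     [simulateEmbeddings()]; the offline stand-in used by the test
#'     fixtures.}
#'   \item{`protrans`}{adapter around a user-supplied function
#'     `residueFun(sequence)` returning a `nchar(sequence) x dim` matrix of
#'     per-residue embeddings (e.g. a ProtT5 bridge). Per-window vectors
#'     are mean-pooled over the non-pad window residues, or taken from the
#'     centre residue alone with `pooling = "center"`.}
#' }
#'
#' @param name provider name: `"table"`, `"synthetic"` or `"protrans"`.
#' @param embeddings matrix with key rownames, or path to an embedding TSV
#'   (`table` provider).
#' @param dim,signal,seed,directionSeed synthetic-provider parameters, see
#'   [simulateEmbeddings()].
#' @param residueFun per-residue embedding function (`protrans` provider).
#' @param pooling `"mean"` (default) or `"center"` (`protrans` provider).
#' @return A provider object with a `$get(windows)` method.
#' @export
embeddingProvider <- function(name = c("table", "synthetic", "protrans"),
                              embeddings = NULL, dim = 1024L, signal = 3,
                              seed = 1L, directionSeed = 1000L,
                              residueFun = NULL,
                              pooling = c("mean", "center")) {
  name <- match.arg(name)
  pooling <- match.arg(pooling)
  self <- list(name = name)
  if (name == "table") {
    if (is.character(embeddings)) {
      df <- utils::read.delim(embeddings, colClasses = c(key = "character"))
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$key
      embeddings <- m
    }
    if (!is.matrix(embeddings) || is.null(rownames(embeddings)))
      stop("'table' provider needs a key-rowed matrix or an embedding TSV")
    self$get <- function(windows) {
      keys <- windowKeys(windows)
      miss <- setdiff(keys, rownames(embeddings))
      if (length(miss))
        stop("no embedding for ", length(miss), " window(s), e.g. ", miss[1])
      embeddings[keys, , drop = FALSE]
    }
  } else if (name == "synthetic") {
    self$get <- function(windows)
      simulateEmbeddings(windows, dim = dim, signal = signal, seed = seed,
                         directionSeed = directionSeed)
  } else {
    if (!is.function(residueFun))
      stop("'protrans' provider needs a residueFun(sequence) function")
    self$get <- function(windows) {
      chars <- window_char_matrix(windows)
      out <- NULL
      for (i in seq_len(length(windows))) {
        w <- gsub(PAD_CHAR, "", windowStrings(windows)[i], fixed = TRUE)
        per_res <- residueFun(w)
        v <- if (pooling == "mean") colMeans(per_res)
             else per_res[match("K", strsplit(w, "")[[1]]), ]
        if (is.null(out)) out <- matrix(0, length(windows), length(v))
        out[i, ] <- v
      }
      rownames(out) <- windowKeys(windows)
      out
    }
  }
  class(self) <- "embeddingProvider"
  self
}

#' Encode a window set into the three network input channels
#'
#' @param windows A [SiteWindowSet-class].
#' @param provider an [embeddingProvider()], or a precomputed embedding
#'   matrix with `protein_id:center_pos` rownames (shorthand for the
#'   `table` provider).
#' @param aaTable,blosum lookup tables, normally the packaged defaults.
#' @return List with `aaindex` (`N x L x 31`), `blosum` (`N x L x 20`),
#'   `embedding` (`N x dim`) and `label`.
#' @export
encodeWindows <- function(windows, provider, aaTable = propertyTable(),
                          blosum = blosumTable()) {
  if (is.matrix(provider))
    provider <- embeddingProvider("table", embeddings = provider)
  if (!inherits(provider, "embeddingProvider"))
    stop("'provider' must be an embeddingProvider or an embedding matrix")
  list(aaindex = encodeAAIndex(windows, aaTable),
       blosum = encodeBlosum(windows, blosum),
       embedding = unname(provider$get(windows)),
       label = windowLabels(windows))
}

subset_features <- function(features, idx) {
  list(aaindex = features$aaindex[idx, , , drop = FALSE],
       blosum = features$blosum[idx, , , drop = FALSE],
       embedding = features$embedding[idx, , drop = FALSE],
       label = features$label[idx])
}
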