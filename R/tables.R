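#' Min-max normalization
#'
#' `(x - min) / (max - min)` applied either per column (the convention for
#' the amino-acid property table, so each property spans exactly `[0, 1]`
#' over the 20 standard residues) or over the whole matrix (the convention
#' for the substitution matrix, preserving the relative ordering of all
#' scores).
#'
#' @param x numeric matrix.
#' @param scope `"column"` or `"matrix"`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @examples
#' normalizeMinMax(cbind(p = c(1, 3, 5)))
#' @export
normalizeMinMax <- function(x, scope = c("column", "matrix")) {
  scope <- match.arg(scope)
  x <- as.matrix(x)
  if (scope == "matrix") {
    rng <- range(x)
    if (rng[1] == rng[2]) stop("cannot min-max normalize a constant matrix")
    return((x - rng[1]) / (rng[2] - rng[1]))
  }
  const <- apply(x, 2, function(col) max(col) == min(col))
  if (any(const))
    stop("constant column(s), min-max normalization undefined: ",
         paste(colnames(x)[const] %||% which(const), collapse = ", "))
  apply(x, 2, function(col) (col - min(col)) / (max(col) - min(col)))
}

read_packaged_table <- function(fname) {
  path <- system.file("extdata", fname, package = "resubinet", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[AA_STANDARD, , drop = FALSE]
}

#' The 31-property amino-acid table
#'
#' A `20 x 31` matrix of physicochemical and biological amino-acid
#' properties drawn from the AAindex database (columns named by AAindex
#' accession), min-max normalized per property over the 20 standard
#' residues. The selection spans hydrophobicity, charge/electronic,
#' steric and secondary-structure-propensity classes; accession-level
#' descriptions ship in `extdata/aaindex31_descriptions.tsv`.
#'
#' @param normalized return the normalized (default) or raw table.
#' @return Numeric matrix, rows the 20 amino acids, 31 property columns.
#' @examples
#' pt <- propertyTable()
#' range(pt)
#' @export
propertyTable <- function(normalized = TRUE) {
  raw <- read_packaged_table("aaindex31.tsv")
  if (normalized) normalizeMinMax(raw, "column") else raw
}

#' The normalized BLOSUM62 substitution table
#'
#' The standard `20 x 20` BLOSUM62 matrix (from \pkg{Biostrings}),
#' min-max normalized over the whole matrix: the minimum score (-4) maps
#' to 0 and the maximum (11) to 1.
#'
#' @param normalized return the normalized (default) or raw table.
#' @return Numeric `20 x 20` matrix over the standard amino acids.
#' @examples
#' blosumTable(normalized = FALSE)["K", "K"]
#' @export
blosumTable <- function(normalized = TRUE) {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment())[1], envir = environment())
  raw <- b62[AA_STANDARD, AA_STANDARD]
  if (normalized) normalizeMinMax(raw, "matrix") else raw
}

#' The VHSE amino-acid descriptor table
#'
#' The eight VHSE principal-component descriptor scales (Mei et al. 2005)
#' for the 20 standard amino acids: VHSE1-2 summarize hydrophobic
#' properties, VHSE3-4 steric properties and VHSE5-8 electronic
#' properties.
#'
#' @return Numeric `20 x 8` matrix, columns `VHSE1`..`VHSE8`.
#' @examples
#' vhseTable()["L", "VHSE1"]
#' @export
vhseTable <- function() read_packaged_table("vhse.tsv")
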