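#' Construct a ProteinSet
#'
#' @param sequences named character vector or `AAStringSet` of protein
#'   sequences (uppercase amino acids).
#' @param ubiqSites named list of 1-based annotated ubiquitination
#'   positions; names must match sequence names. Every annotated position
#'   must carry a lysine, otherwise construction fails (bad annotations
#'   are rejected at load time, not silently skipped).
#' @return A [ProteinSet-class].
#' @examples
#' ps <- ProteinSet(c(p1 = "AAAKAAAKCC"), list(p1 = 4L))
#' ps
#' @export
ProteinSet <- function(sequences, ubiqSites = NULL) {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  if (is.null(ubiqSites)) {
    ubiqSites <- rep(list(integer(0)), length(sequences))
    names(ubiqSites) <- names(sequences)
  }
  missing <- setdiff(names(ubiqSites), names(sequences))
  if (length(missing))
    stop("annotations reference unknown proteins: ",
         paste(missing, collapse = ", "))
  sites <- rep(list(integer(0)), length(sequences))
  names(sites) <- names(sequences)
  sites[names(ubiqSites)] <- lapply(ubiqSites, function(p) sort(as.integer(p)))
  new("ProteinSet", sequences = sequences, ubiqSites = sites)
}

#' Read proteins from FASTA and an annotation table
#'
#' The FASTA id is the first whitespace-delimited token of each header.
#' The annotation TSV needs a header row with columns `protein_id`,
#' `position` (1-based) and `label`; rows with `label == 1` become
#' annotated ubiquitination sites. An annotation at a non-lysine residue
#' is an error.
#'
#' @param fastaFile path to a protein FASTA file.
#' @param annotationFile optional path to the annotation TSV.
#' @return A [ProteinSet-class].
#' @export
readProteins <- function(fastaFile, annotationFile = NULL) {
  seqs <- Biostrings::readAAStringSet(fastaFile)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sites <- NULL
  if (!is.null(annotationFile)) {
    ann <- readAnnotations(annotationFile)
    ann <- ann[ann$label == 1L, , drop = FALSE]
    bad <- setdiff(unique(ann$protein_id), names(seqs))
    if (length(bad))
      stop("annotation references proteins absent from FASTA: ",
           paste(bad, collapse = ", "))
    sites <- split(ann$position, ann$protein_id)
  }
  ProteinSet(seqs, sites)
}

#' Read a site annotation table
#'
#' @param file TSV with header columns `protein_id`, `position`, `label`.
#' @return data.frame with typed columns.
#' @export
readAnnotations <- function(file) {
  ann <- utils::read.delim(file, colClasses = c(protein_id = "character"))
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  ann$position <- as.integer(ann$position)
  ann$label <- as.integer(ann$label)
  if (!all(ann$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  ann
}

#' Extract a lysine-centred window
#'
#' Returns the `(L-1)/2` residues upstream of `pos`, the centre lysine,
#' and `(L-1)/2` residues downstream. Positions beyond either terminus
#' are filled with the pad character `-`, which encoders map to all-zero
#' feature rows.
#'
#' @param sequence a protein sequence string.
#' @param pos 1-based position of the centre residue; must be a lysine.
#' @param L odd window length, at least 3.
#' @return Character window of length `L`.
#' @examples
#' extractWindow("MKRKLFY", 4, 3)   # "RKL"
#' extractWindow("KAA", 1, 5)       # "--KAA"
#' @export
extractWindow <- function(sequence, pos, L) {
  L <- as.integer(L)
  if (L < 3L || L %% 2L == 0L) stop("'L' must be an odd integer >= 3")
  n <- nchar(sequence)
  if (pos < 1L || pos > n) stop("position ", pos, " out of range [1, ", n, "]")
  if (substring(sequence, pos, pos) != "K")
    stop("residue at position ", pos, " is '",
         substring(sequence, pos, pos), "', expected 'K'")
  half <- (L - 1L) %/% 2L
  lo <- pos - half; hi <- pos + half
  core <- substring(sequence, max(lo, 1L), min(hi, n))
  paste0(strrep(PAD_CHAR, max(0L, 1L - lo)), core,
         strrep(PAD_CHAR, max(0L, hi - n)))
}

all_k_positions <- function(sequence) {
  which(strsplit(sequence, "", fixed = TRUE)[[1]] == "K")
}

#' Build a balanced window dataset from annotated proteins
#'
#' One positive window per annotated site; for each positive, one negative
#' window centred on a non-annotated lysine sampled (without replacement,
#' seeded) from the same protein. Proteins whose eligible negative lysines
#' are outnumbered by their positives contribute as many negatives as they
#' have, and the imbalance is reported with a warning naming the protein.
#'
#' @param proteins A [ProteinSet-class].
#' @param L odd window length.
#' @param seed integer seed controlling negative sampling.
#' @return A [SiteWindowSet-class] with positives first, then negatives.
#' @examples
#' ps <- ProteinSet(c(p1 = "KAAKAAKAAKAA"), list(p1 = c(4L, 7L)))
#' buildDataset(ps, L = 5, seed = 1)
#' @export
buildDataset <- function(proteins, L = 25L, seed = 1L) {
  stopifnot(is(proteins, "ProteinSet"))
  if (length(proteins@sequences) == 0L) stop("'proteins' is empty")
  seqs <- as.character(proteins@sequences)
  rng <- local_rng(seed)
  win <- chr <- character(0); pos <- integer(0); lab <- integer(0)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    psites <- proteins@ubiqSites[[id]]
    if (length(psites) == 0L) next
    for (p in psites) {
      win <- c(win, extractWindow(s, p, L)); chr <- c(chr, id)
      pos <- c(pos, p); lab <- c(lab, 1L)
    }
    neg_pool <- setdiff(all_k_positions(s), psites)
    if (length(neg_pool) == 0L) {
      warning("protein '", id, "' has no non-annotated lysine; ",
              length(psites), " positive(s) without matched negatives",
              call. = FALSE)
      next
    }
    n_take <- min(length(psites), length(neg_pool))
    if (n_take < length(psites))
      warning("protein '", id, "': only ", n_take, " eligible negative(s) for ",
              length(psites), " positive(s)", call. = FALSE)
    picked <- rng$sample(neg_pool, n_take)
    for (p in picked) {
      win <- c(win, extractWindow(s, p, L)); chr <- c(chr, id)
      pos <- c(pos, p); lab <- c(lab, 0L)
    }
  }
  ord <- order(-lab)
  new("SiteWindowSet", windows = win[ord], proteinId = chr[ord],
      centerPos = pos[ord], label = lab[ord], L = as.integer(L))
}

#' Build windows for every lysine of a protein set
#'
#' Candidate-site enumeration for prediction: one unlabelled window per
#' lysine (label set to 0 as a placeholder).
#'
#' @param proteins A [ProteinSet-class].
#' @param L odd window length.
#' @return A [SiteWindowSet-class].
#' @export
allLysineWindows <- function(proteins, L = 25L) {
  seqs <- as.character(proteins@sequences)
  win <- chr <- character(0); pos <- integer(0)
  for (id in names(seqs)) {
    for (p in all_k_positions(seqs[[id]])) {
      win <- c(win, extractWindow(seqs[[id]], p, L))
      chr <- c(chr, id); pos <- c(pos, p)
    }
  }
  new("SiteWindowSet", windows = win, proteinId = chr, centerPos = pos,
      label = rep(0L, length(win)), L = as.integer(L))
}

#' Write / read a window table
#'
#' Plain TSV with columns `protein_id`, `center_pos`, `label`, `window`.
#'
#' @param windows A [SiteWindowSet-class].
#' @param file output path.
#' @export
writeWindowTable <- function(windows, file) {
  df <- data.frame(protein_id = windows@proteinId,
                   center_pos = windows@centerPos,
                   label = windows@label, window = windows@windows)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeWindowTable
#' @return `readWindowTable` returns a [SiteWindowSet-class].
#' @export
readWindowTable <- function(file) {
  df <- utils::read.delim(file, colClasses = c(protein_id = "character",
                                               window = "character"))
  L <- unique(nchar(df$window))
  if (length(L) != 1L) stop("windows in ", file, " have mixed lengths")
  new("SiteWindowSet", windows = df$window, proteinId = df$protein_id,
      centerPos = as.integer(df$center_pos), label = as.integer(df$label),
      L = as.integer(L))
}

# Seeded RNG scoped to a closure so library calls never disturb the
# caller's random stream.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  env$sample <- function(x, size) with_state(function()
    x[sample.int(length(x), size)])
  env$runif <- function(n, ...) with_state(function() stats::runif(n, ...))
  env$rnorm <- function(n, ...) with_state(function() stats::rnorm(n, ...))
  env$sample_int <- function(n, size, replace = FALSE, prob = NULL)
    with_state(function() sample.int(n, size, replace = replace, prob = prob))
  env
}
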