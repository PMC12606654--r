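# Synthetic-data generators. They emulate the sequence structure reported
# for real ubiquitination data: hydrophobic L/F/Y enrichment in the close
# flanks (positions -4..+4) of ubiquitinated lysines, K/R/C/E enrichment
# in the wider flanks (-7..+7) of non-ubiquitinated lysines, and
# label-correlated protein-language-model embeddings.

MOTIF_POS <- c("L", "F", "Y")
MOTIF_NEG <- c("K", "R", "C", "E")
BG_ALPHABET <- setdiff(AA_STANDARD, "K")  # background lysines would blur the
                                          # positive/negative centre contrast

#' Simulate proteins with planted ubiquitination motifs
#'
#' Each protein carries `sitesPerProtein` annotated (positive) lysines
#' whose flanking positions within -4..+4 are enriched for the
#' hydrophobic residues L/F/Y, and the same number of non-annotated
#' (negative) lysines whose flanks within -7..+7 are enriched for
#' K/R/C/E. The enrichment probability is `0.7 * motifStrength` per
#' position for positives and `0.6 * motifStrength` for negatives; at
#' `motifStrength = 0` both flank classes are drawn from the same uniform
#' background and are statistically indistinguishable. Background
#' positions never use lysine, so every K in a simulated protein is a
#' deliberate candidate site.
#'
#' @param nProteins number of proteins to simulate.
#' @param motifStrength motif intensity in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the identical
#'   protein set.
#' @param sitesPerProtein planted positive sites (and planted negative
#'   lysines) per protein.
#' @return A [ProteinSet-class] with annotated positive sites.
#' @examples
#' ps <- simulateProteins(5, motifStrength = 1, seed = 1)
#' ps
#' @export
simulateProteins <- function(nProteins, motifStrength = 1, seed = 1L,
                             sitesPerProtein = 2L) {
  stopifnot(nProteins >= 1, motifStrength >= 0, motifStrength <= 1)
  rng <- local_rng(seed)
  flank <- 7L
  block <- 2L * flank + 1L
  spacer <- 6L
  p_pos <- 0.7 * motifStrength
  p_neg <- 0.6 * motifStrength

  draw_bg <- function(n) BG_ALPHABET[rng$sample_int(length(BG_ALPHABET), n,
                                                    replace = TRUE)]
  make_block <- function(kind) {
    res <- draw_bg(block)
    res[flank + 1L] <- "K"
    offs <- setdiff(seq_len(block) - flank - 1L, 0L)
    if (kind == "pos") {
      hot <- which(abs(offs) <= 4L)
      enr <- MOTIF_POS; p <- p_pos
    } else {
      hot <- which(abs(offs) <= 7L)
      enr <- MOTIF_NEG; p <- p_neg
    }
    hit <- rng$runif(length(hot)) < p
    if (any(hit))
      res[ifelse(hot >= flank + 1L, hot + 1L, hot)[hit]] <-
        enr[rng$sample_int(length(enr), sum(hit), replace = TRUE)]
    res
  }

  seqs <- character(nProteins)
  sites <- vector("list", nProteins)
  for (i in seq_len(nProteins)) {
    kinds <- rng$sample(rep(c("pos", "neg"), sitesPerProtein),
                        2L * sitesPerProtein)
    parts <- character(0)
    centres <- integer(0)
    cursor <- 0L
    for (kind in kinds) {
      sp <- draw_bg(spacer)
      bl <- make_block(kind)
      parts <- c(parts, sp, bl)
      centre <- cursor + spacer + flank + 1L
      cursor <- cursor + spacer + block
      if (kind == "pos") centres <- c(centres, centre)
    }
    parts <- c(parts, draw_bg(spacer))
    seqs[i] <- paste(parts, collapse = "")
    sites[[i]] <- centres
  }
  names(seqs) <- sprintf("SYN%04d", seq_len(nProteins))
  names(sites) <- names(seqs)
  ProteinSet(seqs, sites)
}

#' Simulate label-correlated embedding vectors
#'
#' Stands in for protein-language-model output during offline testing.
#' Each window receives `class mean + standard Gaussian noise`, where the
#' two class means sit `signal` apart along a random unit direction of the
#' embedding space. The direction is controlled by `directionSeed` and
#' deliberately decoupled from the noise seed: it plays the role of the
#' fixed embedding model, so independently simulated training and test
#' sets share the same class geometry. `signal = 0` yields label-free
#' vectors; `signal = 3` makes the classes linearly separable with AUC
#' above 0.95.
#'
#' @param windows A [SiteWindowSet-class].
#' @param dim embedding dimension (1024 matches the ProtT5 convention).
#' @param signal class-mean separation in noise standard deviations.
#' @param seed integer seed for the per-window noise.
#' @param directionSeed integer seed fixing the class-separation
#'   direction; keep it identical across related datasets.
#' @return Numeric `N x dim` matrix with rownames `protein_id:center_pos`.
#' @export
simulateEmbeddings <- function(windows, dim = 1024L, signal = 3, seed = 1L,
                               directionSeed = 1000L) {
  stopifnot(is(windows, "SiteWindowSet"), dim >= 1L, signal >= 0)
  n <- length(windows)
  u <- local_rng(directionSeed)$rnorm(dim)
  u <- u / sqrt(sum(u * u))
  rng <- local_rng(seed)
  shift <- outer(ifelse(windows@label == 1L, signal / 2, -signal / 2), u)
  emb <- matrix(rng$rnorm(n * as.integer(dim)), nrow = n) + shift
  rownames(emb) <- windowKeys(windows)
  emb
}

#' Stable per-window keys
#'
#' @param windows A [SiteWindowSet-class].
#' @return Character vector `protein_id:center_pos`.
#' @export
windowKeys <- function(windows)
  paste0(windows@proteinId, ":", windows@centerPos)

#' Write an embedding table
#'
#' TSV with a `key` column (`protein_id:center_pos`) followed by one
#' column per embedding dimension; [embeddingProvider()] reads it back.
#'
#' @param emb matrix with rownames as keys.
#' @param file output path.
#' @export
writeEmbeddingTable <- function(emb, file) {
  df <- data.frame(key = rownames(emb), emb, check.names = FALSE)
  colnames(df) <- c("key", paste0("e", seq_len(ncol(emb))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' The standard synthetic benchmark fixture
#'
#' Convenience wrapper reproducing the package's reference simulation:
#' `nProteins` proteins with planted motifs, balanced windows of length
#' `L`, and embeddings at the given signal strength. With the defaults
#' (1000 proteins, two positive and two negative lysines each) this
#' yields 4000 windows.
#'
#' @param nProteins,motifStrength,seed,sitesPerProtein passed to
#'   [simulateProteins()].
#' @param L window length.
#' @param embeddingDim,signal passed to [simulateEmbeddings()].
#' @return List with elements `proteins`, `windows`, `embeddings`.
#' @export
simulateBenchmark <- function(nProteins = 1000L, motifStrength = 1,
                              signal = 3, L = 25L, embeddingDim = 1024L,
                              seed = 1L, sitesPerProtein = 2L) {
  proteins <- simulateProteins(nProteins, motifStrength, seed,
                               sitesPerProtein)
  windows <- buildDataset(proteins, L = L, seed = seed + 1L)
  embeddings <- simulateEmbeddings(windows, dim = embeddingDim,
                                   signal = signal, seed = seed + 2L)
  list(proteins = proteins, windows = windows, embeddings = embeddings)
}
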