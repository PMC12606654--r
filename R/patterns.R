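# Sequence-pattern analyses of positive versus negative windows:
# pooled amino-acid frequencies, position-wise two-sample-logo
# enrichment/depletion testing, and positional VHSE property profiles.

position_offsets <- function(L) seq_len(L) - (L + 1L) %/% 2L

#' Per-class amino-acid frequencies
#'
#' Pools residue counts over all non-pad window positions (optionally
#' excluding the centre lysine, the convention for ubiquitination data)
#' and normalizes to frequencies per class.
#'
#' @param windows A [SiteWindowSet-class].
#' @param excludeCenter drop the centre residue from the counts
#'   (default `TRUE`).
#' @return Matrix with one row per class present (`"negative"`,
#'   `"positive"`) and 20 amino-acid columns, each row summing to 1.
#' @export
aaFrequencies <- function(windows, excludeCenter = TRUE) {
  if (length(windows) == 0L) stop("'windows' is empty")
  chars <- window_char_matrix(windows)
  if (excludeCenter) chars <- chars[, -((windows@L + 1L) %/% 2L), drop = FALSE]
  classes <- sort(unique(windows@label))
  out <- matrix(0, length(classes), length(AA_STANDARD),
                dimnames = list(ifelse(classes == 1L, "positive", "negative"),
                                AA_STANDARD))
  for (i in seq_along(classes)) {
    cc <- chars[windows@label == classes[i], , drop = FALSE]
    counts <- table(factor(cc, levels = AA_STANDARD))
    out[i, ] <- counts / sum(counts)
  }
  out
}

#' Two-sample-logo enrichment analysis
#'
#' For every position and residue, compares per-window occurrence
#' indicators (1 if the residue occupies that position) between the
#' positive and negative sets with a two-sided Welch t-test. Residues
#' with `p < alpha` are reported as enriched (more frequent in
#' positives) or depleted (more frequent in negatives). Residues absent
#' from both classes at a position are excluded from testing. No
#' multiple-testing correction is applied by default, matching the
#' `p < 0.05` screen conventional for two-sample logos; `correction`
#' switches on `p.adjust`.
#'
#' @param posWindows,negWindows [SiteWindowSet-class] objects of equal
#'   window length.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return data.frame with columns `position` (offset from the centre),
#'   `residue`, `direction` (`"enriched"`/`"depleted"`), `t`, `p`,
#'   `freqPos`, `freqNeg`, containing only the significant tests.
#' @export
twoSampleLogo <- function(posWindows, negWindows, alpha = 0.05,
                          correction = c("none", "bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (length(posWindows) == 0L || length(negWindows) == 0L)
    stop("both window sets must be non-empty")
  if (posWindows@L != negWindows@L)
    stop("window lengths differ")
  L <- posWindows@L
  cp <- window_char_matrix(posWindows)
  cn <- window_char_matrix(negWindows)
  offs <- position_offsets(L)
  rows <- list()
  for (j in seq_len(L)) {
    if (offs[j] == 0L) next                       # centre is K everywhere
    for (aa in AA_STANDARD) {
      xp <- as.numeric(cp[, j] == aa)
      xn <- as.numeric(cn[, j] == aa)
      if (sum(xp) + sum(xn) == 0) next
      # Welch t-test on occurrence indicators; degenerate (zero-variance-
      # in-both) splits can't be tested
      if (stats::var(xp) == 0 && stats::var(xn) == 0) {
        if (mean(xp) == mean(xn)) next
        tt <- list(statistic = c(t = sign(mean(xp) - mean(xn)) * Inf),
                   p.value = 0)
      } else {
        tt <- stats::t.test(xp, xn)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = offs[j], residue = aa,
        direction = if (mean(xp) > mean(xn)) "enriched" else "depleted",
        t = unname(tt$statistic), p = tt$p.value,
        freqPos = mean(xp), freqNeg = mean(xn))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), residue = character(0),
               direction = character(0), t = numeric(0), p = numeric(0),
               freqPos = numeric(0), freqNeg = numeric(0))
  if (correction != "none") res$p <- stats::p.adjust(res$p, correction)
  res[res$p < alpha, , drop = FALSE]
}

#' Fraction of position-residue tests flagged significant
#'
#' Calibration helper: on label-permuted data the flagged fraction should
#' be close to `alpha`.
#'
#' @param posWindows,negWindows window sets.
#' @param alpha significance level.
#' @return Flagged tests divided by performed tests.
#' @export
logoFlaggedFraction <- function(posWindows, negWindows, alpha = 0.05) {
  hits <- twoSampleLogo(posWindows, negWindows, alpha = 1.01)  # all tests
  if (nrow(hits) == 0L) return(0)
  sum(hits$p < alpha) / nrow(hits)
}

#' Positional VHSE property profile
#'
#' For each window position and class, the arithmetic mean of the chosen
#' VHSE component over the residues occupying that position (pad
#' positions skipped). VHSE1 tracks hydrophobicity, VHSE3 steric bulk,
#' VHSE5 electronic properties.
#'
#' @param windows A [SiteWindowSet-class].
#' @param component VHSE component, 1-8.
#' @param table descriptor table, default [vhseTable()].
#' @return data.frame with columns `position`, `class`, `mean`.
#' @export
vhseProfile <- function(windows, component = 1L, table = vhseTable()) {
  component <- as.integer(component)
  if (component < 1L || component > ncol(table))
    stop("'component' must be in 1..", ncol(table))
  chars <- window_char_matrix(windows)
  vals <- matrix(table[match(chars, rownames(table)), component],
                 nrow = nrow(chars))
  offs <- position_offsets(windows@L)
  rows <- list()
  for (cls in sort(unique(windows@label))) {
    sel <- windows@label == cls
    mu <- colMeans(vals[sel, , drop = FALSE], na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      position = offs, class = if (cls == 1L) "positive" else "negative",
      mean = mu)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
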