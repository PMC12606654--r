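# Shared fixture builders and independent oracles for the test suite.

# Construct a SiteWindowSet directly from window strings (centre must be K).
make_windows <- function(strings, labels, L = nchar(strings[1])) {
  new("SiteWindowSet", windows = strings,
      proteinId = sprintf("p%d", seq_along(strings)),
      centerPos = rep((L + 1L) %/% 2L, length(strings)),
      label = as.integer(labels), L = as.integer(L))
}

# A small encoded dataset for network/training tests: planted motifs and
# separable embeddings, low dimension so training is fast.
small_feature_fixture <- function(nProteins = 40, dim = 16L, signal = 3,
                                  L = 11L, seed = 7L) {
  ps <- simulateProteins(nProteins, motifStrength = 1, seed = seed)
  win <- buildDataset(ps, L = L, seed = seed + 1L)
  emb <- simulateEmbeddings(win, dim = dim, signal = signal, seed = seed + 2L)
  list(windows = win, features = encodeWindows(win, emb))
}

# Linear probe oracle: project held-out samples on the difference of
# class means estimated from a training half, score by ROC AUC.
linear_probe_auc <- function(emb, labels, seed = 1L) {
  set.seed(seed)
  n <- nrow(emb)
  tr <- sample.int(n, n %/% 2)
  mu1 <- colMeans(emb[tr, , drop = FALSE][labels[tr] == 1, , drop = FALSE])
  mu0 <- colMeans(emb[tr, , drop = FALSE][labels[tr] == 0, , drop = FALSE])
  w <- mu1 - mu0
  te <- setdiff(seq_len(n), tr)
  rocAUC(labels[te], as.numeric(emb[te, , drop = FALSE] %*% w))
}

# O(n^2) pairwise-comparison oracle for ROC AUC (ties count one half).
pairwise_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Naive loop oracle for confusion counts.
loop_confusion_oracle <- function(labels, scores, threshold) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (!pred && labels[i] == 0) tn <- tn + 1L
    else if (pred) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Direct formula evaluation of the six scalar metrics (independent of the
# package's safe-division plumbing); NA where undefined.
loop_scalar_oracle <- function(cts) {
  tp <- cts["TP"]; tn <- cts["TN"]; fp <- cts["FP"]; fn <- cts["FN"]
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- div(tp, tp + fn); sp <- div(tn, tn + fp); pr <- div(tp, tp + fp)
  f1 <- if (is.na(pr) || is.na(sn) || pr + sn == 0) NA_real_
        else 2 * pr * sn / (pr + sn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) NA_real_ else unname((tp * tn - fp * fn) / den)
  c(acc = unname(div(tp + tn, tp + tn + fp + fn)), sn = unname(sn),
    sp = unname(sp), precision = unname(pr), f1 = unname(f1), mcc = mcc)
}
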