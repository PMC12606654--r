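# 5-fold cross-validation training and averaged-probability ensembling,
# plus the window-length sweep experiment. Optimization follows the
# published recipe: Adam at learning rate 5e-4, binary cross-entropy,
# batch size 128; the epoch budget and best-validation-loss
# checkpointing with early stopping are this package's bounded defaults.

#' Stratified k-fold assignment
#'
#' Seeded, stratified by label: per-fold class proportions are within one
#' sample of the global proportions, and the folds partition the data
#' exactly.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
kfoldSplit <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  for (cls in unique(labels))
    if (sum(labels == cls) < k)
      stop("class ", cls, " has fewer than k = ", k, " samples")
  rng <- local_rng(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- rng$sample(idx, length(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

bce_loss <- function(p, y) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

train_network <- function(model, trainFeat, valFeat, epochs = 40L,
                          lr = 5e-4, batchSize = 128L, patience = 10L,
                          verbose = FALSE) {
  net <- model@net
  opt <- adam_new(net$params, lr = lr)
  ntr <- length(trainFeat$label)
  best_val <- Inf
  best_snap <- snapshot_params(net$params)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(ntr)
    batch_losses <- numeric(0)
    for (bs in split(perm, ceiling(seq_along(perm) / batchSize))) {
      b <- subset_features(trainFeat, bs)
      p <- net$forward(list(aaindex = b$aaindex, blosum = b$blosum,
                            embedding = b$embedding), training = TRUE)
      loss <- bce_loss(p, b$label)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (batch of ", length(bs), "; p range [",
             paste(signif(range(p), 3), collapse = ", "), "])")
      batch_losses <- c(batch_losses, loss)
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      dprob <- (pc - b$label) / (pc * (1 - pc)) / length(bs)
      opt$zero()
      net$backward(dprob)
      opt$step()
    }
    pv <- predictProb(model, valFeat)
    vloss <- bce_loss(pv, valFeat$label)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   trainLoss = mean(batch_losses),
                                   valLoss = vloss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep,
                      mean(batch_losses), vloss))
    if (vloss < best_val - 1e-6) {
      best_val <- vloss
      best_snap <- snapshot_params(net$params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  restore_params(net$params, best_snap)
  attr(hist, "lr") <- lr
  attr(hist, "batchSize") <- batchSize
  attr(hist, "bestValLoss") <- best_val
  hist
}

#' Train one cross-validation fold
#'
#' Builds a fresh network (seeded weight initialisation), trains it with
#' Adam (learning rate 5e-4), binary cross-entropy and batch size 128,
#' and returns the checkpoint with the best validation loss. Training
#' stops early when the validation loss has not improved for `patience`
#' epochs.
#'
#' @param trainFeat,valFeat encoded feature lists from [encodeWindows()]
#'   (must carry a `label` element).
#' @param cfg A [ModelConfig-class].
#' @param seed integer seed covering weight init, batch shuffling and
#'   dropout.
#' @param epochs maximum epochs.
#' @param lr,batchSize optimizer settings.
#' @param patience early-stopping patience in epochs.
#' @param verbose print per-epoch losses.
#' @return List with `model` (a [BuiltModel-class]) and `history` (per-
#'   epoch loss data.frame with `lr`, `batchSize`, `bestValLoss`
#'   attributes).
#' @export
trainFold <- function(trainFeat, valFeat, cfg, seed = 1L, epochs = 40L,
                      lr = 5e-4, batchSize = 128L, patience = 10L,
                      verbose = FALSE) {
  set.seed(as.integer(seed))
  model <- buildModel(cfg)
  history <- train_network(model, trainFeat, valFeat, epochs = epochs,
                           lr = lr, batchSize = batchSize,
                           patience = patience, verbose = verbose)
  list(model = model, history = history)
}

#' Train the k-fold cross-validation ensemble
#'
#' Splits the samples into stratified folds, trains one sub-model per
#' fold (trained on k-1 folds, validated on the held-out fold), and
#' returns the ensemble whose prediction is the arithmetic mean of the
#' sub-model probabilities.
#'
#' @param features encoded feature list from [encodeWindows()].
#' @param cfg A [ModelConfig-class].
#' @param k number of folds (default 5).
#' @param seed integer seed; fold `i` trains with seed `seed + i`.
#' @param ... passed to [trainFold()] (`epochs`, `lr`, `batchSize`,
#'   `patience`, `verbose`).
#' @return A [FoldEnsemble-class].
#' @export
trainEnsemble <- function(features, cfg, k = 5L, seed = 1L, ...) {
  fold <- kfoldSplit(features$label, k = k, seed = seed)
  models <- vector("list", k)
  histories <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- subset_features(features, which(fold != i))
    va <- subset_features(features, which(fold == i))
    fit <- trainFold(tr, va, cfg, seed = seed + i, ...)
    models[[i]] <- fit$model
    histories[[i]] <- fit$history
  }
  new("FoldEnsemble", subModels = models, foldAssignments = fold,
      trainHistory = histories, config = cfg)
}

#' Averaged-probability ensemble prediction
#'
#' @param ensemble A [FoldEnsemble-class].
#' @param features encoded feature list.
#' @return Numeric vector: the arithmetic mean of the sub-model
#'   probabilities.
#' @export
predictEnsemble <- function(ensemble, features) {
  probs <- vapply(ensemble@subModels, predictProb,
                  numeric(length(features$label) %||% dim(features$aaindex)[1]),
                  features = features)
  rowMeans(probs)
}

#' Seeded split of proteins into train and test partitions
#'
#' Splitting is by protein identity, so no protein contributes windows to
#' both partitions.
#'
#' @param proteins A [ProteinSet-class].
#' @param testFraction fraction of proteins assigned to the test set.
#' @param seed integer seed.
#' @return List with `train` and `test` [ProteinSet-class] objects.
#' @export
splitProteins <- function(proteins, testFraction = 0.3, seed = 1L) {
  n <- length(proteins@sequences)
  rng <- local_rng(seed)
  ntest <- max(1L, round(testFraction * n))
  test_idx <- sort(rng$sample(seq_len(n), ntest))
  subset_ps <- function(idx)
    new("ProteinSet", sequences = proteins@sequences[idx],
        ubiqSites = proteins@ubiqSites[idx])
  list(train = subset_ps(setdiff(seq_len(n), test_idx)),
       test = subset_ps(test_idx))
}

#' Default window-length grid
#'
#' The odd integers from 7 to 69: 32 settings.
#'
#' @return Integer vector of length 32.
#' @export
defaultSweepLengths <- function() seq(7L, 69L, by = 2L)

#' Window-length sweep experiment
#'
#' For each window length, rebuilds the window datasets from the training
#' and test proteins, regenerates embeddings, retrains the full
#' cross-validation ensemble and records metrics on the cross-validation
#' folds and the held-out test proteins.
#'
#' @param trainProteins,testProteins [ProteinSet-class] partitions, e.g.
#'   from [splitProteins()].
#' @param lengths odd window lengths; default [defaultSweepLengths()].
#' @param cfgFor function mapping a length to a [ModelConfig-class].
#' @param signal embedding signal strength for the synthetic provider.
#' @param embeddingDim embedding dimension.
#' @param k folds.
#' @param seed integer seed.
#' @param threshold decision threshold for scalar metrics.
#' @param ... passed to [trainFold()].
#' @return data.frame with one row per (length, split) and the eight
#'   metric columns.
#' @export
lengthSweep <- function(trainProteins, testProteins,
                        lengths = defaultSweepLengths(),
                        cfgFor = function(L) smallModelConfig(L = L),
                        signal = 3, embeddingDim = 1024L, k = 5L,
                        seed = 1L, threshold = 0.5, ...) {
  if (any(lengths %% 2L == 0L))
    stop("window lengths must be odd: ",
         paste(lengths[lengths %% 2L == 0L], collapse = ", "))
  rows <- list()
  for (L in as.integer(lengths)) {
    wtr <- buildDataset(trainProteins, L = L, seed = seed)
    wte <- buildDataset(testProteins, L = L, seed = seed)
    ftr <- encodeWindows(wtr, embeddingProvider("synthetic",
             dim = embeddingDim, signal = signal, seed = seed))
    fte <- encodeWindows(wte, embeddingProvider("synthetic",
             dim = embeddingDim, signal = signal, seed = seed + 1L))
    ens <- trainEnsemble(ftr, cfgFor(L), k = k, seed = seed, ...)
    # validation metrics: each sample scored by the model that held it out
    val_scores <- numeric(length(ftr$label))
    for (i in seq_len(k)) {
      idx <- which(ens@foldAssignments == i)
      val_scores[idx] <- predictProb(ens@subModels[[i]],
                                     subset_features(ftr, idx))
    }
    test_scores <- predictEnsemble(ens, fte)
    for (split in c("validation", "test")) {
      rep <- if (split == "validation")
        evaluateScores(ftr$label, val_scores, threshold)
      else evaluateScores(fte$label, test_scores, threshold)
      rows[[length(rows) + 1L]] <- data.frame(length = L, split = split,
        t(reportMetrics(rep)))
    }
  }
  do.call(rbind, rows)
}
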