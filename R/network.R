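#' Create a ResUbiNet architecture configuration
#'
#' The published architecture fixes its layer dimensions in supplementary
#' material; the defaults here are this package's reconstruction from the
#' figure-level wiring plus the published trainable-parameter count
#' (399,411), which [buildModel()] reproduces exactly. Every dimension can
#' be overridden, so smaller configurations can be used for fast
#' experiments.
#'
#' @param L odd window length (default 25).
#' @param nHeads number of attention heads in the transformer blocks.
#' @param attnKeyDim per-head query/key/value dimension.
#' @param transformerDenseUnits hidden width of the transformer feed-forward
#'   sub-block.
#' @param mkKernelSizes distinct kernel sizes of the multi-kernel
#'   convolution.
#' @param mkFiltersPerKernel filters per kernel size (output channels are
#'   `length(mkKernelSizes) * mkFiltersPerKernel`).
#' @param convFilters channels of the two standard convolutions, the SE
#'   block and the residual shortcut projection.
#' @param convKernelSize kernel size of the two standard convolutions.
#' @param seRatio squeeze-and-excitation bottleneck ratio; must divide
#'   `convFilters`.
#' @param poolSize max-pooling window (stride equals the window).
#' @param headDenseUnits widths of the two dense layers after concatenating
#'   the two sequence branches.
#' @param embedDenseUnits widths of the two dense layers on the embedding
#'   branch.
#' @param fusionDenseUnits widths of the two dense layers after fusing
#'   sequence and embedding features.
#' @param dropoutRates dropout rates applied after the two sequence-head
#'   dense layers and the first fusion dense layer.
#' @param embeddingDim length of the protein-language-model embedding
#'   vector (1024).
#' @return A validated [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig()
#' cfg
#' @export
modelConfig <- function(L = 25L, nHeads = 4L, attnKeyDim = 16L,
                        transformerDenseUnits = 64L,
                        mkKernelSizes = c(3L, 5L, 7L),
                        mkFiltersPerKernel = 16L,
                        convFilters = 48L, convKernelSize = 3L,
                        seRatio = 8L, poolSize = 2L,
                        headDenseUnits = c(132L, 48L),
                        embedDenseUnits = c(160L, 32L),
                        fusionDenseUnits = c(64L, 32L),
                        dropoutRates = c(0.3, 0.3, 0.3),
                        embeddingDim = 1024L) {
  new("ModelConfig", L = as.integer(L), nHeads = as.integer(nHeads),
      attnKeyDim = as.integer(attnKeyDim),
      transformerDenseUnits = as.integer(transformerDenseUnits),
      mkKernelSizes = as.integer(mkKernelSizes),
      mkFiltersPerKernel = as.integer(mkFiltersPerKernel),
      convFilters = as.integer(convFilters),
      convKernelSize = as.integer(convKernelSize),
      seRatio = as.integer(seRatio), poolSize = as.integer(poolSize),
      headDenseUnits = as.integer(headDenseUnits),
      embedDenseUnits = as.integer(embedDenseUnits),
      fusionDenseUnits = as.integer(fusionDenseUnits),
      dropoutRates = as.numeric(dropoutRates),
      embeddingDim = as.integer(embeddingDim))
}

#' A small configuration for fast experiments and tests
#'
#' Same topology as [modelConfig()] with every width reduced, so a full
#' 5-fold ensemble trains in minutes on one CPU. Used by the packaged
#' examples and the synthetic-fixture experiments.
#'
#' @param L odd window length.
#' @param embeddingDim embedding vector length.
#' @return A [ModelConfig-class] object.
#' @export
smallModelConfig <- function(L = 25L, embeddingDim = 1024L) {
  modelConfig(L = L, nHeads = 2L, attnKeyDim = 8L,
              transformerDenseUnits = 16L, mkKernelSizes = c(3L, 5L),
              mkFiltersPerKernel = 4L, convFilters = 16L,
              convKernelSize = 3L, seRatio = 4L, poolSize = 2L,
              headDenseUnits = c(32L, 16L), embedDenseUnits = c(32L, 16L),
              fusionDenseUnits = c(16L, 8L),
              dropoutRates = c(0.2, 0.2, 0.2),
              embeddingDim = as.integer(embeddingDim))
}

# transformer block: attention with residual, layer norm, two-layer dense
# with residual, layer norm; sequence shape preserved
nn_transformer_block <- function(seq_len, feat_dim, cfg) {
  if (feat_dim < cfg@nHeads)
    stop("feature dimension (", feat_dim, ") must be >= number of heads (",
         cfg@nHeads, ")")
  nn_seq(
    nn_residual(nn_mha(feat_dim, cfg@nHeads, cfg@attnKeyDim)),
    nn_layernorm(feat_dim),
    nn_residual(nn_seq(
      nn_dense(feat_dim, cfg@transformerDenseUnits, "relu"),
      nn_dense(cfg@transformerDenseUnits, feat_dim, "linear"))),
    nn_layernorm(feat_dim))
}

# residual block: multi-kernel conv -> max-pool -> two convs -> SE, with a
# kernel-size-1 conv + max-pool shortcut projection
nn_residual_block <- function(feat_dim, cfg) {
  c1 <- length(cfg@mkKernelSizes) * cfg@mkFiltersPerKernel
  main <- nn_seq(
    nn_multikernel(feat_dim, cfg@mkFiltersPerKernel, cfg@mkKernelSizes),
    nn_maxpool1d(cfg@poolSize),
    nn_conv1d(c1, cfg@convFilters, cfg@convKernelSize, "relu"),
    nn_conv1d(cfg@convFilters, cfg@convFilters, cfg@convKernelSize, "relu"),
    nn_se(cfg@convFilters, cfg@seRatio))
  shortcut <- nn_seq(
    nn_conv1d(feat_dim, cfg@convFilters, 1L, "linear"),
    nn_maxpool1d(cfg@poolSize))
  nn_residual(main, shortcut)
}

#' Build a ResUbiNet model
#'
#' Constructs the three-input network: the AAindex (`L x 31`) and BLOSUM62
#' (`L x 20`) channels each pass through a transformer block followed by a
#' residual convolution block with squeeze-and-excitation; their flattened
#' outputs are concatenated and processed by two dense layers with dropout;
#' the 1024-dimensional embedding passes through two dense layers; the
#' fused features pass through two further dense layers and a sigmoid
#' output neuron giving the ubiquitination probability.
#'
#' Weight initialisation draws from the current R random number stream;
#' call `set.seed()` first for reproducible builds.
#'
#' @param cfg A [ModelConfig-class], e.g. [modelConfig()].
#' @return A [BuiltModel-class] object.
#' @examples
#' set.seed(1)
#' m <- buildModel(smallModelConfig())
#' paramCount(m)
#' @export
buildModel <- function(cfg) {
  validObject(cfg)
  L <- cfg@L
  lp <- L %/% cfg@poolSize
  flat_per_branch <- lp * cfg@convFilters

  net <- new.env(parent = emptyenv())
  net$branchA <- nn_seq(nn_transformer_block(L, 31L, cfg),
                        nn_residual_block(31L, cfg), nn_flatten())
  net$branchB <- nn_seq(nn_transformer_block(L, 20L, cfg),
                        nn_residual_block(20L, cfg), nn_flatten())
  net$seqHead <- nn_seq(
    nn_dense(2L * flat_per_branch, cfg@headDenseUnits[1], "relu"),
    nn_dropout(cfg@dropoutRates[1]),
    nn_dense(cfg@headDenseUnits[1], cfg@headDenseUnits[2], "relu"),
    nn_dropout(cfg@dropoutRates[2]))
  net$embHead <- nn_seq(
    nn_dense(cfg@embeddingDim, cfg@embedDenseUnits[1], "relu"),
    nn_dense(cfg@embedDenseUnits[1], cfg@embedDenseUnits[2], "relu"))
  net$fusion <- nn_seq(
    nn_dense(cfg@headDenseUnits[2] + cfg@embedDenseUnits[2],
             cfg@fusionDenseUnits[1], "relu"),
    nn_dropout(cfg@dropoutRates[3]),
    nn_dense(cfg@fusionDenseUnits[1], cfg@fusionDenseUnits[2], "relu"),
    nn_dense(cfg@fusionDenseUnits[2], 1L, "sigmoid"))
  net$params <- c(net$branchA$params, net$branchB$params, net$seqHead$params,
                  net$embHead$params, net$fusion$params)
  net$d2 <- cfg@headDenseUnits[2]

  net$forward <- function(batch, training = FALSE) {
    fa <- net$branchA$forward(batch$aaindex, training)
    fb <- net$branchB$forward(batch$blosum, training)
    h <- net$seqHead$forward(cbind(fa, fb), training)
    e <- net$embHead$forward(batch$embedding, training)
    net$na <- ncol(fa)
    p <- net$fusion$forward(cbind(h, e), training)
    as.numeric(p)
  }
  net$backward <- function(dprob) {
    dz <- net$fusion$backward(matrix(dprob, ncol = 1))
    dh <- dz[, seq_len(net$d2), drop = FALSE]
    de <- dz[, -seq_len(net$d2), drop = FALSE]
    net$embHead$backward(de)
    dcat <- net$seqHead$backward(dh)
    net$branchA$backward(dcat[, seq_len(net$na), drop = FALSE])
    net$branchB$backward(dcat[, -seq_len(net$na), drop = FALSE])
    invisible(NULL)
  }

  new("BuiltModel", net = net, config = cfg,
      paramCount = as.integer(n_params(net$params)))
}

#' Number of trainable parameters
#'
#' @param model A [BuiltModel-class].
#' @return Integer parameter count.
#' @export
paramCount <- function(model) model@paramCount

#' Predict ubiquitination probabilities with a built model
#'
#' Deterministic inference (dropout disabled). Input features are encoded
#' with [encodeWindows()].
#'
#' @param model A [BuiltModel-class].
#' @param features A feature list with elements `aaindex` (`N x L x 31`),
#'   `blosum` (`N x L x 20`) and `embedding` (`N x embeddingDim`), as
#'   returned by [encodeWindows()].
#' @param batchSize samples per forward pass.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predictProb <- function(model, features, batchSize = 256L) {
  n <- dim(features$aaindex)[1]
  out <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    out[s] <- model@net$forward(list(
      aaindex = features$aaindex[s, , , drop = FALSE],
      blosum = features$blosum[s, , , drop = FALSE],
      embedding = features$embedding[s, , drop = FALSE]), training = FALSE)
  }
  out
}
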