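test_that("stratified k-fold assignment partitions the data exactly", {
  labels <- rep(c(1L, 0L), each = 50)
  fold <- kfoldSplit(labels, k = 5, seed = 1)
  expect_identical(sort(unique(fold)), 1:5)
  for (i in 1:5) {
    expect_equal(sum(fold == i), 20L)
    expect_equal(sum(fold == i & labels == 1L), 10L)
  }
  expect_identical(fold, kfoldSplit(labels, k = 5, seed = 1))
  expect_false(identical(fold, kfoldSplit(labels, k = 5, seed = 2)))
})

test_that("fold proportions stay within one sample of global on odd sizes", {
  set.seed(20)
  labels <- rbinom(103, 1, 0.37)
  fold <- kfoldSplit(labels, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  pos_per_fold <- tapply(labels, fold, sum)
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_error(kfoldSplit(c(1, 1, 0, 0), k = 5, seed = 1), "fewer than k")
})

test_that("training on separable data reduces the validation loss quickly", {
  fix <- small_feature_fixture(nProteins = 40, dim = 16L, signal = 3)
  fold <- kfoldSplit(fix$features$label, k = 4, seed = 5)
  tr <- resubinet:::subset_features(fix$features, which(fold != 1))
  va <- resubinet:::subset_features(fix$features, which(fold == 1))
  cfg <- smallModelConfig(L = 11L, embeddingDim = 16L)
  fit <- trainFold(tr, va, cfg, seed = 6, epochs = 5, patience = 5,
                   batchSize = 32)
  h <- fit$history
  expect_lt(min(h$valLoss), h$valLoss[1])
  expect_lt(min(h$valLoss), log(2))          # better than chance
  # optimizer settings are echoed into the history metadata
  expect_equal(attr(h, "lr"), 5e-4)
  expect_equal(attr(h, "batchSize"), 32)
})

test_that("training is reproducible under a fixed seed", {
  fix <- small_feature_fixture(nProteins = 16, dim = 8L)
  fold <- kfoldSplit(fix$features$label, k = 4, seed = 7)
  tr <- resubinet:::subset_features(fix$features, which(fold != 1))
  va <- resubinet:::subset_features(fix$features, which(fold == 1))
  cfg <- smallModelConfig(L = 11L, embeddingDim = 8L)
  f1 <- trainFold(tr, va, cfg, seed = 9, epochs = 2, batchSize = 16)
  f2 <- trainFold(tr, va, cfg, seed = 9, epochs = 2, batchSize = 16)
  expect_equal(f1$history$valLoss, f2$history$valLoss, tolerance = 1e-3)
})

test_that("ensemble probabilities are the arithmetic mean of the folds", {
  fix <- small_feature_fixture(nProteins = 16, dim = 8L)
  ens <- trainEnsemble(fix$features, smallModelConfig(L = 11L,
                       embeddingDim = 8L), k = 3, seed = 1, epochs = 1,
                       batchSize = 16)
  expect_s4_class(ens, "FoldEnsemble")
  expect_length(ens@subModels, 3L)
  p_ens <- predictEnsemble(ens, fix$features)
  per_model <- sapply(ens@subModels, predictProb, features = fix$features)
  expect_equal(p_ens, rowMeans(per_model), tolerance = 1e-15)
  expect_true(all(p_ens >= apply(per_model, 1, min) - 1e-15))
  expect_true(all(p_ens <= apply(per_model, 1, max) + 1e-15))
  # every sample is assigned to exactly one validation fold
  expect_identical(sort(unique(ens@foldAssignments)), 1:3)
  expect_length(ens@foldAssignments, length(fix$features$label))
})

test_that("mean aggregation reproduces the worked example", {
  # sub-model outputs {0.2, 0.4, 0.6, 0.8, 1.0} average to 0.6
  expect_equal(mean(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)
  fix <- small_feature_fixture(nProteins = 8, dim = 8L)
  ens <- trainEnsemble(fix$features, smallModelConfig(L = 11L,
                       embeddingDim = 8L), k = 2, seed = 2, epochs = 1,
                       batchSize = 16)
  # identical sub-models -> ensemble equals any sub-model
  ens@subModels[[2]] <- ens@subModels[[1]]
  expect_equal(predictEnsemble(ens, fix$features),
               predictProb(ens@subModels[[1]], fix$features),
               tolerance = 1e-15)
})

test_that("ensembles and configs round-trip through their files", {
  fix <- small_feature_fixture(nProteins = 10, dim = 8L)
  cfg <- smallModelConfig(L = 11L, embeddingDim = 8L)
  ens <- trainEnsemble(fix$features, cfg, k = 2, seed = 3, epochs = 1,
                       batchSize = 16)
  f <- tempfile(fileext = ".rds")
  saveEnsemble(ens, f)
  back <- loadEnsemble(f)
  expect_equal(predictEnsemble(back, fix$features),
               predictEnsemble(ens, fix$features), tolerance = 1e-15)
  cf <- tempfile(fileext = ".json")
  writeModelConfig(cfg, cf)
  cfg2 <- readModelConfig(cf)
  expect_identical(resubinet:::config_to_list(cfg2),
                   resubinet:::config_to_list(cfg))
})

test_that("the default sweep grid is the 32 odd lengths from 7 to 69", {
  lens <- defaultSweepLengths()
  expect_length(lens, 32L)
  expect_identical(lens[1], 7L)
  expect_identical(lens[32], 69L)
  expect_true(all(lens %% 2L == 1L))
})

test_that("the length sweep trains per length and rejects even lengths", {
  ps <- simulateProteins(24, 1, seed = 30)
  parts <- splitProteins(ps, testFraction = 0.33, seed = 31)
  expect_error(lengthSweep(parts$train, parts$test, lengths = c(8L)),
               "odd")
  tab <- lengthSweep(parts$train, parts$test, lengths = 9L,
                     cfgFor = function(L) smallModelConfig(L = L,
                       embeddingDim = 8L),
                     embeddingDim = 8L, k = 2, seed = 32, epochs = 1,
                     batchSize = 16)
  expect_equal(nrow(tab), 2L)                # validation + test rows
  expect_setequal(tab$split, c("validation", "test"))
  expect_true(all(c("acc", "auc", "mcc") %in% names(tab)))
})
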