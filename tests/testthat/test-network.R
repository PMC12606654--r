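cfg_tiny <- function() modelConfig(L = 9L, nHeads = 2L, attnKeyDim = 4L,
  transformerDenseUnits = 8L, mkKernelSizes = c(1L, 3L),
  mkFiltersPerKernel = 4L, convFilters = 8L, convKernelSize = 3L,
  seRatio = 4L, poolSize = 2L, headDenseUnits = c(12L, 8L),
  embedDenseUnits = c(12L, 8L), fusionDenseUnits = c(8L, 4L),
  dropoutRates = c(0.2, 0.2, 0.2), embeddingDim = 16L)

rand_seq_input <- function(n, l, c) array(runif(n * l * c), dim = c(n, l, c))

test_that("the transformer block preserves sequence shape", {
  set.seed(1)
  blk <- resubinet:::nn_transformer_block(9L, 31L, cfg_tiny())
  x <- rand_seq_input(4, 9, 31)
  y <- blk$forward(x)
  expect_identical(dim(y), dim(x))
  # batch independence: permuting samples permutes outputs identically
  perm <- c(3, 1, 4, 2)
  y2 <- blk$forward(x[perm, , , drop = FALSE])
  expect_equal(y2, y[perm, , , drop = FALSE], tolerance = 1e-12)
})

test_that("multi-kernel convolution concatenates channels, keeps length", {
  set.seed(2)
  mk1 <- resubinet:::nn_multikernel(5L, 8L, 1L)
  expect_identical(dim(mk1$forward(rand_seq_input(3, 7, 5)))[3], 8L)
  mk3 <- resubinet:::nn_multikernel(5L, 16L, c(3L, 5L, 7L))
  y <- mk3$forward(rand_seq_input(3, 25, 5))
  expect_identical(dim(y), c(3L, 25L, 48L))   # 3 kernels x 16 filters, same length
})

test_that("SE gate limits recover identity and zero transformations", {
  set.seed(3)
  se <- resubinet:::nn_se(8L, 4L)
  x <- rand_seq_input(2, 6, 8)
  # force gate to ~1: zero the second dense weights, huge positive bias
  se$fc2$W$value[] <- 0
  se$fc2$b$value[] <- 50
  expect_equal(se$forward(x), x, tolerance = 1e-12)
  # force gate to ~0: huge negative bias
  se$fc2$b$value[] <- -50
  expect_equal(max(abs(se$forward(x))), 0, tolerance = 1e-12)
  # generic gate: every channel scaled by a value in (0, 1)
  set.seed(4)
  se2 <- resubinet:::nn_se(8L, 4L)
  y <- se2$forward(x)
  ratio <- y / x
  expect_true(all(ratio > 0 & ratio < 1))
  expect_error(resubinet:::nn_se(9L, 4L))     # ratio must divide channels
})

test_that("the residual block reduces to its shortcut when the main path is zeroed", {
  set.seed(5)
  cfg <- cfg_tiny()
  blk <- resubinet:::nn_residual_block(5L, cfg)
  x <- rand_seq_input(3, 9, 5)
  y_full <- blk$forward(x)
  expect_identical(dim(y_full), c(3L, 4L, 8L))  # L/pool positions, convFilters
  # zero every main-path parameter: output must equal the shortcut branch
  for (p in blk$params) p$value[] <- 0
  # rebuild shortcut weights only
  sc <- resubinet:::nn_seq(resubinet:::nn_conv1d(5L, 8L, 1L, "linear"),
                           resubinet:::nn_maxpool1d(2L))
  set.seed(6)
  sc$nodes[[1]]$W$value[] <- rnorm(length(sc$nodes[[1]]$W$value))
  # copy those weights into the block's shortcut (last two params)
  np <- length(blk$params)
  blk$params[[np - 1L]]$value <- sc$nodes[[1]]$W$value
  blk$params[[np]]$value <- sc$nodes[[1]]$b$value
  expect_equal(blk$forward(x), sc$forward(x), tolerance = 1e-12)
})

test_that("model output is a probability for any finite input", {
  set.seed(7)
  m <- buildModel(cfg_tiny())
  batch <- list(aaindex = rand_seq_input(6, 9, 31),
                blosum = rand_seq_input(6, 9, 20),
                embedding = matrix(runif(6 * 16), 6))
  p <- m@net$forward(batch)
  expect_true(all(p > 0 & p < 1))
  # adversarial all-ones / all-zeros inputs stay finite and bounded
  ones <- list(aaindex = array(1, c(2, 9, 31)), blosum = array(1, c(2, 9, 20)),
               embedding = matrix(1, 2, 16))
  zeros <- list(aaindex = array(0, c(2, 9, 31)), blosum = array(0, c(2, 9, 20)),
                embedding = matrix(0, 2, 16))
  expect_true(all(is.finite(m@net$forward(ones))))
  expect_true(all(m@net$forward(zeros) >= 0 & m@net$forward(zeros) <= 1))
})

test_that("the default configuration builds with 399,411 trainable parameters", {
  set.seed(8)
  m <- buildModel(modelConfig())
  expect_identical(paramCount(m), 399411L)
  set.seed(9)                                  # count is init-independent
  expect_identical(paramCount(buildModel(modelConfig())), 399411L)
})

test_that("invalid configurations fail at build time with clear messages", {
  expect_error(modelConfig(L = 24L), "odd")
  expect_error(modelConfig(mkKernelSizes = c(3L, 3L)), "distinct")
  expect_error(modelConfig(convFilters = 10L, seRatio = 4L), "divide")
  expect_error(buildModel(modelConfig(nHeads = 32L)), "heads")
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(10)
  m <- buildModel(cfg_tiny())
  net <- m@net
  b <- list(aaindex = rand_seq_input(5, 9, 31),
            blosum = rand_seq_input(5, 9, 20),
            embedding = matrix(rnorm(5 * 16), 5))
  y <- c(1, 0, 1, 1, 0)
  loss_fn <- function() {
    p <- net$forward(b, training = FALSE)
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(y * log(pc) + (1 - y) * log(1 - pc))
  }
  p0 <- net$forward(b, training = FALSE)
  pc <- pmin(pmax(p0, 1e-7), 1 - 1e-7)
  for (pp in net$params) pp$grad <- array(0, dim = dim(pp$value))
  net$backward((pc - y) / (pc * (1 - pc)) / length(y))
  eps <- 1e-5
  set.seed(11)
  for (trial in 1:50) {
    pi <- sample(length(net$params), 1)
    par <- net$params[[pi]]
    ei <- sample(length(par$value), 1)
    v0 <- par$value[ei]
    par$value[ei] <- v0 + eps; lp <- loss_fn()
    par$value[ei] <- v0 - eps; lm <- loss_fn()
    par$value[ei] <- v0
    g_num <- (lp - lm) / (2 * eps)
    g_ana <- par$grad[ei]
    denom <- max(1e-6, abs(g_num) + abs(g_ana))
    expect_lt(abs(g_num - g_ana) / denom, 1e-4)
  }
})

test_that("inference is deterministic (dropout only active in training)", {
  set.seed(12)
  m <- buildModel(cfg_tiny())
  fix <- small_feature_fixture(nProteins = 4, dim = 16L, L = 9L)
  p1 <- predictProb(m, fix$features)
  p2 <- predictProb(m, fix$features)
  expect_identical(p1, p2)
})
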