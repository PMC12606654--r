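test_that("min-max normalization follows the stated closed form", {
  expect_equal(normalizeMinMax(cbind(c(1, 3, 5)))[, 1], c(0, 0.5, 1))
  expect_equal(normalizeMinMax(cbind(c(0, 1)))[, 1], c(0, 1))
  m <- cbind(a = c(1, 2), b = c(3, 3))
  expect_error(normalizeMinMax(m), "b")
})

test_that("the property table is 20 x 31 with exact per-column 0/1 range", {
  pt <- propertyTable()
  expect_identical(dim(pt), c(20L, 31L))
  expect_equal(unname(apply(pt, 2, min)), rep(0, 31))
  expect_equal(unname(apply(pt, 2, max)), rep(1, 31))
  expect_identical(rownames(pt),
    c("A","R","N","D","C","Q","E","G","H","I",
      "L","K","M","F","P","S","T","W","Y","V"))
})

test_that("BLOSUM62 normalization maps the published extremes", {
  raw <- blosumTable(normalized = FALSE)
  expect_identical(dim(raw), c(20L, 20L))
  expect_true(isSymmetric(raw))
  expect_equal(min(raw), -4)
  expect_equal(max(raw), 11)
  nb <- blosumTable()
  expect_equal(nb["W", "W"], 1)              # the max score (11)
  expect_equal(unname(nb["A", "K"]), (raw["A", "K"] + 4) / 15)
  # the K/K raw score of 5 maps to 9/15 = 0.6
  expect_equal(unname(raw["K", "K"]), 5)
  expect_equal(unname(nb["K", "K"]), 9 / 15)
})

test_that("AAindex encoding zero-fills pads and nonstandard residues", {
  win <- make_windows(c("--AKXW-"), 1L)
  enc <- encodeAAIndex(win)
  expect_identical(dim(enc), c(1L, 7L, 31L))
  expect_equal(enc[1, 1, ], setNames(rep(0, 31), colnames(propertyTable())))
  expect_equal(unname(enc[1, 2, ]), rep(0, 31))
  expect_equal(unname(enc[1, 5, ]), rep(0, 31))   # X
  expect_equal(unname(enc[1, 7, ]), rep(0, 31))
  expect_equal(unname(enc[1, 3, ]), unname(propertyTable()["A", ]))
})

test_that("a poly-A window encodes constant property rows", {
  win <- make_windows("AAAKAAA", 1L)
  enc <- encodeAAIndex(win)
  for (j in c(1:3, 5:7))
    expect_equal(unname(enc[1, j, ]), unname(propertyTable()["A", ]))
})

test_that("BLOSUM encoding is deterministic with K-diagonal dominance", {
  win <- make_windows(c("ARNKCQE", "ARNKCQE"), c(1L, 0L))
  e1 <- encodeBlosum(win)
  e2 <- encodeBlosum(win)
  expect_identical(e1, e2)
  # the K row scores K highest (diagonal dominance of BLOSUM62 for K)
  krow <- e1[1, 4, ]
  expect_identical(names(which.max(krow)), "K")
  # pad rows are zero
  ep <- encodeBlosum(make_windows("--KAA", 1L))
  expect_equal(unname(ep[1, 1, ]), rep(0, 20))
})

test_that("encoding is a pure function of the window string", {
  a <- encodeAAIndex(make_windows("LYFKWCV", 1L))
  b <- encodeAAIndex(make_windows("LYFKWCV", 0L))   # label must not matter
  expect_identical(a, b)
})

test_that("embedding providers honour the dimension contract", {
  win7 <- make_windows("AAAKAAA", 1L)
  win11 <- make_windows("AAAAAKAAAAA", 1L)
  prov <- embeddingProvider("synthetic", dim = 1024, signal = 1, seed = 5)
  expect_identical(ncol(prov$get(win7)), 1024L)
  expect_identical(ncol(prov$get(win11)), 1024L)   # independent of L
  expect_identical(prov$get(win7), prov$get(win7)) # reproducible
  # distinct windows with signal > 0 give distinct vectors
  two <- buildDataset(ProteinSet(c(p = "AKAAKAA"), list(p = 2L)),
                      L = 5, seed = 1)
  vecs <- prov$get(two)
  expect_false(isTRUE(all.equal(vecs[1, ], vecs[2, ])))
})

test_that("unknown providers and missing table keys are errors", {
  expect_error(embeddingProvider("prot5"), "arg")
  win <- make_windows("AAAKAAA", 1L)
  m <- matrix(0, 1, 4, dimnames = list("other:1", NULL))
  prov <- embeddingProvider("table", embeddings = m)
  expect_error(prov$get(win), "no embedding")
})

test_that("the protrans adapter pools per-residue embeddings", {
  # mock residue embedder: residue index repeated across 4 dims
  mock <- function(seq) {
    idx <- match(strsplit(seq, "")[[1]], LETTERS)
    matrix(rep(idx, 4), ncol = 4)
  }
  win <- make_windows("-CKW-", 1L)   # non-pad residues C K W
  mean_prov <- embeddingProvider("protrans", residueFun = mock)
  got <- mean_prov$get(win)
  expect_equal(unname(got[1, ]), rep(mean(match(c("C","K","W"), LETTERS)), 4))
  ctr_prov <- embeddingProvider("protrans", residueFun = mock,
                                pooling = "center")
  expect_equal(unname(ctr_prov$get(win)[1, ]), rep(match("K", LETTERS), 4))
})

test_that("encodeWindows assembles all three channels with labels", {
  fix <- small_feature_fixture(nProteins = 5, dim = 8L)
  f <- fix$features
  expect_identical(dim(f$aaindex)[3], 31L)
  expect_identical(dim(f$blosum)[3], 20L)
  expect_identical(ncol(f$embedding), 8L)
  expect_identical(f$label, windowLabels(fix$windows))
})
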