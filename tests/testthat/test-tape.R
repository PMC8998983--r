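# Finite-difference validation of the autodiff tape that underlies every
# trainable component.  Each case builds a scalar loss from one parameter
# matrix and compares the tape gradient against central differences.

tp <- function(nm) getFromNamespace(nm, "triCPI")

test_that("core tape operations backpropagate correctly", {
  set.seed(1)
  X <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  t15 <- rnorm(15); t9 <- rnorm(9); t6 <- rnorm(6)

  expectGradMatches(function(tape, p) {
    o <- tp("tpMM")(tape, p, B)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 15, 1), t15)
  }, X)

  expectGradMatches(function(tape, p) {
    o <- tp("tpMM")(tape, X, p)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 15, 1), t15)
  }, B)

  X3 <- matrix(rnorm(9), 3, 3)
  S <- Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(2, 3, 1, 3), x = 1,
                            dims = c(3, 3))
  expectGradMatches(function(tape, p) {
    o <- tp("tpAdd")(tape, p, tp("tpSpMM")(tape, S, p))
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 9, 1), t9)
  }, X3)

  expectGradMatches(function(tape, p) {
    o <- tp("tpAddBias")(tape, X3, p)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 9, 1), t9)
  }, matrix(rnorm(3), 1, 3))

  expectGradMatches(function(tape, p) {
    o <- tp("tpScaleRows")(tape, X3, p)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 9, 1), t9)
  }, matrix(rnorm(3), ncol = 1))

  for (fn in c("tpSigmoid", "tpTanh", "tpRelu", "tpOneMinus")) {
    expectGradMatches(function(tape, p) {
      tp("tpMSE")(tape, tp("tpReshape")(tape, tp(fn)(tape, p), 9, 1), t9)
    }, X3)
  }

  expectGradMatches(function(tape, p) {
    o <- tp("tpRows")(tape, p, c(2, 2, 1, 3, 3))
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 15, 1), t15)
  }, X3)

  expectGradMatches(function(tape, p) {
    o <- tp("tpCols")(tape, p, c(3, 1))
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 6, 1), t6)
  }, X3)
})

test_that("attention, pooling and loss operations backpropagate correctly", {
  set.seed(2)
  t9 <- rnorm(9); t5 <- rnorm(5); t6 <- rnorm(6); t4 <- rnorm(4)
  X3 <- matrix(rnorm(9), 3, 3)
  msk <- matrix(c(1, 1, 0, 1, 1, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  expectGradMatches(function(tape, p) {
    o <- tp("tpMaskedSoftmaxRows")(tape, p, msk)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 9, 1), t9)
  }, X3)

  grp <- c(1, 1, 2, 2, 2)
  expectGradMatches(function(tape, p) {
    tp("tpMSE")(tape, tp("tpGroupSoftmax")(tape, p, grp), t5)
  }, matrix(rnorm(5), ncol = 1))

  X5 <- matrix(rnorm(15), 5, 3)
  expectGradMatches(function(tape, p) {
    o <- tp("tpGroupSum")(tape, p, grp, 2)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 6, 1), t6)
  }, X5)

  Xp <- matrix(rnorm(12), 6, 2)
  valid <- c(1, 1, 1, 1, 1, 0)
  expectGradMatches(function(tape, p) {
    o <- tp("tpMaxPoolTime")(tape, p, 2, 3, valid)
    tp("tpMSE")(tape, tp("tpReshape")(tape, o, 4, 1), t4)
  }, Xp)

  L <- matrix(rnorm(20), 4, 5)
  expectGradMatches(function(tape, p) {
    tp("tpCrossEntropy")(tape, p, c(2L, 5L, 1L, 3L), c(1, 1, 0, 1))
  }, L)
})

test_that("a full GRU step backpropagates through every gate", {
  set.seed(3)
  h <- 4L
  x0 <- matrix(rnorm(2 * 3), 2, 3)
  g <- triCPI:::.gruInit(3L, h)
  t8 <- rnorm(8)
  hPrev <- matrix(rnorm(2 * h), 2, h)
  # gradient wrt the input
  expectGradMatches(function(tape, p) {
    pn <- lapply(g, function(m) m)
    out <- triCPI:::.gruStep(tape, p, hPrev, pn, h, m = c(1, 0))
    tp("tpMSE")(tape, tp("tpReshape")(tape, out, 8, 1), t8)
  }, x0)
  # gradient wrt the recurrent weights
  expectGradMatches(function(tape, p) {
    pn <- list(W = g$W, U = p, bi = g$bi, bh = g$bh)
    out <- triCPI:::.gruStep(tape, x0, hPrev, pn, h)
    tp("tpMSE")(tape, tp("tpReshape")(tape, out, 8, 1), t8)
  }, g$U)
})

test_that("one optimization step lowers the batch loss at small rates", {
  # end-to-end differentiability of the unified forward pass
  ds <- tinyDataset(nPairs = 8, seed = 13)
  cfg <- tinyConfig()
  model <- initCPIModel(cfg, seed = 2)
  prep <- triCPI:::.prepareSamples(samples(ds), model)
  lossAt <- function(params) {
    tape <- triCPI:::tpTape()
    pred <- triCPI:::.unifiedForward(tape, params, prep, 1:8, cfg,
                                     training = FALSE)
    triCPI:::tpVal(triCPI:::tpMSE(tape, pred, prep$label[1:8]))
  }
  tape <- triCPI:::tpTape()
  pnodes <- triCPI:::.wrapParams(tape, model@params)
  pred <- triCPI:::.unifiedForward(tape, pnodes, prep, 1:8, cfg,
                                   training = FALSE)
  loss <- triCPI:::tpMSE(tape, pred, prep$label[1:8])
  triCPI:::tpBackward(tape, loss)
  grads <- triCPI:::.collectGrads(pnodes)
  l0 <- triCPI:::tpVal(loss)
  for (lr in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    stepped <- Map(function(p, g) p - lr * g, model@params, grads)
    if (lr <= 1e-3) expect_lt(lossAt(stepped), l0)
  }
})
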