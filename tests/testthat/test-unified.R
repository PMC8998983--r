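# Unit tests of the unified regressor on deliberately tiny configurations;
# the full-size overfit and generalization runs live in the acceptance suite.

test_that("attendSequence normalizes weights over live positions", {
  ap <- initAttentionParams(5, seed = 1)
  x1 <- matrix(rnorm(5), 1, 5)
  at <- attendSequence(x1, ap)
  expect_equal(at$weights, 1)
  same <- matrix(rep(rnorm(5), each = 6), 6, 5)
  expect_equal(attendSequence(same, ap)$weights, rep(1 / 6, 6))
  for (seed in 1:100) {
    set.seed(seed)
    x <- matrix(rnorm(7 * 5), 7, 5)
    mask <- c(rep(1, 5), 0, 0)
    at <- attendSequence(x, ap, mask)
    expect_equal(sum(at$weights), 1)
    expect_true(all(at$weights >= 0))
    expect_equal(at$weights[6:7], c(0, 0))
  }
  expect_error(attendSequence(matrix(rnorm(10), 2, 5), ap, mask = c(0, 0)),
               "all-pad")
})

test_that("conv1dExtract matches a nested-loop oracle and ignores pads", {
  convOracle <- function(x, K, b, len) {
    k <- length(K); f <- ncol(K[[1]])
    best <- rep(-Inf, f)
    for (t in seq_len(len - k + 1)) {
      acc <- as.numeric(b)
      for (j in seq_len(k)) {
        for (ff in seq_len(f)) {
          acc[ff] <- acc[ff] + sum(x[t + j - 1, ] * K[[j]][, ff])
        }
      }
      best <- pmax(best, pmax(acc, 0))
    }
    best
  }
  set.seed(2)
  for (case in 1:20) {
    p <- initConvParams(4, filters = 3, kernel = 2, seed = case)
    x <- matrix(rnorm(40), 10, 4)
    expect_equal(conv1dExtract(x, p), convOracle(x, p$K, p$b, 10),
                 tolerance = 1e-10)
  }
  # constant input with a single averaging kernel returns the constant
  x <- matrix(1.7, 8, 2)
  p <- list(K = list(matrix(c(0.5, 0), 2, 1), matrix(c(0.5, 0), 2, 1)),
            b = matrix(0, 1, 1))
  expect_equal(conv1dExtract(x, p), 1.7)
  # appending pad rows beyond validLength changes nothing
  p2 <- initConvParams(4, filters = 3, kernel = 2, seed = 5)
  x <- matrix(rnorm(24), 6, 4)
  xpad <- rbind(x, matrix(9, 4, 4))
  expect_equal(conv1dExtract(xpad, p2, validLength = 6),
               conv1dExtract(x, p2))
  expect_error(conv1dExtract(x[1, , drop = FALSE], p2), "shorter than kernel")
})

test_that("fuseCompound concatenates sequence part first", {
  expect_equal(fuseCompound(c(a = 1, b = 2), c(g = 3)), c(a = 1, b = 2, g = 3))
  expect_length(fuseCompound(rnorm(64), rnorm(128)), 192)
  expect_equal(fuseCompound(graphVec = 1:3), 1:3)   # degenerate fusion
  expect_error(fuseCompound(), "at least one")
})

test_that("channel configurations are validated", {
  expect_error(channelConfig(channels = c("sps")), "compound channel")
  expect_error(channelConfig(channels = c("smiles", "graph")),
               "protein channel")
  cfg <- channelConfig(channels = c("sps", "graph"))
  expect_setequal(cfg$channels, c("sps", "graph"))
})

test_that("forward pass is deterministic in eval mode and finite under fuzz", {
  ds <- tinyDataset(nPairs = 40, noiseSd = 0.5, seed = 23)
  model <- initCPIModel(tinyConfig(), seed = 3)
  p1 <- predictAffinity(model, ds)
  p2 <- predictAffinity(model, ds)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_length(p1, 40)
})

test_that("missing channel data raises an error naming the channel", {
  ds <- tinyDataset(nPairs = 6, seed = 24)
  df <- samples(ds)
  df$amino <- NULL
  model4 <- initCPIModel(tinyConfig(channels = c("smiles", "sps", "graph",
                                                 "amino")), seed = 5)
  expect_error(predictAffinity(model4, df), "amino")
})

test_that("ablations train and evaluate without code changes", {
  ds <- tinyDataset(nPairs = 16, noiseSd = 0, seed = 25)
  for (channels in list(c("sps", "graph"), c("smiles", "sps", "graph"))) {
    m <- trainUnified(ds, config = tinyConfig(channels = channels),
                      epochs = 2, lr = 1e-3, batchSize = 8, seed = 6)
    expect_equal(nrow(trainingHistory(m)), 2)
    expect_true(all(is.finite(predictAffinity(m, ds))))
  }
})

test_that("training is seeded, tracks history and uses best-val params", {
  ds <- tinyDataset(nPairs = 30, noiseSd = 0.2, seed = 26)
  parts <- splitDataset(ds, 0.2, seed = 1)
  m1 <- trainUnified(parts$train, parts$val, config = tinyConfig(),
                     epochs = 3, lr = 1e-3, batchSize = 12, seed = 7)
  m2 <- trainUnified(parts$train, parts$val, config = tinyConfig(),
                     epochs = 3, lr = 1e-3, batchSize = 12, seed = 7)
  expect_identical(m1@params, m2@params)
  h <- trainingHistory(m1)
  expect_equal(nrow(h), 3)
  expect_true(all(is.finite(h$val_loss)))
  # returned parameters reproduce the best recorded validation loss
  best <- min(h$val_loss)
  got <- mean((predictAffinity(m1, parts$val) - samples(parts$val)$label)^2)
  expect_equal(got, best, tolerance = 1e-9)
  expect_error(trainUnified(newCPIDataset(samples(ds)[0, ])), "empty")
})

test_that("warm starts copy pretrained encoder parameters into the model", {
  corpus <- tinySmilesCorpus(6)
  ae <- pretrainAutoencoder(corpus, "smiles", dim = 12, epochs = 1,
                            batchSize = 3, seed = 8)
  cfg <- tinyConfig()
  m <- initCPIModel(cfg, warm = list(smiles = ae), seed = 9)
  expect_identical(m@params[["smiles.E"]], ae@params[["enc.E"]])
  expect_identical(m@params[["smiles.gru2.U"]], ae@params[["enc.gru2.U"]])
  # dimension mismatches are refused
  ae24 <- pretrainAutoencoder(corpus, "smiles", dim = 24, epochs = 0)
  expect_error(initCPIModel(cfg, warm = list(smiles = ae24)), "mismatch")
})

test_that("the four-channel variant with an amino channel trains", {
  ds <- tinyDataset(nPairs = 12, seed = 27)
  cfg <- tinyConfig(channels = c("smiles", "sps", "graph", "amino"))
  m <- trainUnified(ds, config = cfg, epochs = 2, lr = 1e-3, batchSize = 6,
                    seed = 10)
  expect_true(all(is.finite(predictAffinity(m, ds))))
  # bidirectional channel carries separate reverse-direction parameters
  expect_true("amino.rev.gru1.W" %in% names(m@params))
})
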