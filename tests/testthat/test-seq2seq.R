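# Unit tests of the seq2seq autoencoder use deliberately small dimensions and
# corpora; the full-size overfit run lives in the acceptance suite.

test_that("thought vectors have the channel dimension for any length", {
  v <- smilesVocabulary()
  ae <- triCPI:::.s2sInit(v, dim = 16, maxLength = 60, seed = 1)
  for (s in c("C", "CCO", paste(rep("C", 50), collapse = ""))) {
    tv <- thoughtVectors(ae, s)
    expect_equal(dim(tv), c(1, 16))
    expect_true(all(is.finite(tv)))
  }
})

test_that("default channel dimensions are 128 for compounds, 256 for proteins", {
  expect_equal(triCPI:::.KIND_DIM[["smiles"]], 128L)
  expect_equal(triCPI:::.KIND_DIM[["sps"]], 256L)
  ae <- pretrainAutoencoder(tinySmilesCorpus(4), "smiles", epochs = 0)
  expect_equal(ae@config$dim, 128L)
  expect_equal(dim(ae@params[["enc.E"]]), c(68L, 128L))
})

test_that("padding amount does not change the thought vector", {
  v <- smilesVocabulary()
  ae <- triCPI:::.s2sInit(v, dim = 12, maxLength = 40, seed = 2)
  short <- triCPI:::.tokenizeMatrix(c("CCO", "CCN"), v, maxLength = 8)
  long <- triCPI:::.tokenizeMatrix(c("CCO", "CCN"), v, maxLength = 40)
  t1 <- thoughtVectors(ae, short)
  t2 <- thoughtVectors(ae, long)
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("decoder scores are masked row-normalized distributions", {
  v <- smilesVocabulary()
  ae <- triCPI:::.s2sInit(v, dim = 12, maxLength = 20, seed = 3)
  dec <- decodeScores(ae, c("CCO", "C"))
  sums <- apply(dec$scores, c(1, 2), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  # pad positions carry zero weight: sequence "C" has 2 live targets (C, end)
  expect_equal(sum(dec$weights[2, ]), 2)
  expect_equal(sum(dec$weights[1, ]), 4)
})

test_that("untrained accuracy sits at chance level for the vocabulary", {
  set.seed(4)
  v <- smilesVocabulary()
  ae <- triCPI:::.s2sInit(v, dim = 24, maxLength = 40, seed = 11)
  corpus <- tinySmilesCorpus(60, seed = 12, maxChars = 30)
  acc <- reconstructionAccuracy(ae, corpus)
  # untrained argmax over 68 classes: near 1/68, allow generous binomial slack
  expect_lt(acc, 0.15)
  expect_error(reconstructionAccuracy(ae, character(0)), "empty corpus")
})

test_that("a single sequence is memorized exactly", {
  ae <- pretrainAutoencoder("CC(N)CO", "smiles", dim = 24, epochs = 100,
                            batchSize = 1, lr = 0.01, dropout = 0, seed = 5)
  expect_equal(reconstructionAccuracy(ae, "CC(N)CO"), 1.0)
  # greedy teacher-forced decode reproduces the input tokens
  dec <- decodeScores(ae, "CC(N)CO")
  pred <- apply(dec$scores[1, , ], 1, which.max)
  live <- dec$weights[1, ] > 0
  expect_identical(pred[live], as.integer(dec$targets[1, live]))
})

test_that("pretraining is seeded and loss decreases on a small corpus", {
  corpus <- tinySmilesCorpus(12, seed = 6)
  a <- pretrainAutoencoder(corpus, "smiles", dim = 12, epochs = 8,
                           batchSize = 6, lr = 0.005, seed = 7)
  b <- pretrainAutoencoder(corpus, "smiles", dim = 12, epochs = 8,
                           batchSize = 6, lr = 0.005, seed = 7)
  expect_identical(trainingHistory(a)$loss, trainingHistory(b)$loss)
  expect_identical(a@params, b@params)
  h <- trainingHistory(a)
  expect_lt(h$loss[8], h$loss[1])
  expect_equal(nrow(h), 8)
  expect_error(pretrainAutoencoder(character(0), "smiles"), "empty corpus")
})

test_that("the SPS channel pretrains on encoded proteins", {
  prots <- genProteins(6, seed = 8)
  corpus <- vapply(prots, function(ann) {
    paste(spsWords(encodeSPS(ann)), collapse = " ")
  }, "")
  ae <- pretrainAutoencoder(corpus, "sps", dim = 12, epochs = 3,
                            batchSize = 3, seed = 9)
  expect_equal(ae@kind, "sps")
  expect_equal(nrow(trainingHistory(ae)), 3)
  expect_true(all(is.finite(thoughtVectors(ae, corpus))))
})
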