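test_that("small molecules parse to the expected graphs", {
  g <- parseSmiles("CC")
  expect_equal(atomCount(g), 2)
  expect_equal(nrow(g@edges), 1)
  expect_equal(g@degrees, c(1L, 1L))

  g <- parseSmiles("C1CC1")
  expect_equal(atomCount(g), 3)
  expect_equal(nrow(g@edges), 3)
  expect_equal(g@degrees, rep(2L, 3))
  expect_true(all(g@features[, "ring"] == 1))

  g <- parseSmiles("c1ccccc1")
  expect_equal(atomCount(g), 6)
  expect_equal(nrow(g@edges), 6)
  expect_equal(g@degrees, rep(2L, 6))

  g <- parseSmiles("CCO")
  expect_equal(g@elements, c("C", "C", "O"))
  expect_true(all(g@features[, "ring"] == 0))

  err <- tryCatch(parseSmiles("C1CC"), error = function(e) conditionMessage(e))
  expect_match(err, "C1CC")                     # error carries the string
})

test_that("identity weights and linear activation reduce to neighbor sums", {
  # single isolated atom: output equals the projected input
  g1 <- triCPI:::.newMolecularGraph("C", "C", matrix(integer(0), ncol = 2))
  d <- ncol(g1@features)
  w <- initGraphConvWeights(d, d, radius = 1, activation = "identity", seed = 1)
  w@Win <- diag(d); w@bin <- matrix(0, 1, d)
  for (n in 1:5) w@H[[1]][[n]] <- diag(d)
  expect_equal(graphConvForward(g1, w), g1@features, ignore_attr = TRUE)

  # path A-B-C, R = 1: center atom state = sum of all three inputs
  g <- parseSmiles("CCO")
  out <- graphConvForward(g, w)
  expect_equal(out[2, ], colSums(g@features), ignore_attr = TRUE)
  expect_equal(out[1, ], g@features[1, ] + g@features[2, ],
               ignore_attr = TRUE)
})

test_that("graph convolution matches the nested-loop oracle on random cases", {
  smallMols <- c("C", "CC", "CCO", "C1CC1", "CC(N)O", "C1CCC1", "OCC(C)N",
                 "C1CCCC1", "N#Cc1ccccc1"[1])
  set.seed(20)
  for (case in 1:50) {
    g <- parseSmiles(sample(smallMols, 1))
    w <- initGraphConvWeights(ncol(g@features), sample(4:10, 1),
                              radius = sample(1:3, 1), seed = 1000 + case)
    got <- graphConvForward(g, w)
    ref <- referenceGraphConv(g, w)
    expect_lt(max(abs(got - ref)) / max(1e-9, max(abs(ref))), 1e-5)
  }
})

test_that("atom relabeling permutes states and leaves the pooled vector alone", {
  set.seed(77)
  mols <- genCompounds(20, seed = 8)
  for (s in mols) {
    g <- parseSmiles(s)
    w <- initGraphConvWeights(ncol(g@features), 8, seed = 3)
    ap <- initAttentionParams(8, seed = 4)
    out <- graphConvForward(g, w)
    pooled <- attentionPool(out, ap)
    perm <- sample(atomCount(g))
    gp <- relabelGraph(g, perm)
    outP <- graphConvForward(gp, w)
    expect_equal(outP, out[perm, , drop = FALSE], tolerance = 1e-10,
                 ignore_attr = TRUE)
    pooledP <- attentionPool(outP, ap)
    expect_equal(as.numeric(pooledP), as.numeric(pooled), tolerance = 1e-10)
  }
})

test_that("with R layers information travels at most R bonds", {
  g <- parseSmiles("CCCCCCCC")          # 8-atom path
  w <- initGraphConvWeights(ncol(g@features), 6, radius = 3, seed = 5)
  base <- graphConvForward(g, w)
  g2 <- g
  g2@features[8, "charge"] <- 5         # perturb the far end
  out <- graphConvForward(g2, w)
  expect_equal(out[1:4, ], base[1:4, ], tolerance = 1e-12,
               ignore_attr = TRUE)      # atoms > 3 bonds away unchanged
  expect_false(isTRUE(all.equal(out[8, ], base[8, ])))
})

test_that("degree clamping uses the fifth filter beyond five neighbors", {
  # star with 6 leaves around a center atom
  edges <- cbind(rep(1L, 6), 2:7)
  g <- triCPI:::.newMolecularGraph("synthetic-star", rep("C", 7), edges)
  w <- initGraphConvWeights(ncol(g@features), 5, radius = 1, seed = 6)
  ref <- referenceGraphConv(g, w)       # oracle clamps identically
  expect_equal(graphConvForward(g, w), ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("in-place mode differs from synchronous on ordered graphs", {
  g <- parseSmiles("CCO")
  w <- initGraphConvWeights(ncol(g@features), 6, seed = 7)
  sync <- graphConvForward(g, w)
  inplace <- graphConvForward(g, w, mode = "inplace")
  expect_false(isTRUE(all.equal(sync, inplace)))
})

test_that("attention pooling satisfies its boundary contracts", {
  ap <- initAttentionParams(6, seed = 9)
  x <- matrix(rnorm(6), 1, 6)
  expect_equal(as.numeric(attentionPool(x, ap)), as.numeric(x))
  same <- matrix(rep(rnorm(6), each = 4), 4, 6)
  pooled <- attentionPool(same, ap)
  expect_equal(attr(pooled, "weights"), rep(0.25, 4))
  expect_error(attentionPool(matrix(nrow = 0, ncol = 6), ap), "empty")
})
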