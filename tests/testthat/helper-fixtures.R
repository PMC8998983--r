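# Shared fixtures: tiny seeded corpora and a finite-difference gradient
# checker for the autodiff tape.  Everything is generated in code; no files.

tinySmilesCorpus <- function(n = 20, seed = 3, maxChars = 20) {
  pool <- genCompounds(5 * n, seed = seed)
  head(pool[nchar(pool) <= maxChars], n)
}

tinyDataset <- function(nPairs = 24, noiseSd = 0, seed = 5) {
  genDataset(synthConfig(nCompounds = 12L, nProteins = 6L,
                         nPairs = as.integer(nPairs),
                         noiseSd = noiseSd, seed = seed))
}

# Small channel configuration so unit tests of the unified model stay fast.
tinyConfig <- function(channels = c("smiles", "sps", "graph"), ...) {
  channelConfig(channels = channels,
                dims = list(smiles = 12L, sps = 12L, amino = 12L, graph = 12L),
                convFilters = 8L, kernel = 3L, headHidden = 16L, ...)
}

numericGradient <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Builds the loss twice: once for the analytic gradient via the tape, and
# repeatedly for central differences.  `build(tape, paramNode)` must return
# a scalar loss node and be deterministic.
expectGradMatches <- function(build, x0, tol = 1e-5) {
  f <- function(x) {
    tape <- triCPI:::tpTape()
    p <- triCPI:::tpParam(tape, x)
    triCPI:::tpVal(build(tape, p))
  }
  tape <- triCPI:::tpTape()
  p <- triCPI:::tpParam(tape, x0)
  out <- build(tape, p)
  triCPI:::tpBackward(tape, out)
  ng <- numericGradient(f, x0)
  scale <- max(1e-8, max(abs(ng)))
  expect_lt(max(abs(p$g - ng)) / scale, tol)
}

# Independent nested-loop reference for the degree-filtered graph
# convolution (synchronous reading: all atoms update from the previous
# layer's states).
referenceGraphConv <- function(g, w) {
  r <- sweep(g@features %*% w@Win, 2, as.numeric(w@bin), "+")
  act <- switch(w@activation, relu = function(x) pmax(x, 0), tanh = tanh,
                identity = identity)
  for (L in seq_len(w@radius)) {
    rNew <- r
    for (a in seq_len(atomCount(g))) {
      v <- r[a, ]
      for (u in g@adjacency[[a]]) v <- v + r[u, ]
      bucket <- min(max(length(g@adjacency[[a]]), 1L), 5L)
      rNew[a, ] <- act(as.numeric(v %*% w@H[[L]][[bucket]]))
    }
    r <- rNew
  }
  r
}

relabelGraph <- function(g, perm) {
  inv <- order(perm)   # inv[old] = new position
  edges <- g@edges
  if (nrow(edges)) edges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
  triCPI:::.newMolecularGraph(g@smiles, g@elements[perm], edges,
                              g@features[perm, "charge"])
}

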