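# Reverse-mode automatic differentiation over dense/sparse matrices.
#
# A Tape records each forward operation as a node (an environment holding the
# value, the parent nodes and a backward closure).  tpBackward() then sweeps
# the tape in reverse creation order, accumulating gradients into every node.
# Constants enter operations as plain matrices/vectors and are never recorded;
# learnable parameters are wrapped once per forward pass with tpParam() so
# their gradients can be read off after the backward sweep.
#
# The op set is the minimum needed for the models in this package: dense and
# sparse matmul, broadcast bias, elementwise arithmetic and nonlinearities,
# row/column gathers (embedding lookups, time-step slicing of stacked
# sequences), grouped softmax/sum/max-pooling (attention over atoms of a
# molecule or positions of a padded sequence), dropout, and fused softmax
# cross-entropy / MSE losses.

tpTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 1024L)
  tape$n <- 0L
  tape
}

tpIsNode <- function(x) is.environment(x)

tpVal <- function(x) if (is.environment(x)) x$v else x

.tpPush <- function(tape, value, parents = NULL, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- value
  node$g <- NULL
  node$parents <- parents
  node$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# Leaf node for a learnable parameter; gradient readable from $g afterwards.
tpParam <- function(tape, value) .tpPush(tape, value)

# Seed the output node and sweep the tape backwards, accumulating gradients.
tpBackward <- function(tape, node, seed = 1) {
  node$g <- seed
  for (id in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[id]]
    if (is.null(nd$g) || is.null(nd$backward)) next
    gs <- nd$backward(nd$g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!tpIsNode(p) || is.null(gs[[k]])) next
      p$g <- if (is.null(p$g)) gs[[k]] else p$g + gs[[k]]
    }
  }
  invisible(NULL)
}

.tpParents <- function(...) list(...)

tpMM <- function(tape, a, b) {
  va <- tpVal(a); vb <- tpVal(b)
  .tpPush(tape, va %*% vb, .tpParents(a, b), function(g) {
    list(
      if (tpIsNode(a)) g %*% t(vb) else NULL,
      if (tpIsNode(b)) crossprod(va, g) else NULL
    )
  })
}

# S is a constant sparse (or dense) matrix; a is a node.  value = S %*% a.
tpSpMM <- function(tape, S, a) {
  va <- tpVal(a)
  .tpPush(tape, as.matrix(S %*% va), .tpParents(a), function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

tpAdd <- function(tape, a, b) {
  .tpPush(tape, tpVal(a) + tpVal(b), .tpParents(a, b), function(g) {
    list(if (tpIsNode(a)) g else NULL, if (tpIsNode(b)) g else NULL)
  })
}

tpSub <- function(tape, a, b) {
  .tpPush(tape, tpVal(a) - tpVal(b), .tpParents(a, b), function(g) {
    list(if (tpIsNode(a)) g else NULL, if (tpIsNode(b)) -g else NULL)
  })
}

tpMul <- function(tape, a, b) {
  va <- tpVal(a); vb <- tpVal(b)
  .tpPush(tape, va * vb, .tpParents(a, b), function(g) {
    list(if (tpIsNode(a)) g * vb else NULL, if (tpIsNode(b)) g * va else NULL)
  })
}

tpScalarMul <- function(tape, a, k) {
  .tpPush(tape, tpVal(a) * k, .tpParents(a), function(g) list(g * k))
}

tpOneMinus <- function(tape, a) {
  .tpPush(tape, 1 - tpVal(a), .tpParents(a), function(g) list(-g))
}

# Add a length-k bias vector to every row of an n x k matrix.
tpAddBias <- function(tape, a, b) {
  va <- tpVal(a); vb <- as.numeric(tpVal(b))
  .tpPush(tape, va + rep(vb, each = nrow(va)), .tpParents(a, b), function(g) {
    list(
      if (tpIsNode(a)) g else NULL,
      if (tpIsNode(b)) matrix(colSums(g), nrow = 1) else NULL
    )
  })
}

# Multiply each row i of a by scalar s[i]; s may be a node (n x 1) or numeric.
tpScaleRows <- function(tape, a, s) {
  va <- tpVal(a); vs <- as.numeric(tpVal(s))
  .tpPush(tape, va * vs, .tpParents(a, s), function(g) {
    list(
      if (tpIsNode(a)) g * vs else NULL,
      if (tpIsNode(s)) matrix(rowSums(g * va), ncol = 1) else NULL
    )
  })
}

tpSigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-tpVal(a)))
  .tpPush(tape, y, .tpParents(a), function(g) list(g * y * (1 - y)))
}

tpTanh <- function(tape, a) {
  y <- tanh(tpVal(a))
  .tpPush(tape, y, .tpParents(a), function(g) list(g * (1 - y * y)))
}

tpRelu <- function(tape, a) {
  va <- tpVal(a)
  y <- pmax(va, 0)
  .tpPush(tape, y, .tpParents(a), function(g) list(g * (va > 0)))
}

tpCols <- function(tape, a, idx) {
  va <- tpVal(a)
  .tpPush(tape, va[, idx, drop = FALSE], .tpParents(a), function(g) {
    ga <- matrix(0, nrow(va), ncol(va))
    ga[, idx] <- g
    list(ga)
  })
}

# Gather rows (embedding lookup / time-step selection); idx may repeat.
tpRows <- function(tape, a, idx) {
  va <- tpVal(a)
  .tpPush(tape, va[idx, , drop = FALSE], .tpParents(a), function(g) {
    ga <- matrix(0, nrow(va), ncol(va))
    agg <- rowsum(g, group = idx, reorder = FALSE)
    ga[as.integer(rownames(agg)), ] <- agg
    list(ga)
  })
}

tpRbind <- function(tape, parts) {
  vals <- lapply(parts, tpVal)
  sizes <- vapply(vals, nrow, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  .tpPush(tape, do.call(rbind, vals), parts, function(g) {
    lapply(seq_along(parts), function(k) {
      if (tpIsNode(parts[[k]])) g[starts[k]:ends[k], , drop = FALSE] else NULL
    })
  })
}

tpConcatCols <- function(tape, parts) {
  vals <- lapply(parts, tpVal)
  sizes <- vapply(vals, ncol, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  .tpPush(tape, do.call(cbind, vals), parts, function(g) {
    lapply(seq_along(parts), function(k) {
      if (tpIsNode(parts[[k]])) g[, starts[k]:ends[k], drop = FALSE] else NULL
    })
  })
}

# Reinterpret an (n*m) x 1 column as an n x m matrix (column-major), or back.
tpReshape <- function(tape, a, nrow, ncol) {
  va <- tpVal(a)
  .tpPush(tape, matrix(as.numeric(va), nrow, ncol), .tpParents(a), function(g) {
    list(matrix(as.numeric(g), dim(va)[1], dim(va)[2]))
  })
}

# Row-wise softmax with a 0/1 mask; masked entries get probability 0.
tpMaskedSoftmaxRows <- function(tape, a, mask) {
  x <- tpVal(a)
  x[mask == 0] <- -Inf
  mx <- apply(x, 1, max)
  e <- exp(x - mx)
  e[mask == 0] <- 0
  p <- e / rowSums(e)
  .tpPush(tape, p, .tpParents(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# Softmax over a column vector within groups (e.g. atoms of each molecule).
tpGroupSoftmax <- function(tape, a, groups) {
  x <- as.numeric(tpVal(a))
  mx <- stats::ave(x, groups, FUN = max)
  e <- exp(x - mx)
  denom <- stats::ave(e, groups, FUN = sum)
  p <- e / denom
  .tpPush(tape, matrix(p, ncol = 1), .tpParents(a), function(g) {
    gv <- as.numeric(g)
    s <- stats::ave(gv * p, groups, FUN = sum)
    list(matrix(p * (gv - s), ncol = 1))
  })
}

# Sum rows by group; result row k is the sum over rows with groups == k.
tpGroupSum <- function(tape, a, groups, ngroups) {
  va <- tpVal(a)
  out <- rowsum(va, group = groups, reorder = TRUE)
  full <- matrix(0, ngroups, ncol(va))
  full[as.integer(rownames(out)), ] <- out
  .tpPush(tape, full, .tpParents(a), function(g) {
    list(g[groups, , drop = FALSE])
  })
}

# Global max pooling over time for a stacked sequence laid out t-major:
# row (t-1)*b + i holds sample i at position t.  valid is a 0/1 vector of
# length b*t marking positions that participate in the max.
tpMaxPoolTime <- function(tape, a, b, tlen, valid) {
  va <- tpVal(a)
  f <- ncol(va)
  best <- matrix(-Inf, b, f)
  arg <- matrix(0L, b, f)
  for (t in seq_len(tlen)) {
    rows <- (t - 1L) * b + seq_len(b)
    xt <- va[rows, , drop = FALSE]
    xt[valid[rows] == 0, ] <- -Inf
    upd <- xt > best
    best[upd] <- xt[upd]
    arg[upd] <- t
  }
  if (any(arg == 0L)) stop("max pooling over an empty set of valid positions")
  .tpPush(tape, best, .tpParents(a), function(g) {
    ga <- matrix(0, nrow(va), f)
    rows <- (arg - 1L) * b + row(arg)          # stacked row index per (i, f)
    flat <- as.numeric(rows) + (as.numeric(col(arg)) - 1) * nrow(va)
    ga[flat] <- ga[flat] + as.numeric(g)
    list(ga)
  })
}

# Fused GRU step (gates laid out [r | z | n] along the columns of W/U).
#   r = sig(x W1 + h U1 + b1);  z = sig(x W2 + h U2 + b2)
#   n = tanh(x W3 + b3i + r * (h U3 + b3h))
#   h' = (1 - z) n + z h,  masked per sample: out = m h' + (1 - m) h
# One tape node replaces the ~16 elementary ops of the unfused step.
tpGRUStep <- function(tape, x, h, W, U, bi, bh, hDim, m = NULL) {
  vx <- tpVal(x); vh <- tpVal(h)
  vW <- tpVal(W); vU <- tpVal(U)
  b <- nrow(vx)
  gi <- vx %*% vW + rep(as.numeric(tpVal(bi)), each = b)
  gh <- vh %*% vU + rep(as.numeric(tpVal(bh)), each = b)
  i1 <- seq_len(hDim); i2 <- hDim + i1; i3 <- 2L * hDim + i1
  r <- 1 / (1 + exp(-(gi[, i1, drop = FALSE] + gh[, i1, drop = FALSE])))
  z <- 1 / (1 + exp(-(gi[, i2, drop = FALSE] + gh[, i2, drop = FALSE])))
  gh3 <- gh[, i3, drop = FALSE]
  n <- tanh(gi[, i3, drop = FALSE] + r * gh3)
  hNew <- (1 - z) * n + z * vh
  useMask <- !is.null(m) && !all(m == 1)
  out <- if (useMask) hNew * m + vh * (1 - m) else hNew
  .tpPush(tape, out, .tpParents(x, h, W, U, bi, bh), function(g) {
    dhNew <- if (useMask) g * m else g
    dh <- if (useMask) g * (1 - m) else 0
    dz <- dhNew * (vh - n)
    dn <- dhNew * (1 - z)
    dh <- dh + dhNew * z
    dnp <- dn * (1 - n * n)
    dr <- dnp * gh3
    dgi <- cbind(dr * r * (1 - r), dz * z * (1 - z), dnp)
    dgh <- cbind(dgi[, i1, drop = FALSE], dgi[, i2, drop = FALSE], dnp * r)
    dh <- dh + dgh %*% t(vU)
    list(
      if (tpIsNode(x)) dgi %*% t(vW) else NULL,
      if (tpIsNode(h)) dh else NULL,
      if (tpIsNode(W)) crossprod(vx, dgi) else NULL,
      if (tpIsNode(U)) crossprod(vh, dgh) else NULL,
      if (tpIsNode(bi)) matrix(colSums(dgi), nrow = 1) else NULL,
      if (tpIsNode(bh)) matrix(colSums(dgh), nrow = 1) else NULL
    )
  })
}

# Inverted dropout; the mask is sampled from the session RNG at build time.
tpDropout <- function(tape, a, rate) {
  va <- tpVal(a)
  if (rate <= 0) return(a)
  keep <- 1 - rate
  m <- (matrix(stats::runif(length(va)), nrow(va), ncol(va)) < keep) / keep
  .tpPush(tape, va * m, .tpParents(a), function(g) list(g * m))
}

# Mean squared error between an n x 1 prediction node and a numeric target.
tpMSE <- function(tape, pred, target) {
  vp <- as.numeric(tpVal(pred))
  d <- vp - as.numeric(target)
  n <- length(d)
  .tpPush(tape, sum(d * d) / n, .tpParents(pred), function(g) {
    list(matrix(2 * d / n * as.numeric(g), ncol = 1))
  })
}

# Fused masked softmax cross-entropy.  logits: n x V node; target: integer
# class per row; weights: per-row nonnegative weight (0 masks the row out).
# Value is the weighted mean negative log-likelihood.
tpCrossEntropy <- function(tape, logits, target, weights) {
  x <- tpVal(logits)
  n <- nrow(x)
  mx <- apply(x, 1, max)
  e <- exp(x - mx)
  z <- rowSums(e)
  p <- e / z
  idx <- cbind(seq_len(n), target)
  wsum <- sum(weights)
  loss <- sum(weights * (log(z) + mx - x[idx])) / wsum
  .tpPush(tape, loss, .tpParents(logits), function(g) {
    gl <- p * (weights / wsum)
    gl[idx] <- gl[idx] - weights / wsum
    list(gl * as.numeric(g))
  })
}
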