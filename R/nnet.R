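# Internal neural building blocks shared by the autoencoder and the unified
# model: GRU layers, additive attention, 1D convolution with global max
# pooling, and the Adam optimizer.  All builders operate on the autodiff
# tape; parameters are kept in flat named lists of matrices so the optimizer
# and checkpointing stay trivial.

.initMat <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# One GRU layer's parameters; gates laid out [r | z | n] along columns.
.gruInit <- function(inputDim, hiddenDim) {
  sc <- 1 / sqrt(hiddenDim)
  list(W = .initMat(inputDim, 3L * hiddenDim, sc),
       U = .initMat(hiddenDim, 3L * hiddenDim, sc),
       bi = matrix(0, 1, 3L * hiddenDim),
       bh = matrix(0, 1, 3L * hiddenDim))
}

# Wrap a flat named parameter list onto the tape; returns a parallel list of
# nodes from which gradients are collected after the backward sweep.
.wrapParams <- function(tape, params) {
  lapply(params, function(p) tpParam(tape, p))
}

.collectGrads <- function(nodes) {
  lapply(nodes, function(nd) if (is.null(nd$g)) 0 * nd$v else nd$g)
}

# One GRU step.  x, h are b x in / b x h nodes (or constants); p holds node
# (or constant) parameters W, U, bi, bh.  m is the per-sample 0/1 step mask:
# masked samples carry their previous state through unchanged.
.gruStep <- function(tape, x, h, p, hDim, m = NULL) {
  tpGRUStep(tape, x, h, p$W, p$U, p$bi, p$bh, hDim, m)
}

# Run one GRU layer over a list of per-step input nodes.  masks[[t]] is the
# 0/1 vector of live samples at step t.  Returns the per-step hidden states
# and the final state (which, thanks to masking, is each sample's state at
# its own last live step).
.gruLayer <- function(tape, xs, p, hDim, masks, reverse = FALSE) {
  b <- nrow(tpVal(xs[[1]]))
  h <- matrix(0, b, hDim)
  steps <- if (reverse) rev(seq_along(xs)) else seq_along(xs)
  hs <- vector("list", length(xs))
  for (t in steps) {
    h <- .gruStep(tape, xs[[t]], h, p, hDim, masks[[t]])
    hs[[t]] <- h
  }
  list(hs = hs, final = h)
}

# Embed a b x L token matrix and run a stack of GRU layers (optionally
# bidirectional).  Per-step inputs to upper layers get inverted dropout when
# training.  Returns per-position top-layer outputs, the stacked
# (b*L) x dim output matrix (t-major), per-layer finals and the step masks.
.encoderTape <- function(tape, pnodes, prefix, tokens, nLayers, hDim,
                         dropout, training, bidirectional = FALSE) {
  b <- nrow(tokens); L <- ncol(tokens)
  E <- pnodes[[paste0(prefix, ".E")]]
  xs <- lapply(seq_len(L), function(t) tpRows(tape, E, tokens[, t]))
  masks <- lapply(seq_len(L), function(t) as.numeric(tokens[, t] != 3L))
  finals <- list()
  outs <- xs
  dirs <- if (bidirectional) c(FALSE, TRUE) else FALSE
  perDir <- vector("list", length(dirs))
  for (d in seq_along(dirs)) {
    ins <- xs
    for (l in seq_len(nLayers)) {
      if (l > 1L && training && dropout > 0) {
        ins <- lapply(ins, function(x) tpDropout(tape, x, dropout))
      }
      tag <- paste0(prefix, if (dirs[d]) ".rev" else "", ".gru", l)
      p <- list(W = pnodes[[paste0(tag, ".W")]], U = pnodes[[paste0(tag, ".U")]],
                bi = pnodes[[paste0(tag, ".bi")]], bh = pnodes[[paste0(tag, ".bh")]])
      run <- .gruLayer(tape, ins, p, hDim, masks, reverse = dirs[d])
      ins <- run$hs
      finals[[paste0(tag, ".final")]] <- run$final
    }
    perDir[[d]] <- ins
  }
  outs <- if (bidirectional) {
    Map(function(a, b2) tpConcatCols(tape, list(a, b2)), perDir[[1]], perDir[[2]])
  } else {
    perDir[[1]]
  }
  stack <- tpRbind(tape, outs)
  list(outs = outs, stack = stack, finals = finals, masks = masks, b = b, L = L)
}

# Additive attention weights over the positions of a stacked sequence
# (t-major (b*L) x d).  mask is the b x L 0/1 matrix of live positions.
# Returns list(alpha = b x L node, flat = (b*L) x 1 node).
.attnOverPositions <- function(tape, stack, Wa, ba, va, b, L, mask) {
  u <- tpTanh(tape, tpAddBias(tape, tpMM(tape, stack, Wa), ba))
  s <- tpMM(tape, u, va)
  alpha <- tpMaskedSoftmaxRows(tape, tpReshape(tape, s, b, L), mask)
  list(alpha = alpha, flat = tpReshape(tape, alpha, b * L, 1L))
}

# 1D convolution (kernel k, F filters) + ReLU + global max pooling over the
# positions whose whole window lies inside the live (non-pad) prefix.
# x is the stacked (b*L) x d sequence, lens the per-sample live length.
.convMaxPoolTape <- function(tape, x, Kmats, bias, b, L, k, lens) {
  P <- L - k + 1L
  if (P < 1L) stop("sequence shorter than kernel")
  if (any(lens < k)) stop("sequence shorter than kernel")
  conv <- NULL
  base <- as.vector(outer(seq_len(b), (seq_len(P) - 1L) * b, "+"))
  for (j in seq_len(k)) {
    xk <- tpMM(tape, x, Kmats[[j]])
    part <- tpRows(tape, xk, base + (j - 1L) * b)
    conv <- if (is.null(conv)) part else tpAdd(tape, conv, part)
  }
  conv <- tpRelu(tape, tpAddBias(tape, conv, bias))
  pos <- rep(seq_len(P), each = b)
  valid <- as.numeric(pos + k - 1L <= rep(lens, P))
  tpMaxPoolTime(tape, conv, b, P, valid)
}

# ---- Adam -------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L)
}

.globalClip <- function(grads, maxNorm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(nrm) && nrm > maxNorm) {
    grads <- lapply(grads, function(g) g * (maxNorm / nrm))
  }
  grads
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  grads <- .globalClip(grads, clip)
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

# Plain SGD with multiplicative per-epoch decay (the alternative published
# schedule: initial rate 0.5, decay 0.99 per epoch).
.sgdStep <- function(params, grads, lr, clip = 5) {
  grads <- .globalClip(grads, clip)
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}
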