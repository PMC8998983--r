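# The unified end-to-end regressor.  Three channels (four with the amino
# channel): GRU encoders over tokenized SMILES and SPS whose per-position
# outputs are attention-weighted and fed to a 1D convolution with global max
# pooling; a degree-filtered graph convolution with attention pooling over
# the 2D molecular graph; concatenative fusion (sequence part first) of the
# compound vectors, then of compound and protein vectors; and a fully
# connected head predicting the scalar affinity.  Trained with mean squared
# error on the log10(IC50) scale, optionally warm-started from pretrained
# autoencoders.

.COMPOUND_CHANNELS <- c("smiles", "graph")
.PROTEIN_CHANNELS <- c("sps", "amino")

#' Channel configuration of the unified model
#'
#' The default three channels (`smiles`, `sps`, `graph`) give the base model;
#' adding `"amino"` gives the extended variant with a bidirectional GRU over
#' the raw residue sequence.  Any subset with at least one compound channel
#' (smiles or graph) and one protein channel (sps or amino) is a valid
#' ablation and trains without code changes.
#'
#' @param channels character subset of smiles, sps, graph, amino.
#' @param dims named list of per-channel hidden dimensions.
#' @param convFilters number of 1D convolution filters per sequence channel.
#' @param kernel convolution kernel width.
#' @param headHidden hidden width of the fully connected head.
#' @param dropout dropout rate (stacked GRU inputs and head hidden layer).
#' @param graphRadius graph convolution radius R.
#' @param activation graph convolution nonlinearity.
#' @param maxLengths named list of per-channel sequence caps.
#' @return validated configuration list.
#' @export
channelConfig <- function(channels = c("smiles", "sps", "graph"),
                          dims = list(), convFilters = 64L, kernel = 4L,
                          headHidden = 512L, dropout = 0.2, graphRadius = 3L,
                          activation = "relu", maxLengths = list()) {
  channels <- match.arg(channels, c("smiles", "sps", "graph", "amino"),
                        several.ok = TRUE)
  if (!any(channels %in% .COMPOUND_CHANNELS)) {
    stop("at least one compound channel (smiles or graph) must be enabled")
  }
  if (!any(channels %in% .PROTEIN_CHANNELS)) {
    stop("at least one protein channel (sps or amino) must be enabled")
  }
  d <- list(smiles = 128L, sps = 256L, amino = 256L, graph = 128L)
  d[names(dims)] <- lapply(dims, as.integer)
  ml <- list(smiles = defaultMaxLength("smiles"), sps = defaultMaxLength("sps"),
             amino = defaultMaxLength("amino"))
  ml[names(maxLengths)] <- lapply(maxLengths, as.integer)
  list(channels = channels, dims = d, convFilters = as.integer(convFilters),
       kernel = as.integer(kernel), headHidden = as.integer(headHidden),
       dropout = dropout, graphRadius = as.integer(graphRadius),
       activation = activation, maxLengths = ml, layers = 2L,
       featureDim = length(.ELEMENT_PALETTE) + 4L)
}

.seqChannelInit <- function(p, prefix, V, d, cfg, bidirectional = FALSE) {
  p[[paste0(prefix, ".E")]] <- .initMat(V, d, 0.1)
  dirs <- if (bidirectional) c("", ".rev") else ""
  for (dir in dirs) {
    for (l in seq_len(cfg$layers)) {
      g <- .gruInit(d, d)
      for (nm in names(g)) {
        p[[paste0(prefix, dir, ".gru", l, ".", nm)]] <- g[[nm]]
      }
    }
  }
  outDim <- if (bidirectional) 2L * d else d
  sc <- 1 / sqrt(outDim)
  p[[paste0(prefix, ".att.Wa")]] <- .initMat(outDim, outDim, sc)
  p[[paste0(prefix, ".att.ba")]] <- matrix(0, 1, outDim)
  p[[paste0(prefix, ".att.va")]] <- .initMat(outDim, 1, sc)
  for (j in seq_len(cfg$kernel)) {
    p[[paste0(prefix, ".conv.K", j)]] <- .initMat(outDim, cfg$convFilters,
                                                  1 / sqrt(outDim * cfg$kernel))
  }
  p[[paste0(prefix, ".conv.b")]] <- matrix(0, 1, cfg$convFilters)
  p
}

.channelOutDim <- function(cfg, ch) {
  if (ch == "graph") cfg$dims$graph else cfg$convFilters
}

#' Initialize a unified compound-protein affinity model
#'
#' @param config a [channelConfig()] list.
#' @param vocabs named list of [Vocabulary] objects for the active sequence
#'   channels; defaults to the base vocabularies.
#' @param warm optional named list of pretrained [SeqAutoencoder]s
#'   (`smiles`, `sps`, `amino`) whose embedding and encoder parameters
#'   warm-start the corresponding channels (dimensions must match; the
#'   reverse direction of the bidirectional amino channel stays fresh).
#' @param seed RNG seed for the fresh parameters.
#' @return an untrained [CPIModel].
#' @export
initCPIModel <- function(config = channelConfig(), vocabs = NULL,
                         warm = NULL, seed = 1L) {
  set.seed(seed)
  cfg <- config
  if (is.null(vocabs)) vocabs <- list()
  defaults <- list(smiles = smilesVocabulary, sps = spsVocabulary,
                   amino = aminoVocabulary)
  for (ch in intersect(cfg$channels, names(defaults))) {
    if (is.null(vocabs[[ch]])) vocabs[[ch]] <- defaults[[ch]]()
  }
  p <- list()
  for (ch in intersect(cfg$channels, c("smiles", "sps", "amino"))) {
    p <- .seqChannelInit(p, ch, vocabSize(vocabs[[ch]]), cfg$dims[[ch]], cfg,
                         bidirectional = ch == "amino")
  }
  if ("graph" %in% cfg$channels) {
    gw <- initGraphConvWeights(cfg$featureDim, cfg$dims$graph,
                               cfg$graphRadius, cfg$activation,
                               seed = seed + 101L)
    p[["graph.Win"]] <- gw@Win
    p[["graph.bin"]] <- gw@bin
    for (L in seq_len(cfg$graphRadius)) {
      for (n in 1:5) p[[paste0("graph.H", L, ".", n)]] <- gw@H[[L]][[n]]
    }
    sc <- 1 / sqrt(cfg$dims$graph)
    p[["graph.att.Wa"]] <- .initMat(cfg$dims$graph, cfg$dims$graph, sc)
    p[["graph.att.ba"]] <- matrix(0, 1, cfg$dims$graph)
    p[["graph.att.va"]] <- .initMat(cfg$dims$graph, 1, sc)
  }
  inDim <- sum(vapply(cfg$channels, function(ch) .channelOutDim(cfg, ch), 1L))
  p[["head.W1"]] <- .initMat(inDim, cfg$headHidden, 1 / sqrt(inDim))
  p[["head.b1"]] <- matrix(0, 1, cfg$headHidden)
  p[["head.W2"]] <- .initMat(cfg$headHidden, 1L, 1 / sqrt(cfg$headHidden))
  p[["head.b2"]] <- matrix(0, 1, 1)
  if (!is.null(warm)) {
    for (ch in intersect(names(warm), cfg$channels)) {
      ae <- warm[[ch]]
      if (is.null(ae)) next
      stopifnot(is(ae, "SeqAutoencoder"))
      if (ae@config$dim != cfg$dims[[ch]]) {
        stop("warm-start dimension mismatch for channel ", ch)
      }
      p[[paste0(ch, ".E")]] <- ae@params[["enc.E"]]
      for (l in seq_len(cfg$layers)) {
        for (nm in c("W", "U", "bi", "bh")) {
          p[[paste0(ch, ".gru", l, ".", nm)]] <-
            ae@params[[paste0("enc.gru", l, ".", nm)]]
        }
      }
    }
  }
  new("CPIModel", config = cfg, vocabs = vocabs, params = p,
      history = data.frame())
}

# Tokenize/parse a sample table once per dataset.  Graphs are parsed per
# unique SMILES and cached; failures abort (training requires valid input).
.prepareSamples <- function(df, model) {
  cfg <- model@config
  out <- list(n = nrow(df), label = df$label)
  for (ch in intersect(cfg$channels, c("smiles", "sps", "amino"))) {
    col <- if (ch == "smiles") "smiles" else ch
    if (is.null(df[[col]]) || anyNA(df[[col]])) {
      stop("missing channel data: ", ch)
    }
    out[[paste0(ch, ".tokens")]] <-
      .asTokenMatrix(df[[col]], model@vocabs[[ch]], cfg$maxLengths[[ch]])
  }
  if ("graph" %in% cfg$channels) {
    if (is.null(df$smiles) || anyNA(df$smiles)) stop("missing channel data: graph")
    uniq <- unique(df$smiles)
    cache <- lapply(uniq, parseSmiles)
    names(cache) <- uniq
    out$graphs <- cache[df$smiles]
  }
  out
}

# Forward pass over a prepared batch; returns the b x 1 prediction node.
.unifiedForward <- function(tape, pnodes, prep, rows, cfg, training) {
  vecs <- list()
  for (ch in cfg$channels) {
    if (ch == "graph") {
      batch <- .graphBatch(prep$graphs[rows])
      H <- lapply(seq_len(cfg$graphRadius), function(L) {
        lapply(1:5, function(n) pnodes[[paste0("graph.H", L, ".", n)]])
      })
      atoms <- .graphConvTape(tape, batch, pnodes[["graph.Win"]],
                              pnodes[["graph.bin"]], H, cfg$graphRadius,
                              cfg$activation)
      vecs[[ch]] <- .attnPoolTape(tape, atoms, batch$mol, batch$nmol,
                                  pnodes[["graph.att.Wa"]],
                                  pnodes[["graph.att.ba"]],
                                  pnodes[["graph.att.va"]])
    } else {
      tokens <- prep[[paste0(ch, ".tokens")]][rows, , drop = FALSE]
      keep <- max(rowSums(tokens != 3L)) + 1L
      tokens <- tokens[, seq_len(min(ncol(tokens), keep + 1L)), drop = FALSE]
      d <- cfg$dims[[ch]]
      bidir <- ch == "amino"
      enc <- .encoderTape(tape, pnodes, ch, tokens, cfg$layers, d,
                          cfg$dropout, training, bidirectional = bidir)
      b <- enc$b; L <- enc$L
      maskMat <- matrix(as.numeric(tokens != 3L), b, L)
      at <- .attnOverPositions(tape, enc$stack, pnodes[[paste0(ch, ".att.Wa")]],
                               pnodes[[paste0(ch, ".att.ba")]],
                               pnodes[[paste0(ch, ".att.va")]], b, L, maskMat)
      weighted <- tpScaleRows(tape, enc$stack, at$flat)
      Kmats <- lapply(seq_len(cfg$kernel), function(j) {
        pnodes[[paste0(ch, ".conv.K", j)]]
      })
      vecs[[ch]] <- .convMaxPoolTape(tape, weighted, Kmats,
                                     pnodes[[paste0(ch, ".conv.b")]],
                                     b, L, cfg$kernel, rowSums(maskMat))
    }
  }
  # fusion: sequence part first within the compound vector, compound before
  # protein in the head input
  order <- c("smiles", "graph", "sps", "amino")
  parts <- vecs[intersect(order, names(vecs))]
  x <- if (length(parts) > 1L) tpConcatCols(tape, parts) else parts[[1]]
  h1 <- tpRelu(tape, tpAddBias(tape, tpMM(tape, x, pnodes[["head.W1"]]),
                               pnodes[["head.b1"]]))
  if (training && cfg$dropout > 0) h1 <- tpDropout(tape, h1, cfg$dropout)
  tpAddBias(tape, tpMM(tape, h1, pnodes[["head.W2"]]), pnodes[["head.b2"]])
}

.predictPrepared <- function(params, prep, cfg, batchSize = 256L) {
  out <- numeric(prep$n)
  for (start in seq(1L, prep$n, by = batchSize)) {
    rows <- start:min(start + batchSize - 1L, prep$n)
    tape <- tpTape()
    pred <- .unifiedForward(tape, params, prep, rows, cfg, training = FALSE)
    out[rows] <- as.numeric(tpVal(pred))
  }
  out
}

.asSampleFrame <- function(newdata) {
  if (is(newdata, "CPIDataset")) samples(newdata) else as.data.frame(newdata)
}

#' @describeIn predictAffinity CPIModel method.  Deterministic in evaluation
#'   mode: dropout is disabled and repeated calls return identical values.
#' @export
setMethod("predictAffinity", "CPIModel", function(object, newdata,
                                                  batchSize = 256) {
  df <- .asSampleFrame(newdata)
  if (nrow(df) == 0L) return(numeric(0))
  if (is.null(df$label)) df$label <- 0
  prep <- .prepareSamples(df, object)
  out <- numeric(nrow(df))
  for (start in seq(1L, nrow(df), by = batchSize)) {
    rows <- start:min(start + batchSize - 1L, nrow(df))
    tape <- tpTape()
    pred <- .unifiedForward(tape, object@params, prep, rows, object@config,
                            training = FALSE)
    out[rows] <- as.numeric(tpVal(pred))
  }
  out
})

#' Train the unified model end to end
#'
#' Minimizes the mean squared error of predicted vs. observed affinity with
#' Adam (published unified-stage learning rate 1e-4), optionally warm-started
#' from pretrained sequence autoencoders.  When a validation set is given,
#' the returned model carries the parameters of the best validation epoch;
#' otherwise the final parameters.
#'
#' @param train a [CPIDataset] (or sample data.frame) of training pairs.
#' @param val optional validation [CPIDataset]; may be NULL.
#' @param config a [channelConfig()].
#' @param warm optional named list of pretrained [SeqAutoencoder]s.
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate (default 1e-4).
#' @param batchSize minibatch size (default 64).
#' @param seed RNG seed; fixes initialization, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a trained [CPIModel]; `trainingHistory()` holds per-epoch train
#'   and validation loss (MSE).
#' @export
trainUnified <- function(train, val = NULL, config = channelConfig(),
                         warm = NULL, epochs = 100L, lr = 1e-4,
                         batchSize = 64L, seed = 1L, verbose = FALSE) {
  dfTrain <- .asSampleFrame(train)
  if (nrow(dfTrain) == 0L) stop("empty training set")
  model <- initCPIModel(config, warm = warm, seed = seed)
  prep <- .prepareSamples(dfTrain, model)
  prepVal <- NULL
  if (!is.null(val)) {
    dfVal <- .asSampleFrame(val)
    if (nrow(dfVal) > 0L) prepVal <- .prepareSamples(dfVal, model)
  }
  set.seed(seed + 1L)
  params <- model@params
  state <- .adamInit(params)
  n <- nrow(dfTrain)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  bestVal <- Inf
  bestParams <- params
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batchSize)) {
      rows <- ord[start:min(start + batchSize - 1L, n)]
      tape <- tpTape()
      pnodes <- .wrapParams(tape, params)
      pred <- .unifiedForward(tape, pnodes, prep, rows, model@config,
                              training = TRUE)
      loss <- tpMSE(tape, pred, prep$label[rows])
      tpBackward(tape, loss)
      upd <- .adamStep(params, .collectGrads(pnodes), state, lr)
      params <- upd$params; state <- upd$state
      tot <- tot + tpVal(loss) * length(rows)
    }
    valLoss <- NA_real_
    if (!is.null(prepVal)) {
      pv <- .predictPrepared(params, prepVal, model@config)
      valLoss <- mean((pv - prepVal$label)^2)
      if (valLoss < bestVal) {
        bestVal <- valLoss
        bestParams <- params
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / n,
                                   val_loss = valLoss))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %s", ep, tot / n,
                      ifelse(is.na(valLoss), "-", sprintf("%.4f", valLoss))))
    }
  }
  model@params <- if (!is.null(prepVal)) bestParams else params
  model@history <- hist
  model
}

#' @describeIn trainingHistory CPIModel method.
#' @export
setMethod("trainingHistory", "CPIModel", function(x) x@history)

setMethod("show", "CPIModel", function(object) {
  tr <- if (nrow(object@history)) {
    sprintf("trained %d epochs", max(object@history$epoch))
  } else "untrained"
  cat(sprintf("CPIModel: channels {%s}, %s\n",
              paste(object@config$channels, collapse = ", "), tr))
})

# ---- standalone channel operations ------------------------------------

#' Attention-weight the positions of an encoder output sequence
#'
#' Computes additive attention weights over the non-pad positions (weights
#' are nonnegative and sum to 1) and scales each position's vector by its
#' weight.  A single live position gets weight 1; identical position vectors
#' get uniform weights.
#'
#' @param outputs positions x dim numeric matrix of encoder outputs.
#' @param params attention parameters (`Wa`, `ba`, `va`), e.g. from
#'   [initAttentionParams()].
#' @param mask optional 0/1 vector marking live positions (default all).
#' @return list with `weights` (length positions; masked entries 0) and
#'   `weighted` (positions x dim matrix of scaled outputs).
#' @export
attendSequence <- function(outputs, params, mask = NULL) {
  outputs <- as.matrix(outputs)
  if (is.null(mask)) mask <- rep(1, nrow(outputs))
  if (sum(mask) < 1) stop("cannot attend over an all-pad sequence")
  u <- tanh(sweep(outputs %*% params$Wa, 2, as.numeric(params$ba), "+"))
  s <- as.numeric(u %*% params$va)
  s[mask == 0] <- -Inf
  a <- exp(s - max(s))
  a <- a / sum(a)
  list(weights = a, weighted = outputs * a)
}

#' 1D convolution + global max pooling over a weighted sequence
#'
#' Convolves the position dimension with `length(params$K)` kernel slices,
#' applies ReLU and takes the maximum over all positions whose window lies
#' within the first `validLength` positions, making the result independent of
#' the pad tail.
#'
#' @param x positions x dim numeric matrix (attention-weighted outputs).
#' @param params list with `K` (list of dim x filters matrices, one per
#'   kernel offset) and `b` (length-filters bias).
#' @param validLength number of live positions (default all rows).
#' @return numeric vector of length filters.
#' @export
conv1dExtract <- function(x, params, validLength = nrow(x)) {
  x <- as.matrix(x)
  k <- length(params$K)
  if (validLength < k) stop("sequence shorter than kernel")
  P <- validLength - k + 1L
  f <- ncol(params$K[[1]])
  conv <- matrix(0, P, f)
  for (t in seq_len(P)) {
    acc <- as.numeric(params$b)
    for (j in seq_len(k)) acc <- acc + as.numeric(x[t + j - 1L, ] %*% params$K[[j]])
    conv[t, ] <- pmax(acc, 0)
  }
  apply(conv, 2, max)
}

#' Initialize standalone 1D convolution parameters
#'
#' @param dim input dimension per position.
#' @param filters number of filters.
#' @param kernel kernel width.
#' @param seed RNG seed.
#' @return list with `K` (list of kernel slices) and `b`.
#' @export
initConvParams <- function(dim, filters = 64L, kernel = 4L, seed = 1L) {
  set.seed(seed)
  sc <- 1 / sqrt(dim * kernel)
  list(K = lapply(seq_len(kernel), function(j) .initMat(dim, filters, sc)),
       b = matrix(0, 1, filters))
}

#' Fuse the two compound representations
#'
#' Concatenates the sequence-derived compound vector and the graph-derived
#' vector (sequence part first).  Under ablation one of the two may be
#' absent, in which case the other is returned unchanged; both absent is an
#' error.
#'
#' @param seqVec sequence-channel compound vector, or NULL.
#' @param graphVec graph-channel compound vector, or NULL.
#' @return the fused numeric vector.
#' @export
fuseCompound <- function(seqVec = NULL, graphVec = NULL) {
  if (is.null(seqVec) && is.null(graphVec)) {
    stop("at least one compound representation is required")
  }
  c(seqVec, graphVec)
}
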