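# GRU seq2seq autoencoder pretraining.  The encoder (2-layer GRU) maps a
# token sequence to a fixed-dimension thought vector (final hidden states of
# both layers, concatenated and projected); the decoder (2-layer GRU with
# additive attention over the encoder outputs) reconstructs the input under
# teacher forcing.  Trained on unlabeled SMILES/SPS corpora, the embedding
# and encoder parameters then warm-start the unified regressor.

.KIND_DIM <- c(smiles = 128L, sps = 256L, amino = 256L)

.s2sInit <- function(vocab, dim, maxLength, layers = 2L, dropout = 0.2,
                     seed = 1L) {
  set.seed(seed)
  V <- vocabSize(vocab)
  d <- as.integer(dim)
  sc <- 1 / sqrt(d)
  p <- list()
  p[["enc.E"]] <- .initMat(V, d, 0.1)
  for (l in seq_len(layers)) {
    g <- .gruInit(d, d)
    for (nm in names(g)) p[[paste0("enc.gru", l, ".", nm)]] <- g[[nm]]
    # decoder layer 1 also consumes the previous step's attention context
    # (input feeding), so its input dimension is 2d
    g <- .gruInit(if (l == 1L) 2L * d else d, d)
    for (nm in names(g)) p[[paste0("dec.gru", l, ".", nm)]] <- g[[nm]]
    p[[paste0("dec.Wi", l)]] <- .initMat(d, d, sc)
    p[[paste0("dec.bi", l)]] <- matrix(0, 1, d)
  }
  p[["Wt"]] <- .initMat(layers * d, d, sc)
  p[["bt"]] <- matrix(0, 1, d)
  p[["att.Wa"]] <- .initMat(d, d, sc)
  p[["att.Ua"]] <- .initMat(d, d, sc)
  p[["att.ba"]] <- matrix(0, 1, d)
  p[["att.va"]] <- .initMat(d, 1, sc)
  p[["Wo"]] <- .initMat(2L * d, V, sc)
  p[["bo"]] <- matrix(0, 1, V)
  new("SeqAutoencoder", kind = vocab@kind, vocab = vocab,
      config = list(dim = d, layers = layers, maxLength = maxLength,
                    dropout = dropout),
      params = p, history = data.frame())
}

# Encoder half: returns per-position top-layer outputs (stacked t-major) and
# the thought vector node.
.s2sEncode <- function(tape, pnodes, tokens, cfg, training) {
  enc <- .encoderTape(tape, pnodes, "enc", tokens, cfg$layers, cfg$dim,
                      cfg$dropout, training)
  finals <- lapply(seq_len(cfg$layers), function(l) {
    enc$finals[[paste0("enc.gru", l, ".final")]]
  })
  thought <- tpTanh(tape, tpAddBias(
    tape, tpMM(tape, tpConcatCols(tape, finals), pnodes[["Wt"]]),
    pnodes[["bt"]]
  ))
  c(enc, list(thought = thought))
}

# Full teacher-forced pass; returns the masked reconstruction loss node, the
# stacked per-position logits and bookkeeping needed for accuracy.
.s2sForward <- function(tape, pnodes, tokens, cfg, training) {
  b <- nrow(tokens); L <- ncol(tokens)
  enc <- .s2sEncode(tape, pnodes, tokens, cfg, training)
  maskMat <- matrix(as.numeric(tokens != 3L), b, L)
  encProj <- tpAddBias(tape, tpMM(tape, enc$stack, pnodes[["att.Wa"]]),
                       pnodes[["att.ba"]])
  rep_b <- rep(seq_len(b), L)
  hs <- lapply(seq_len(cfg$layers), function(l) {
    tpTanh(tape, tpAddBias(tape, tpMM(tape, enc$thought,
                                      pnodes[[paste0("dec.Wi", l)]]),
                           pnodes[[paste0("dec.bi", l)]]))
  })
  E <- pnodes[["enc.E"]]
  logitsList <- vector("list", L - 1L)
  ctxPrev <- matrix(0, b, cfg$dim)
  for (t in seq_len(L - 1L)) {
    x <- tpConcatCols(tape, list(tpRows(tape, E, tokens[, t]), ctxPrev))
    m <- as.numeric(tokens[, t] != 3L)
    for (l in seq_len(cfg$layers)) {
      if (l > 1L && training && cfg$dropout > 0) {
        x <- tpDropout(tape, x, cfg$dropout)
      }
      tag <- paste0("dec.gru", l)
      p <- list(W = pnodes[[paste0(tag, ".W")]], U = pnodes[[paste0(tag, ".U")]],
                bi = pnodes[[paste0(tag, ".bi")]], bh = pnodes[[paste0(tag, ".bh")]])
      hs[[l]] <- .gruStep(tape, x, hs[[l]], p, cfg$dim, m)
      x <- hs[[l]]
    }
    q <- tpMM(tape, hs[[cfg$layers]], pnodes[["att.Ua"]])
    u <- tpTanh(tape, tpAdd(tape, encProj, tpRows(tape, q, rep_b)))
    s <- tpMM(tape, u, pnodes[["att.va"]])
    alpha <- tpMaskedSoftmaxRows(tape, tpReshape(tape, s, b, L), maskMat)
    ctx <- tpGroupSum(tape,
                      tpScaleRows(tape, enc$stack,
                                  tpReshape(tape, alpha, b * L, 1L)),
                      rep_b, b)
    logitsList[[t]] <- tpAddBias(
      tape, tpMM(tape, tpConcatCols(tape, list(hs[[cfg$layers]], ctx)),
                 pnodes[["Wo"]]),
      pnodes[["bo"]]
    )
    ctxPrev <- ctx
  }
  logits <- tpRbind(tape, logitsList)
  targets <- as.integer(tokens[, 2:L])          # t-major flattening
  weights <- as.numeric(targets != 3L)
  loss <- tpCrossEntropy(tape, logits, targets, weights)
  list(loss = loss, logits = logits, targets = targets, weights = weights,
       thought = enc$thought)
}

.asTokenMatrix <- function(x, vocab, maxLength = NULL) {
  if (is.matrix(x)) return(x)
  if (length(x) == 0L) stop("empty corpus")
  m <- .tokenizeMatrix(x, vocab, maxLength)
  keep <- max(vapply(seq_len(nrow(m)), function(i) sum(m[i, ] != 3L), 1L)) + 1L
  m[, seq_len(min(ncol(m), keep + 1L)), drop = FALSE]
}

#' Encode sequences into per-position outputs and thought vectors
#'
#' @param model a [SeqAutoencoder].
#' @param x character vector of raw sequences, or an integer token matrix.
#' @return list with `outputs` (array samples x positions x dim, pad
#'   positions zeroed) and `thought` (samples x dim matrix).  The thought
#'   vector has the channel's fixed dimension regardless of sequence length
#'   and is unaffected by the amount of padding.
#' @export
encodeSequences <- function(model, x) {
  stopifnot(is(model, "SeqAutoencoder"))
  tokens <- .asTokenMatrix(x, model@vocab, model@config$maxLength)
  tape <- tpTape()
  enc <- .s2sEncode(tape, model@params, tokens, model@config, training = FALSE)
  b <- nrow(tokens); L <- ncol(tokens)
  outs <- array(0, c(b, L, model@config$dim))
  for (t in seq_len(L)) {
    live <- tokens[, t] != 3L
    o <- tpVal(enc$outs[[t]])
    o[!live, ] <- 0
    outs[, t, ] <- o
  }
  list(outputs = outs, thought = tpVal(enc$thought))
}

#' Thought vectors of sequences
#'
#' @inheritParams encodeSequences
#' @return samples x dim numeric matrix.
#' @export
thoughtVectors <- function(model, x) encodeSequences(model, x)$thought

#' Teacher-forced decoder scores
#'
#' Runs the full autoencoder pass under teacher forcing and returns the
#' decoder's per-position probability distribution over the vocabulary
#' (positions 2..L of the input; each row sums to 1).  Pad positions carry a
#' zero loss weight and are reported with `weight = 0`.
#'
#' @inheritParams encodeSequences
#' @return list with `scores` (array samples x positions x vocab), `targets`
#'   and `weights`.
#' @export
decodeScores <- function(model, x) {
  stopifnot(is(model, "SeqAutoencoder"))
  tokens <- .asTokenMatrix(x, model@vocab, model@config$maxLength)
  tape <- tpTape()
  fw <- .s2sForward(tape, model@params, tokens, model@config, training = FALSE)
  lg <- tpVal(fw$logits)
  p <- exp(lg - apply(lg, 1, max))
  p <- p / rowSums(p)
  b <- nrow(tokens); L <- ncol(tokens)
  scores <- array(0, c(b, L - 1L, ncol(p)))
  for (t in seq_len(L - 1L)) scores[, t, ] <- p[(t - 1L) * b + seq_len(b), ]
  list(scores = scores,
       targets = matrix(fw$targets, b, L - 1L),
       weights = matrix(fw$weights, b, L - 1L))
}

#' Pretrain a sequence-channel autoencoder
#'
#' Trains the GRU encoder-decoder to reconstruct its own input on an
#' unlabeled corpus.  The default optimizer is Adam at learning rate 1e-3;
#' the alternative published schedule (plain SGD, initial rate 0.5 decayed by
#' 0.99 per epoch) is selectable with `optimizer = "sgd"`.  Training is fully
#' reproducible under `seed`.
#'
#' @param corpus character vector of raw sequences (one per element).
#' @param kind channel kind; inferred from `vocab` when supplied.
#' @param vocab the channel [Vocabulary]; defaults to the base vocabulary of
#'   the kind (68-symbol SMILES, 76-word SPS, amino).
#' @param dim latent/embedding dimension; defaults to 128 for SMILES and 256
#'   for SPS/amino.
#' @param epochs training epochs (default 100).
#' @param batchSize minibatch size (default 64).
#' @param lr Adam learning rate.
#' @param lrDecay multiplicative per-epoch learning-rate decay (1 = constant;
#'   the published pretraining schedule decays by 0.99 per epoch).
#' @param optimizer `"adam"` or `"sgd"` (0.5 with 0.99 per-epoch decay).
#' @param dropout dropout rate between stacked GRU layers.
#' @param maxLength sequence capacity; defaults to the kind's cap.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return a trained [SeqAutoencoder]; `trainingHistory()` holds the
#'   per-epoch reconstruction loss and token accuracy.
#' @export
pretrainAutoencoder <- function(corpus, kind = c("smiles", "sps", "amino"),
                                vocab = NULL, dim = NULL, epochs = 100L,
                                batchSize = 64L, lr = 0.001, lrDecay = 1,
                                optimizer = c("adam", "sgd"),
                                dropout = 0.2, maxLength = NULL, seed = 1L,
                                verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(vocab)) {
    kind <- match.arg(kind)
    vocab <- switch(kind, smiles = smilesVocabulary(), sps = spsVocabulary(),
                    amino = aminoVocabulary())
  }
  if (is.null(dim)) dim <- .KIND_DIM[[vocab@kind]]
  if (is.null(maxLength)) maxLength <- defaultMaxLength(vocab@kind)
  tokens <- .asTokenMatrix(corpus, vocab, maxLength)
  model <- .s2sInit(vocab, dim, maxLength, dropout = dropout, seed = seed)
  set.seed(seed + 1L)
  params <- model@params
  state <- .adamInit(params)
  sgdLr <- 0.5
  lrEp <- lr
  n <- nrow(tokens)
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    totLoss <- 0; totW <- 0; hit <- 0
    for (start in seq(1L, n, by = batchSize)) {
      rows <- ord[start:min(start + batchSize - 1L, n)]
      bt <- tokens[rows, , drop = FALSE]
      keep <- max(rowSums(bt != 3L)) + 1L
      bt <- bt[, seq_len(min(ncol(bt), keep + 1L)), drop = FALSE]
      tape <- tpTape()
      pnodes <- .wrapParams(tape, params)
      fw <- .s2sForward(tape, pnodes, bt, model@config, training = TRUE)
      tpBackward(tape, fw$loss)
      grads <- .collectGrads(pnodes)
      if (optimizer == "adam") {
        upd <- .adamStep(params, grads, state, lrEp)
        params <- upd$params; state <- upd$state
      } else {
        params <- .sgdStep(params, grads, sgdLr)
      }
      w <- sum(fw$weights)
      totLoss <- totLoss + tpVal(fw$loss) * w
      totW <- totW + w
      pred <- max.col(tpVal(fw$logits), ties.method = "first")
      hit <- hit + sum((pred == fw$targets) * fw$weights)
    }
    if (optimizer == "sgd") sgdLr <- sgdLr * 0.99
    lrEp <- lrEp * lrDecay
    hist <- rbind(hist, data.frame(epoch = ep, loss = totLoss / totW,
                                   accuracy = hit / totW))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  acc %.3f", ep,
                      totLoss / totW, hit / totW))
    }
  }
  model@params <- params
  model@history <- hist
  model
}

#' Teacher-forced token reconstruction accuracy
#'
#' Fraction of non-pad target tokens whose greedy (argmax) decoder score
#' matches the input, evaluated without dropout.
#'
#' @inheritParams encodeSequences
#' @return fraction in \[0, 1\].
#' @export
reconstructionAccuracy <- function(model, x) {
  stopifnot(is(model, "SeqAutoencoder"))
  if (length(x) == 0L) stop("empty corpus")
  tokens <- .asTokenMatrix(x, model@vocab, model@config$maxLength)
  tape <- tpTape()
  fw <- .s2sForward(tape, model@params, tokens, model@config, training = FALSE)
  pred <- max.col(tpVal(fw$logits), ties.method = "first")
  sum((pred == fw$targets) * fw$weights) / sum(fw$weights)
}

#' @describeIn trainingHistory SeqAutoencoder method.
#' @export
setMethod("trainingHistory", "SeqAutoencoder", function(x) x@history)

setMethod("show", "SeqAutoencoder", function(object) {
  tr <- if (nrow(object@history)) {
    sprintf("trained %d epochs, final loss %.4f",
            max(object@history$epoch), utils::tail(object@history$loss, 1))
  } else "untrained"
  cat(sprintf("SeqAutoencoder (%s): dim %d, %d GRU layers, %s\n",
              object@kind, object@config$dim, object@config$layers, tr))
})
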