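#' @import methods
NULL

#' Vocabulary of sequence symbols
#'
#' An ordered symbol table for one of the three sequence kinds handled by the
#' package: `"smiles"` (compound SMILES symbols), `"sps"` (4-letter structural
#' property words of a protein) or `"amino"` (one-letter residue codes).  The
#' four reserved tokens -- start, end, pad and unused -- always occupy the
#' first four indices, so the total size is the number of content symbols
#' plus four.
#'
#' @slot symbols character vector of all tokens, specials first.
#' @slot kind one of `"smiles"`, `"sps"`, `"amino"`.
#' @export
setClass("Vocabulary", representation(symbols = "character", kind = "character"))

setValidity("Vocabulary", function(object) {
  sp <- specialTokens()
  if (length(object@kind) != 1L || !object@kind %in% c("smiles", "sps", "amino"))
    return("kind must be one of 'smiles', 'sps', 'amino'")
  if (length(object@symbols) < 5L)
    return("vocabulary must contain the 4 special tokens plus at least one symbol")
  if (!identical(object@symbols[1:4], sp))
    return("the 4 special tokens must occupy the first four indices")
  if (anyDuplicated(object@symbols))
    return("vocabulary symbols must be unique")
  TRUE
})

#' A tokenized, padded sequence
#'
#' A fixed-capacity vector of vocabulary indices laid out as
#' start, tokens..., end, pad... .  `trueLength` counts the real tokens
#' (excluding start/end/pad) and is at most `maxLength - 2`.
#'
#' @slot indices integer vector of exactly `maxLength` vocabulary indices.
#' @slot trueLength number of real tokens.
#' @slot maxLength capacity of the sequence.
#' @slot kind vocabulary kind the indices refer to.
#' @export
setClass("TokenSequence", representation(
  indices = "integer", trueLength = "integer",
  maxLength = "integer", kind = "character"
))

setValidity("TokenSequence", function(object) {
  n <- object@maxLength
  idx <- object@indices
  if (length(idx) != n) return("indices must have exactly maxLength entries")
  if (object@trueLength > n - 2L) return("trueLength exceeds maxLength - 2")
  tl <- object@trueLength
  if (idx[1] != 1L || idx[tl + 2L] != 2L)
    return("sequence must be laid out start, tokens..., end, pad...")
  if (tl + 2L < n && any(idx[(tl + 3L):n] != 3L))
    return("no real token may follow the first pad")
  TRUE
})

#' Structural property sequence of a protein
#'
#' The protein rendered as one 4-letter word per secondary-structure segment:
#' structure (A/B/C), solvent exposure (N/E), dominant physicochemical class
#' (G/T/D/K) and segment length class (S/M/L).
#'
#' @slot words character vector of 4-letter SPS words, one per segment.
#' @slot sourceLength residue count of the underlying protein.
#' @export
setClass("SPSSequence", representation(words = "character", sourceLength = "integer"))

setValidity("SPSSequence", function(object) {
  if (object@sourceLength < 1L) return("sourceLength must be >= 1")
  if (length(object@words) < 1L) return("an SPS sequence must contain at least one word")
  if (length(object@words) > object@sourceLength)
    return("cannot have more segments than residues")
  bad <- !object@words %in% enumerateSPSAlphabet()
  if (any(bad)) return(paste("illegal SPS word:", object@words[bad][1]))
  TRUE
})

#' 2D molecular graph of a compound
#'
#' Heavy-atom graph parsed from a SMILES string: one node per atom, one
#' undirected edge per bond, plus the per-atom initial feature matrix used by
#' the graph convolution channel (element one-hot, scaled degree, ring
#' membership, formal charge).
#'
#' @slot smiles the source SMILES string.
#' @slot elements element symbol per atom.
#' @slot edges two-column integer matrix of bonds (each bond once).
#' @slot adjacency list of integer neighbor vectors, one per atom.
#' @slot degrees integer neighbor count per atom.
#' @slot features numeric matrix of initial atom features (atoms x features).
#' @export
setClass("MolecularGraph", representation(
  smiles = "character", elements = "character", edges = "matrix",
  adjacency = "list", degrees = "integer", features = "matrix"
))

setValidity("MolecularGraph", function(object) {
  n <- length(object@elements)
  if (n < 1L) return("a molecular graph must contain at least one atom")
  if (length(object@adjacency) != n || length(object@degrees) != n ||
      nrow(object@features) != n)
    return("per-atom slots must agree on atom count")
  for (i in seq_len(n)) {
    nb <- object@adjacency[[i]]
    if (any(nb == i)) return("self-loops are not allowed")
    if (length(nb) != object@degrees[i]) return("degrees inconsistent with adjacency")
    for (j in nb) if (!i %in% object@adjacency[[j]])
      return("adjacency must be symmetric")
  }
  TRUE
})

#' Degree-filtered graph convolution weights
#'
#' The filter bank of the graph channel: for each layer L = 1..radius and each
#' neighbor count n = 1..5 one square hidden-dimension matrix H(L, n), plus a
#' linear projection of raw atom features into the hidden dimension.  Atoms
#' with no neighbors use H(L, 1) with an empty neighbor sum; degrees above 5
#' clamp to H(L, 5).
#'
#' @slot radius number of convolution layers (paper default 3).
#' @slot hiddenDim dimension of the per-atom hidden vectors.
#' @slot activation name of the nonlinearity ("relu", "tanh" or "identity").
#' @slot Win input projection, feature-dim x hiddenDim.
#' @slot bin input projection bias.
#' @slot H list of `radius` lists of 5 hiddenDim x hiddenDim filter matrices.
#' @export
setClass("GraphConvWeights", representation(
  radius = "integer", hiddenDim = "integer", activation = "character",
  Win = "matrix", bin = "matrix", H = "list"
))

setValidity("GraphConvWeights", function(object) {
  if (!object@activation %in% c("relu", "tanh", "identity"))
    return("activation must be 'relu', 'tanh' or 'identity'")
  if (length(object@H) != object@radius)
    return("need one filter set per layer")
  d <- object@hiddenDim
  for (hs in object@H) {
    if (length(hs) != 5L) return("need exactly 5 degree filters per layer")
    for (m in hs) if (!all(dim(m) == c(d, d)))
      return("all filters must be square hiddenDim x hiddenDim")
  }
  if (ncol(object@Win) != d) return("input projection must map into hiddenDim")
  TRUE
})

#' Labeled compound-protein interaction dataset
#'
#' A validated table of (compound, protein, affinity) records.  The `samples`
#' data.frame carries columns `compound_id`, `smiles`, `protein_id`, `sps`
#' (space-separated SPS words), optionally `amino`, `label` (real-valued
#' affinity on the model scale, log10 IC50), and `split`.
#'
#' @slot samples the sample table.
#' @slot provenance list with source path, manifest information and, for
#'   synthetic data, the generating mechanism (weights, clean labels).
#' @export
setClass("CPIDataset", representation(samples = "data.frame", provenance = "list"))

setValidity("CPIDataset", function(object) {
  need <- c("compound_id", "smiles", "protein_id", "sps", "label")
  miss <- setdiff(need, names(object@samples))
  if (length(miss)) return(paste("missing required column:", miss[1]))
  if (!is.numeric(object@samples$label)) return("label must be numeric")
  if (any(!is.finite(object@samples$label))) return("labels must be finite")
  TRUE
})

#' GRU seq2seq autoencoder
#'
#' Encoder-decoder over one sequence channel, used to pretrain the embedding
#' and encoder parameters that warm-start the unified regressor.  The encoder
#' is a 2-layer GRU whose final hidden states are projected into the channel's
#' fixed-dimension thought vector; the decoder is a 2-layer GRU with additive
#' attention over the encoder outputs, trained with teacher forcing to
#' reconstruct the input.
#'
#' @slot kind vocabulary kind of the channel.
#' @slot vocab the channel [Vocabulary].
#' @slot config list: dim, layers, maxLength, dropout.
#' @slot params flat named list of parameter matrices.
#' @slot history per-epoch data.frame (epoch, loss, accuracy).
#' @export
setClass("SeqAutoencoder", representation(
  kind = "character", vocab = "Vocabulary",
  config = "list", params = "list", history = "data.frame"
))

#' Multi-channel compound-protein affinity regressor
#'
#' The unified end-to-end model: GRU + attention + 1D CNN channels over the
#' SMILES and SPS sequences, a degree-filtered graph convolution channel over
#' the 2D molecular graph, an optional bidirectional-GRU amino-acid channel,
#' concatenative fusion and a fully connected regression head.
#'
#' @slot config channel configuration list, see [channelConfig()].
#' @slot vocabs named list of [Vocabulary] objects per sequence channel.
#' @slot params flat named list of parameter matrices.
#' @slot history per-epoch training history (epoch, train_loss, val_loss).
#' @export
setClass("CPIModel", representation(
  config = "list", vocabs = "list", params = "list", history = "data.frame"
))
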