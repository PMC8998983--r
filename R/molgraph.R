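# SMILES -> 2D molecular graph, and the degree-filtered graph convolution:
# for layers L = 1..R every atom a simultaneously computes
#   v    = r_a + sum of neighbor states r_u        (previous-layer states)
#   r_a' = sigma(v %*% H(L, clamp(|N|, 1, 5)))
# i.e. the filter matrix is selected by the atom's neighbor count (five
# filters per layer; isolated atoms use the degree-1 filter with an empty
# neighbor sum, degrees above five clamp to the fifth filter).

.ELEMENT_PALETTE <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I")

# SDF V2000 atom-block charge codes -> formal charges.
.SDF_CHARGE <- c("0" = 0, "1" = 3, "2" = 2, "3" = 1, "4" = 0,
                 "5" = -1, "6" = -2, "7" = -3)

#' Parse a SMILES string into a molecular graph
#'
#' Chemistry parsing (ring closure, aromaticity, valence) is delegated to
#' OpenBabel via \pkg{ChemmineR}; the result is reduced to the heavy-atom
#' graph (hydrogens implicit) with one undirected edge per bond.  Initial
#' atom features are: one-hot element over a fixed palette
#' (C, N, O, S, F, P, Cl, Br, I, other), degree scaled by 1/4, a ring
#' membership flag (an atom is in a ring when it has an incident non-bridge
#' edge) and the formal charge.
#'
#' @param smiles a single SMILES string.
#' @return a [MolecularGraph].
#' @examples
#' g <- parseSmiles("C1CC1")  # cyclopropane: 3 atoms, 3 bonds, all degree 2
#' atomCount(g)
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf)) stop("cannot parse SMILES: ", smiles)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) stop("cannot parse SMILES: ", smiles)
  if (!all(grepl("^[A-Za-z]", rownames(ab)))) {
    # single heavy atom: the SDF block parser cannot represent it, so build
    # the one-node graph directly from the SMILES token
    el <- sub("^\\[?([A-Za-z][a-z]?).*$", "\\1", smiles)
    if (nchar(el) == 1L) el <- toupper(el)
    charge <- (nchar(gsub("[^+]", "", smiles)) -
               nchar(gsub("[^-]", "", smiles)))
    return(.newMolecularGraph(smiles, el, matrix(integer(0), ncol = 2),
                              charge))
  }
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bb <- ChemmineR::bondblock(mol)
  edges <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  charge <- rep(0, n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charge <- unname(ifelse(code %in% names(.SDF_CHARGE), .SDF_CHARGE[code], 0))
  }
  .newMolecularGraph(smiles, elements, edges, charge)
}

.newMolecularGraph <- function(smiles, elements, edges, charge = NULL) {
  n <- length(elements)
  if (is.null(charge)) charge <- rep(0, n)
  adjacency <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adjacency[[i]] <- c(adjacency[[i]], j)
      adjacency[[j]] <- c(adjacency[[j]], i)
    }
  }
  degrees <- lengths(adjacency)
  inRing <- rep(FALSE, n)
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    br <- igraph::bridges(g)
    ringEdge <- rep(TRUE, nrow(edges))
    ringEdge[as.integer(br)] <- FALSE
    for (k in which(ringEdge)) inRing[edges[k, ]] <- TRUE
  }
  pal <- .ELEMENT_PALETTE
  onehot <- matrix(0, n, length(pal) + 1L,
                   dimnames = list(NULL, c(pal, "other")))
  slot <- match(elements, pal, nomatch = length(pal) + 1L)
  onehot[cbind(seq_len(n), slot)] <- 1
  features <- cbind(onehot, degree = degrees / 4, ring = as.numeric(inRing),
                    charge = charge)
  new("MolecularGraph", smiles = smiles, elements = elements,
      edges = edges, adjacency = adjacency, degrees = as.integer(degrees),
      features = features)
}

#' @describeIn atomCount MolecularGraph method.
#' @export
setMethod("atomCount", "MolecularGraph", function(x) length(x@elements))

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms, %d bonds\n",
              object@smiles, length(object@elements), nrow(object@edges)))
})

#' Initialize a degree-filtered graph convolution filter bank
#'
#' @param inputDim number of raw atom features (13 for the default recipe).
#' @param hiddenDim per-atom hidden dimension.
#' @param radius number of layers R (default 3).
#' @param activation nonlinearity applied after each filter.
#' @param seed RNG seed for the random initialization.
#' @return a [GraphConvWeights].
#' @export
initGraphConvWeights <- function(inputDim = 13L, hiddenDim = 128L, radius = 3L,
                                 activation = c("relu", "tanh", "identity"),
                                 seed = 1L) {
  activation <- match.arg(activation)
  set.seed(seed)
  sc <- 1 / sqrt(hiddenDim)
  H <- lapply(seq_len(radius), function(L) {
    lapply(1:5, function(n) {
      matrix(stats::runif(hiddenDim^2, -sc, sc), hiddenDim, hiddenDim)
    })
  })
  new("GraphConvWeights",
      radius = as.integer(radius), hiddenDim = as.integer(hiddenDim),
      activation = activation,
      Win = matrix(stats::runif(inputDim * hiddenDim, -sc, sc),
                   inputDim, hiddenDim),
      bin = matrix(0, 1, hiddenDim), H = H)
}

.applySigma <- function(x, activation) {
  switch(activation, relu = pmax(x, 0), tanh = tanh(x), identity = x)
}

# Batched graph-convolution structure: atoms of all graphs stacked into one
# matrix, a sparse adjacency for the neighbor sums, per-atom degree bucket
# (clamped to 1..5) and the owning-molecule index of every atom.
.graphBatch <- function(graphs) {
  counts <- vapply(graphs, atomCount, 1L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  feats <- do.call(rbind, lapply(graphs, function(g) g@features))
  edges <- do.call(rbind, Map(function(g, off) {
    if (nrow(g@edges)) g@edges + off else g@edges
  }, graphs, offsets))
  ntot <- sum(counts)
  S <- if (NROW(edges)) {
    Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                         j = c(edges[, 2], edges[, 1]),
                         x = 1, dims = c(ntot, ntot))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(ntot, ntot))
  }
  degrees <- unlist(lapply(graphs, function(g) g@degrees), use.names = FALSE)
  list(features = feats, S = S, bucket = pmin(pmax(degrees, 1L), 5L),
       mol = rep(seq_along(graphs), counts), nmol = length(graphs))
}

# Tape version of the forward pass over a stacked batch; params are tape
# nodes (training) or plain matrices (inference).  Returns the final-layer
# stacked atom-state node.
.graphConvTape <- function(tape, batch, Win, bin, H, radius, activation) {
  act <- switch(activation,
                relu = function(x) tpRelu(tape, x),
                tanh = function(x) tpTanh(tape, x),
                identity = function(x) x)
  r <- tpAddBias(tape, tpMM(tape, batch$features, Win), bin)
  order <- order(batch$bucket)
  perm <- order(order)  # inverse permutation: bucket-sorted rows -> original
  for (L in seq_len(radius)) {
    v <- tpAdd(tape, r, tpSpMM(tape, batch$S, r))
    pieces <- list()
    for (n in 1:5) {
      rows <- which(batch$bucket == n)
      if (!length(rows)) next
      pieces[[length(pieces) + 1L]] <-
        tpMM(tape, tpRows(tape, v, rows), H[[L]][[n]])
    }
    stacked <- if (length(pieces) > 1L) tpRbind(tape, pieces) else pieces[[1]]
    r <- act(tpRows(tape, stacked, perm))
  }
  r
}

#' Run the graph convolution over a molecular graph
#'
#' `mode = "synchronous"` (the default) updates all atoms of a layer from the
#' previous layer's states, which keeps the output invariant under atom
#' relabeling.  `mode = "inplace"` runs the literal sequential node loop,
#' where later atoms in file order already see updated neighbors; it is
#' provided for comparison only.
#'
#' @param graph a [MolecularGraph].
#' @param weights a [GraphConvWeights].
#' @param mode update discipline, see Details.
#' @return numeric matrix of final per-atom hidden vectors (atoms x hiddenDim).
#' @export
graphConvForward <- function(graph, weights, mode = c("synchronous", "inplace")) {
  mode <- match.arg(mode)
  stopifnot(is(graph, "MolecularGraph"), is(weights, "GraphConvWeights"))
  if (ncol(graph@features) != nrow(weights@Win)) {
    stop("feature dimension of graph does not match input projection")
  }
  if (mode == "synchronous") {
    tape <- tpTape()
    batch <- .graphBatch(list(graph))
    out <- .graphConvTape(tape, batch, weights@Win, weights@bin, weights@H,
                          weights@radius, weights@activation)
    return(tpVal(out))
  }
  # literal in-place variant
  r <- sweep(graph@features %*% weights@Win, 2, as.numeric(weights@bin), "+")
  for (L in seq_len(weights@radius)) {
    for (a in seq_len(atomCount(graph))) {
      nb <- graph@adjacency[[a]]
      v <- r[a, ]
      if (length(nb)) v <- v + colSums(r[nb, , drop = FALSE])
      bucket <- min(max(length(nb), 1L), 5L)
      r[a, ] <- .applySigma(v %*% weights@H[[L]][[bucket]],
                            weights@activation)
    }
  }
  r
}

#' Initialize additive attention-pooling parameters
#'
#' Scoring is additive: each vector is passed through a tanh hidden layer and
#' scored by a dot product; scores are softmax-normalized over the pooled set
#' (atoms of a molecule, or positions of a sequence).
#'
#' @param dim dimension of the pooled vectors.
#' @param seed RNG seed.
#' @return list with matrices `Wa`, `ba`, `va`.
#' @export
initAttentionParams <- function(dim, seed = 1L) {
  set.seed(seed)
  sc <- 1 / sqrt(dim)
  list(Wa = matrix(stats::runif(dim * dim, -sc, sc), dim, dim),
       ba = matrix(0, 1, dim),
       va = matrix(stats::runif(dim, -sc, sc), dim, 1))
}

# Tape attention pooling over stacked rows grouped by `groups` (ngroups
# molecules).  Returns the ngroups x dim pooled node.
.attnPoolTape <- function(tape, x, groups, ngroups, Wa, ba, va) {
  u <- tpTanh(tape, tpAddBias(tape, tpMM(tape, x, Wa), ba))
  scores <- tpMM(tape, u, va)
  alpha <- tpGroupSoftmax(tape, scores, groups)
  tpGroupSum(tape, tpScaleRows(tape, x, alpha), groups, ngroups)
}

#' Attention-pool per-atom vectors into a molecule vector
#'
#' Computes nonnegative attention weights summing to one over the atoms and
#' returns the weighted sum of atom vectors.  A single atom gets weight 1;
#' identical atom vectors get uniform weights.
#'
#' @param atoms numeric matrix of per-atom vectors (atoms x dim).
#' @param params attention parameters from [initAttentionParams()].
#' @return numeric vector of length dim with attribute `"weights"` holding
#'   the attention weights.
#' @export
attentionPool <- function(atoms, params) {
  if (NROW(atoms) == 0L) stop("cannot pool an empty atom set")
  atoms <- as.matrix(atoms)
  u <- tanh(sweep(atoms %*% params$Wa, 2, as.numeric(params$ba), "+"))
  s <- as.numeric(u %*% params$va)
  alpha <- exp(s - max(s))
  alpha <- alpha / sum(alpha)
  out <- as.numeric(crossprod(atoms, alpha))
  attr(out, "weights") <- alpha
  out
}
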