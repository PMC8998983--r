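#' Number of symbols in a vocabulary (including the 4 specials)
#' @param x a [Vocabulary].
#' @return integer size.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' Symbols of a vocabulary
#' @param x a [Vocabulary].
#' @param includeSpecials include the 4 reserved tokens (default TRUE).
#' @return character vector of symbols.
#' @export
setGeneric("vocabSymbols", function(x, includeSpecials = TRUE)
  standardGeneric("vocabSymbols"))

#' Number of atoms of a molecular graph
#' @param x a [MolecularGraph].
#' @return integer atom count.
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' SPS words of an SPS sequence
#' @param x an [SPSSequence].
#' @return character vector of 4-letter words.
#' @export
setGeneric("spsWords", function(x) standardGeneric("spsWords"))

#' Sample table of a CPI dataset
#' @param x a [CPIDataset].
#' @return the samples data.frame.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Number of samples
#' @param x a [CPIDataset].
#' @return integer count.
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))

#' Per-epoch training history
#' @param x a trained [SeqAutoencoder] or [CPIModel].
#' @return data.frame of per-epoch losses.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Save a model checkpoint
#'
#' Writes a checkpoint directory holding the parameter tensors plus a JSON
#' manifest (class, configuration, vocabulary hash).  Reloading with
#' [loadModel()] reproduces predictions bit-exactly.
#'
#' @param object a [SeqAutoencoder] or [CPIModel].
#' @param dir directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
setGeneric("saveModel", function(object, dir) standardGeneric("saveModel"))

#' Predict affinities for compound-protein samples
#'
#' @param object a trained [CPIModel].
#' @param newdata a [CPIDataset] or a data.frame with the columns the model's
#'   active channels require (`smiles`, `sps`, optionally `amino`).
#' @param batchSize forward-pass batch size.
#' @return numeric vector of predicted affinities (log10 IC50 scale; lower
#'   means stronger interaction).
#' @export
setGeneric("predictAffinity", function(object, newdata, batchSize = 256)
  standardGeneric("predictAffinity"))
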