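# Dataset readers/writers, splits and model checkpoints.

#' Construct a validated CPI dataset
#'
#' @param samples data.frame with columns `compound_id`, `smiles`,
#'   `protein_id`, `sps`, optionally `amino`, `label` and `split`.
#' @param provenance free-form provenance list (source path, manifest, ...).
#' @param allowDuplicates permit duplicate (compound, protein) pairs within a
#'   split.
#' @return a [CPIDataset].
#' @export
newCPIDataset <- function(samples, provenance = list(),
                          allowDuplicates = FALSE) {
  if (is.null(samples$split)) samples$split <- "train"
  if (!allowDuplicates) {
    key <- paste(samples$compound_id, samples$protein_id, samples$split)
    if (anyDuplicated(key)) {
      stop("duplicate (compound, protein) pair within a split; ",
           "pass allowDuplicates = TRUE to permit")
    }
  }
  rownames(samples) <- NULL
  new("CPIDataset", samples = samples, provenance = provenance)
}

#' @describeIn samples CPIDataset method.
#' @export
setMethod("samples", "CPIDataset", function(x) x@samples)

#' @describeIn sampleCount CPIDataset method.
#' @export
setMethod("sampleCount", "CPIDataset", function(x) nrow(x@samples))

#' Provenance of a dataset
#' @param x a [CPIDataset].
#' @return the provenance list.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "CPIDataset", function(object) {
  spl <- table(object@samples$split)
  cat(sprintf("CPIDataset: %d samples (%s); %d compounds, %d proteins\n",
              nrow(object@samples),
              paste(names(spl), spl, sep = "=", collapse = ", "),
              length(unique(object@samples$compound_id)),
              length(unique(object@samples$protein_id))))
})

#' Read a CPI table from CSV/TSV
#'
#' Parsing is by column name, never position.  Required columns:
#' `compound_id`, `smiles`, `protein_id`, `sps`, `label`; `amino` and `split`
#' are optional.  Each row is validated: the label must parse as a finite
#' decimal number, the SMILES must parse to a molecular graph and both
#' sequences must tokenize against the channel vocabularies.  In `"strict"`
#' mode any failing row aborts with its row number; in `"lenient"` mode
#' failing rows are dropped and reported (row numbers kept in the
#' provenance).
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param mode `"strict"` or `"lenient"`.
#' @param labelTransform `"none"` if the label column is already on the model
#'   (log10 IC50) scale, `"log10"` to transform raw positive IC50 values.
#' @return a [CPIDataset].
#' @export
readCPITable <- function(path, mode = c("strict", "lenient"),
                         labelTransform = c("none", "log10")) {
  mode <- match.arg(mode)
  labelTransform <- match.arg(labelTransform)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("compound_id", "smiles", "protein_id", "sps", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column: ", miss[1])
  label <- suppressWarnings(as.numeric(df$label))
  if (labelTransform == "log10") label <- log10(label)
  smilesV <- smilesVocabulary()
  spsV <- spsVocabulary()
  bad <- vapply(seq_len(nrow(df)), function(i) {
    if (!is.finite(label[i])) return("malformed label")
    if (inherits(tryCatch(parseSmiles(df$smiles[i]), error = function(e) e),
                 "error")) {
      return("unparsable SMILES")
    }
    ok <- tryCatch({
      tokenize(df$smiles[i], smilesV)
      tokenize(df$sps[i], spsV)
      NA_character_
    }, error = function(e) conditionMessage(e))
    ok
  }, NA_character_)
  failed <- which(!is.na(bad))
  if (length(failed) && mode == "strict") {
    stop(sprintf("row %d: %s", failed[1], bad[failed[1]]))
  }
  if (length(failed)) {
    message(sprintf("readCPITable: dropped %d of %d rows (%s)",
                    length(failed), nrow(df),
                    paste(sprintf("row %d: %s", failed, bad[failed]),
                          collapse = "; ")))
    df <- df[-failed, , drop = FALSE]
    label <- label[-failed]
  }
  df$label <- label
  newCPIDataset(df, provenance = list(source = path,
                                      rejected = failed,
                                      reasons = bad[failed]))
}

#' Write a CPI dataset as CSV/TSV
#'
#' @param dataset a [CPIDataset].
#' @param path output file; extension selects the separator.
#' @return `path`, invisibly.
#' @export
writeCPITable <- function(dataset, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(samples(dataset), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a dataset into train and validation parts
#'
#' Seeded uniform random split; the two parts are disjoint, exhaust the
#' input, and carry split tags `"train"` / `"val"`.
#'
#' @param dataset a [CPIDataset].
#' @param valFraction fraction held out for validation (default 0.1).
#' @param seed RNG seed.
#' @return list with elements `train` and `val` ([CPIDataset]s).
#' @export
splitDataset <- function(dataset, valFraction = 0.1, seed = 1L) {
  if (valFraction <= 0 || valFraction >= 1) {
    stop("valFraction must be in (0, 1)")
  }
  df <- samples(dataset)
  n <- nrow(df)
  if (n == 0L) stop("empty dataset")
  set.seed(seed)
  nVal <- round(n * valFraction)
  valIdx <- sample.int(n, nVal)
  dfVal <- df[valIdx, , drop = FALSE]
  dfTrain <- df[setdiff(seq_len(n), valIdx), , drop = FALSE]
  dfVal$split <- "val"
  dfTrain$split <- "train"
  prov <- dataset@provenance
  prov$splitSeed <- seed
  mech <- prov$mechanism
  if (!is.null(mech$clean)) {
    trainProv <- prov; valProv <- prov
    trainProv$mechanism$clean <- mech$clean[setdiff(seq_len(n), valIdx)]
    valProv$mechanism$clean <- mech$clean[valIdx]
    return(list(train = newCPIDataset(dfTrain, trainProv),
                val = newCPIDataset(dfVal, valProv)))
  }
  list(train = newCPIDataset(dfTrain, prov),
       val = newCPIDataset(dfVal, prov))
}

# ---- checkpoints -------------------------------------------------------

.vocabHash <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(vocab@kind, vocab@symbols), f)
  unname(tools::md5sum(f))
}

.writeCheckpoint <- function(dir, manifest, payload) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(payload, file.path(dir, "params.rds"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @describeIn saveModel SeqAutoencoder method.
#' @export
setMethod("saveModel", "SeqAutoencoder", function(object, dir) {
  .writeCheckpoint(dir,
    manifest = list(class = "SeqAutoencoder", kind = object@kind,
                    dim = object@config$dim, layers = object@config$layers,
                    maxLength = object@config$maxLength,
                    vocab_md5 = .vocabHash(object@vocab),
                    epochs = nrow(object@history)),
    payload = list(class = "SeqAutoencoder", kind = object@kind,
                   vocab = list(kind = object@vocab@kind,
                                symbols = object@vocab@symbols),
                   config = object@config, params = object@params,
                   history = object@history))
})

#' @describeIn saveModel CPIModel method.
#' @export
setMethod("saveModel", "CPIModel", function(object, dir) {
  .writeCheckpoint(dir,
    manifest = list(class = "CPIModel",
                    channels = object@config$channels,
                    vocab_md5 = lapply(object@vocabs, .vocabHash),
                    epochs = nrow(object@history)),
    payload = list(class = "CPIModel", config = object@config,
                   vocabs = lapply(object@vocabs, function(v) {
                     list(kind = v@kind, symbols = v@symbols)
                   }),
                   params = object@params, history = object@history))
})

#' Load a model checkpoint
#'
#' @param dir a checkpoint directory written by [saveModel()].
#' @return the restored [SeqAutoencoder] or [CPIModel]; predictions of the
#'   restored model are bit-identical to the saved one.
#' @export
loadModel <- function(dir) {
  payload <- readRDS(file.path(dir, "params.rds"))
  revive <- function(v) new("Vocabulary", symbols = v$symbols, kind = v$kind)
  if (payload$class == "SeqAutoencoder") {
    new("SeqAutoencoder", kind = payload$kind, vocab = revive(payload$vocab),
        config = payload$config, params = payload$params,
        history = payload$history)
  } else {
    new("CPIModel", config = payload$config,
        vocabs = lapply(payload$vocabs, revive),
        params = payload$params, history = payload$history)
  }
}
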