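#' The four reserved vocabulary tokens
#'
#' Every vocabulary starts with the same four special tokens: sequence start,
#' sequence end, padding (to align sequences within a batch) and an unused
#' slot that the lenient tokenization policy maps unknown tokens onto.
#'
#' @return character vector of length 4, in index order.
#' @export
specialTokens <- function() c("<start>", "<end>", "<pad>", "<unused>")

.KIND_MAXLEN <- c(smiles = 100L, sps = 152L, amino = 400L)

#' Default maximum tokenized length for a vocabulary kind
#'
#' SMILES strings are capped at 100 symbols and SPS strings at 152 words
#' (the 95th-percentile caps used when assembling the training corpus);
#' amino-acid sequences default to 400 residues.  The cap includes the start
#' and end tokens, so the longest admissible sequence has `maxLength - 2`
#' real tokens.
#'
#' @param kind `"smiles"`, `"sps"` or `"amino"`.
#' @return integer length cap.
#' @export
defaultMaxLength <- function(kind) {
  kind <- match.arg(kind, names(.KIND_MAXLEN))
  .KIND_MAXLEN[[kind]]
}

#' The configured 64-symbol SMILES base set
#'
#' The published alphabet size (64 symbols + 4 specials = 68) is known, but
#' the symbols themselves were never enumerated; this table is a plausible
#' reconstruction (organic and aromatic atoms, two-character elements, ring
#' digits, bond and branch punctuation) shipped as a plain-text config file
#' that can be replaced without touching code.  Vocabularies can equally be
#' derived from a corpus with [buildVocabulary()].
#'
#' @param path optional path to an alternative symbol table (one symbol per
#'   line); defaults to the file shipped with the package.
#' @return character vector of 64 symbols.
#' @export
smilesSymbols <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "smiles_symbols.txt", package = "triCPI")
  }
  readLines(path, encoding = "UTF-8")
}

.newVocabulary <- function(tokens, kind) {
  new("Vocabulary", symbols = c(specialTokens(), tokens), kind = kind)
}

#' Construct the default vocabulary for a channel
#'
#' `smilesVocabulary()` wraps the configured 64-symbol base set (size 68 with
#' specials); `spsVocabulary()` wraps the full 72-word SPS alphabet (size 76);
#' `aminoVocabulary()` wraps the 20 standard one-letter residue codes.
#'
#' @return a [Vocabulary].
#' @export
smilesVocabulary <- function() .newVocabulary(smilesSymbols(), "smiles")

#' @rdname smilesVocabulary
#' @export
spsVocabulary <- function() .newVocabulary(enumerateSPSAlphabet(), "sps")

#' @rdname smilesVocabulary
#' @export
aminoVocabulary <- function() .newVocabulary(sort(names(.AA_CLASSES)), "amino")

# Greedy longest-match SMILES splitter.  Two-character symbols from the base
# table are matched before single characters; a bracketed atom ("[...]") is
# always one token.  Matching is case-sensitive, so "CO" is carbon + oxygen
# while "Co" is cobalt.
.splitSmiles <- function(s, twoChar = NULL) {
  if (is.null(twoChar)) twoChar <- .smilesTwoChar()
  n <- nchar(s)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      rest <- substr(s, i, n)
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0) stop("unterminated bracket atom in SMILES: ", s)
      tok <- substr(rest, 1L, close)
      i <- i + close
    } else if (i < n && substr(s, i, i + 1L) %in% twoChar) {
      tok <- substr(s, i, i + 1L)
      i <- i + 2L
    } else {
      tok <- ch
      i <- i + 1L
    }
    k <- k + 1L
    out[k] <- tok
  }
  out[seq_len(k)]
}

.smilesTwoCharCache <- new.env(parent = emptyenv())

.smilesTwoChar <- function() {
  if (is.null(.smilesTwoCharCache$v)) {
    syms <- smilesSymbols()
    .smilesTwoCharCache$v <- syms[nchar(syms) == 2L]
  }
  .smilesTwoCharCache$v
}

.splitSequence <- function(x, kind) {
  switch(kind,
    smiles = .splitSmiles(x),
    sps = {
      toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
      toks[nzchar(toks)]
    },
    amino = strsplit(x, "", fixed = TRUE)[[1]]
  )
}

#' Build a vocabulary from a corpus
#'
#' Collects all tokens observed in the corpus (SMILES are split by greedy
#' longest match against the configured symbol table, SPS strings by
#' whitespace, amino-acid sequences per character), deduplicates them and
#' prepends the four special tokens.  Ordering is deterministic: specials
#' first, then tokens in byte-order sort, independent of corpus order.
#'
#' @param corpus character vector of raw sequences.
#' @param kind `"smiles"`, `"sps"` or `"amino"`.
#' @return a [Vocabulary].
#' @examples
#' vocabSize(buildVocabulary(c("CC", "CO"), "smiles"))  # {C, O} + 4 specials
#' @export
buildVocabulary <- function(corpus, kind = c("smiles", "sps", "amino")) {
  kind <- match.arg(kind)
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- unique(unlist(lapply(corpus, .splitSequence, kind = kind)))
  if (length(toks) == 0L) stop("empty corpus")
  .newVocabulary(sort(toks, method = "radix"), kind)
}

#' Tokenize a sequence against a vocabulary
#'
#' Splits the input (SMILES-aware greedy longest match, whitespace for SPS,
#' per character for amino), maps tokens to vocabulary indices and pads to
#' the fixed capacity as start, tokens..., end, pad... .  Sequences longer
#' than `maxLength - 2` are rejected rather than truncated.
#'
#' @param x a single raw string, or for SPS a character vector of words.
#' @param vocab the [Vocabulary] to tokenize against.
#' @param maxLength capacity; defaults to [defaultMaxLength()] of the kind.
#' @param policy `"strict"` errors on unknown tokens; `"unused"` maps them to
#'   the reserved unused index.
#' @return a [TokenSequence].
#' @examples
#' v <- buildVocabulary("CCO", "smiles")
#' tokenize("CC", v, maxLength = 6)
#' @export
tokenize <- function(x, vocab, maxLength = NULL,
                     policy = c("strict", "unused")) {
  policy <- match.arg(policy)
  stopifnot(is(vocab, "Vocabulary"))
  if (is.null(maxLength)) maxLength <- defaultMaxLength(vocab@kind)
  maxLength <- as.integer(maxLength)
  toks <- if (length(x) > 1L) as.character(x) else .splitSequence(x, vocab@kind)
  if (length(toks) > maxLength - 2L) stop("sequence exceeds max length")
  idx <- match(toks, vocab@symbols)
  if (anyNA(idx)) {
    if (policy == "strict") {
      stop("unknown token: ", toks[which(is.na(idx))[1]])
    }
    idx[is.na(idx)] <- 4L
  }
  full <- rep(3L, maxLength)
  full[1L] <- 1L
  if (length(idx)) full[1L + seq_along(idx)] <- idx
  full[length(idx) + 2L] <- 2L
  new("TokenSequence", indices = full, trueLength = length(idx),
      maxLength = maxLength, kind = vocab@kind)
}

#' Recover the raw sequence from a token sequence
#'
#' Inverse of [tokenize()] for in-vocabulary sequences: strips the specials
#' and maps indices back to symbols.  SMILES and amino sequences are returned
#' as a single string, SPS sequences as a character vector of words.
#'
#' @param t a [TokenSequence].
#' @param vocab the [Vocabulary] it was tokenized against.
#' @return character scalar (smiles/amino) or vector of words (sps).
#' @export
detokenize <- function(t, vocab) {
  stopifnot(is(t, "TokenSequence"), is(vocab, "Vocabulary"))
  body <- t@indices[seq_len(t@trueLength) + 1L]
  if (any(body > length(vocab@symbols))) stop("index out of vocabulary range")
  toks <- vocab@symbols[body]
  if (vocab@kind == "sps") toks else paste(toks, collapse = "")
}

# Tokenize many sequences into an n x maxLength integer index matrix.
.tokenizeMatrix <- function(xs, vocab, maxLength = NULL, policy = "strict") {
  if (is.null(maxLength)) maxLength <- defaultMaxLength(vocab@kind)
  rows <- lapply(xs, function(x) tokenize(x, vocab, maxLength, policy)@indices)
  do.call(rbind, rows)
}

#' Serialize a vocabulary to JSON
#'
#' The file stores the kind and the ordered symbol list (specials included);
#' [readVocabulary()] restores an identical object.
#'
#' @param vocab a [Vocabulary].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(kind = vocab@kind, symbols = vocab@symbols),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Vocabulary", symbols = as.character(obj$symbols), kind = obj$kind)
}

#' @describeIn vocabSize Vocabulary method.
#' @export
setMethod("vocabSize", "Vocabulary", function(x) length(x@symbols))

#' @describeIn vocabSymbols Vocabulary method.
#' @export
setMethod("vocabSymbols", "Vocabulary", function(x, includeSpecials = TRUE) {
  if (includeSpecials) x@symbols else x@symbols[-(1:4)]
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary of kind '%s': %d symbols (%d + 4 specials)\n",
              object@kind, length(object@symbols), length(object@symbols) - 4L))
})

setMethod("show", "TokenSequence", function(object) {
  cat(sprintf("TokenSequence (%s): %d real tokens, capacity %d\n",
              object@kind, object@trueLength, object@maxLength))
})
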