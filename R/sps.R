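# Structural property sequence (SPS) encoding: a protein becomes one 4-letter
# word per secondary-structure segment, drawing one letter per column of the
# property table:
#   secondary structure  Alpha/Beta/Coil          -> A/B/C
#   solvent exposure     not exposed/exposed      -> N/E
#   physicochemical      non-polar/polar/acid/base-> G/T/D/K
#   segment length       short/medium/long        -> S/M/L
# 3 x 2 x 4 x 3 = 72 legal words; with the four specials the channel
# vocabulary has 76 entries.

.SS_LETTER <- c(Alpha = "A", Beta = "B", Coil = "C")
.EXP_LETTER <- c(buried = "N", exposed = "E")
.PROP_LETTER <- c("non-polar" = "G", polar = "T", acidic = "D", basic = "K")
.LEN_LETTER <- c(short = "S", medium = "M", long = "L")

# Residue physicochemical classes.  The four classes are fixed; this default
# assignment of the 20 standard residues is configurable via the `classes`
# argument of the encoding functions.
.AA_CLASSES <- c(
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic",
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  Y = "polar", G = "polar",
  A = "non-polar", V = "non-polar", L = "non-polar", I = "non-polar",
  P = "non-polar", F = "non-polar", M = "non-polar", W = "non-polar"
)

#' Default residue physicochemical class table
#' @return named character vector mapping one-letter residue codes to one of
#'   `"non-polar"`, `"polar"`, `"acidic"`, `"basic"`.
#' @export
spsPropertyClasses <- function() .AA_CLASSES

#' Classify residues into the four physicochemical classes
#'
#' @param aa character vector of one-letter residue codes.
#' @param classes class table, by default [spsPropertyClasses()].
#' @param policy `"strict"` errors on unknown codes, `"na"` returns NA.
#' @return character vector of classes.
#' @examples
#' classifyResidue(c("D", "K", "A"))
#' @export
classifyResidue <- function(aa, classes = spsPropertyClasses(),
                            policy = c("strict", "na")) {
  policy <- match.arg(policy)
  cls <- unname(classes[aa])
  if (anyNA(cls) && policy == "strict") {
    stop("unknown residue code: ", aa[which(is.na(cls))[1]])
  }
  cls
}

# Collapse 8-class (DSSP-style) secondary structure codes to the 3-class
# convention, then normalize H/E/C to Alpha/Beta/Coil.
.normalizeSS <- function(ss) {
  eight <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
             T = "C", S = "C", C = "C", "-" = "C")
  ss <- as.character(ss)
  known3 <- c(Alpha = "Alpha", Beta = "Beta", Coil = "Coil")
  out <- ifelse(ss %in% names(known3), ss,
                c(H = "Alpha", E = "Beta", C = "Coil")[eight[ss]])
  if (anyNA(out)) stop("unknown secondary structure code: ",
                       ss[which(is.na(out))[1]])
  unname(out)
}

.checkAnnotations <- function(annotations) {
  if (NROW(annotations) == 0L) stop("empty protein")
  need <- c("aa", "ss", "exposed")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("missing annotation column: ", miss[1])
  annotations$ss <- .normalizeSS(annotations$ss)
  annotations$exposed <- as.logical(annotations$exposed)
  annotations
}

#' Segment a protein along its secondary structure
#'
#' Splits the residue range into maximal runs of identical secondary-structure
#' category.  Segments are contiguous, non-overlapping and exactly cover the
#' protein; exposure and residue identity may vary within a segment and are
#' majority-voted at encoding time.
#'
#' @param annotations data.frame with columns `aa` (one-letter code), `ss`
#'   (H/E/C, Alpha/Beta/Coil, or 8-class DSSP codes) and `exposed` (logical
#'   or 0/1).
#' @return data.frame with columns `start`, `end` (1-based, inclusive),
#'   `length` and `ss`.
#' @examples
#' ann <- data.frame(aa = rep("A", 8), ss = c("H","H","H","E","E","E","C","C"),
#'                   exposed = TRUE)
#' segmentProtein(ann)
#' @export
segmentProtein <- function(annotations) {
  annotations <- .checkAnnotations(annotations)
  r <- rle(annotations$ss)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end, length = r$lengths, ss = r$values,
             stringsAsFactors = FALSE)
}

.majorityExposure <- function(exposed) {
  # tie -> exposed
  if (mean(exposed) >= 0.5) "exposed" else "buried"
}

.majorityProperty <- function(cls) {
  prio <- c("acidic", "basic", "polar", "non-polar")
  counts <- vapply(prio, function(p) sum(cls == p), 1L)
  prio[which.max(counts)]  # which.max breaks ties by priority order
}

.lengthClass <- function(n, thresholds) {
  if (n <= thresholds[["short"]]) "short"
  else if (n >= thresholds[["long"]]) "long"
  else "medium"
}

#' Encode per-residue annotations into an SPS sequence
#'
#' One 4-letter word per secondary-structure segment: the structure letter
#' from the segment's category, the exposure and property letters by
#' per-residue majority vote (exposure ties go to exposed; property ties are
#' broken acidic > basic > polar > non-polar) and the length letter from the
#' segment residue count (short <= `thresholds["short"]`, long >=
#' `thresholds["long"]`, medium in between).
#'
#' @inheritParams segmentProtein
#' @param thresholds named numeric vector with entries `short` and `long`;
#'   defaults to short <= 3 and long >= 8 residues.
#' @param classes residue class table, see [spsPropertyClasses()].
#' @return an [SPSSequence].
#' @examples
#' ann <- data.frame(aa = "K", ss = "H", exposed = TRUE)[rep(1, 5), ]
#' spsWords(encodeSPS(ann))  # "AEKM"
#' @export
encodeSPS <- function(annotations, thresholds = c(short = 3, long = 8),
                      classes = spsPropertyClasses()) {
  annotations <- .checkAnnotations(annotations)
  segs <- segmentProtein(annotations)
  words <- vapply(seq_len(nrow(segs)), function(k) {
    rows <- segs$start[k]:segs$end[k]
    cls <- classifyResidue(annotations$aa[rows], classes)
    paste0(
      .SS_LETTER[[segs$ss[k]]],
      .EXP_LETTER[[.majorityExposure(annotations$exposed[rows])]],
      .PROP_LETTER[[.majorityProperty(cls)]],
      .LEN_LETTER[[.lengthClass(segs$length[k], thresholds)]]
    )
  }, character(1))
  new("SPSSequence", words = words, sourceLength = nrow(annotations))
}

#' Enumerate the full 72-word SPS alphabet
#'
#' The Cartesian product of the four property columns in a fixed order
#' (structure, then exposure, then property, then length letters), yielding
#' exactly 72 distinct 4-letter words.
#'
#' @return character vector of length 72.
#' @export
enumerateSPSAlphabet <- function() {
  grid <- expand.grid(
    len = unname(.LEN_LETTER), prop = unname(.PROP_LETTER),
    exp = unname(.EXP_LETTER), ss = unname(.SS_LETTER),
    stringsAsFactors = FALSE
  )
  paste0(grid$ss, grid$exp, grid$prop, grid$len)
}

#' Read a per-residue annotation table
#'
#' Expects a TSV with columns `position` (1-based), `aa`, `ss` (H/E/C) and
#' `exposed` (0/1).  If a FASTA file is supplied, the residue sequence is
#' checked against the annotation rows (by name if the FASTA has several
#' records and `id` is given).
#'
#' @param path annotation TSV path.
#' @param fasta optional FASTA path with the raw amino-acid sequence.
#' @param id optional FASTA record name to check against.
#' @return data.frame of annotations ordered by position.
#' @export
readResidueAnnotations <- function(path, fasta = NULL, id = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "aa", "ss", "exposed")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("missing annotation column: ", miss[1])
  ann <- ann[order(ann$position), , drop = FALSE]
  if (!identical(as.integer(ann$position), seq_len(nrow(ann)))) {
    stop("annotation positions must be 1..n without gaps")
  }
  if (!is.null(fasta)) {
    seqs <- Biostrings::readAAStringSet(fasta)
    rec <- if (is.null(id)) seqs[[1]] else seqs[[id]]
    fromFasta <- strsplit(as.character(rec), "")[[1]]
    if (!identical(fromFasta, ann$aa)) {
      stop("FASTA sequence disagrees with annotation residues")
    }
  }
  ann
}

#' @describeIn spsWords SPSSequence method.
#' @export
setMethod("spsWords", "SPSSequence", function(x) x@words)

setMethod("show", "SPSSequence", function(object) {
  cat(sprintf("SPSSequence: %d words from %d residues\n  %s\n",
              length(object@words), object@sourceLength,
              paste(utils::head(object@words, 12), collapse = " ")))
})

setMethod("length", "SPSSequence", function(x) length(x@words))
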