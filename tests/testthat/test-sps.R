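test_that("residue classification follows the four-class table", {
  expect_identical(classifyResidue("D"), "acidic")
  expect_identical(classifyResidue("E"), "acidic")
  expect_identical(classifyResidue("K"), "basic")
  expect_identical(classifyResidue("A"), "non-polar")
  expect_identical(classifyResidue("S"), "polar")
  expect_identical(classifyResidue(c("D", "K", "A")),
                   c("acidic", "basic", "non-polar"))
  expect_error(classifyResidue("X"), "unknown residue")
  # total over the 20 standard residues
  expect_false(anyNA(classifyResidue(names(spsPropertyClasses()))))
})

test_that("segmentation decomposes the protein into ss runs", {
  ann <- data.frame(aa = "A", ss = "H", exposed = TRUE)[rep(1, 10), ]
  seg <- segmentProtein(ann)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(1, 10))

  ann2 <- data.frame(aa = "A", ss = c("H","H","H","E","E","E","C","C"),
                     exposed = TRUE)
  seg2 <- segmentProtein(ann2)
  expect_equal(nrow(seg2), 3)
  expect_equal(seg2$length, c(3, 3, 2))
  expect_equal(seg2$ss, c("Alpha", "Beta", "Coil"))

  expect_error(segmentProtein(data.frame()), "empty protein")

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(1:60, 1)
    ann <- data.frame(aa = sample(names(spsPropertyClasses()), n, TRUE),
                      ss = sample(c("H", "E", "C"), n, TRUE),
                      exposed = sample(c(TRUE, FALSE), n, TRUE))
    seg <- segmentProtein(ann)
    expect_equal(sum(seg$length), n)                  # exact partition
    expect_equal(seg$start, c(1, head(seg$end, -1) + 1))  # contiguous
  }
})

test_that("the canonical helix example encodes to AEKM", {
  ann <- data.frame(aa = "K", ss = "H", exposed = TRUE)[rep(1, 5), ]
  expect_identical(spsWords(encodeSPS(ann)), "AEKM")
})

test_that("a short buried alanine coil encodes to CNGS", {
  ann <- data.frame(aa = "A", ss = "C", exposed = FALSE)[rep(1, 2), ]
  expect_identical(spsWords(encodeSPS(ann)), "CNGS")
})

test_that("length thresholds split at 3 and 8 residues", {
  mk <- function(n) data.frame(aa = "K", ss = "H", exposed = TRUE)[rep(1, n), ]
  expect_identical(substr(spsWords(encodeSPS(mk(3))), 4, 4), "S")
  expect_identical(substr(spsWords(encodeSPS(mk(4))), 4, 4), "M")
  expect_identical(substr(spsWords(encodeSPS(mk(7))), 4, 4), "M")
  expect_identical(substr(spsWords(encodeSPS(mk(8))), 4, 4), "L")
})

test_that("majority votes and tie-breaks are deterministic", {
  # exposure tie (2 of 4) -> exposed
  ann <- data.frame(aa = "K", ss = "H", exposed = c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(substr(spsWords(encodeSPS(ann)), 2, 2), "E")
  # property tie basic vs polar -> basic by priority
  ann2 <- data.frame(aa = c("K", "K", "S", "S"), ss = "H", exposed = TRUE)
  expect_identical(substr(spsWords(encodeSPS(ann2)), 3, 3), "K")
  # acidic beats basic on ties
  ann3 <- data.frame(aa = c("D", "K"), ss = "H", exposed = TRUE)
  expect_identical(substr(spsWords(encodeSPS(ann3)), 3, 3), "D")
})

test_that("the SPS alphabet is the full 72-word product", {
  ab <- enumerateSPSAlphabet()
  expect_equal(length(ab), 72)
  expect_equal(anyDuplicated(ab), 0)
  expect_true("AEKM" %in% ab)
  expect_true(all(nchar(ab) == 4))
})

test_that("every encoding lands inside the alphabet and is deterministic", {
  ab <- enumerateSPSAlphabet()
  prots <- genProteins(25, seed = 9)
  for (ann in prots) {
    w <- spsWords(encodeSPS(ann))
    expect_true(all(w %in% ab))
    expect_lte(length(w), nrow(ann))
    expect_identical(w, spsWords(encodeSPS(ann)))    # determinism
  }
})

test_that("8-class secondary structure codes collapse to 3 classes", {
  ann <- data.frame(aa = "A", ss = c("G", "G", "B", "T"), exposed = TRUE)
  seg <- segmentProtein(ann)
  expect_equal(seg$ss, c("Alpha", "Beta", "Coil"))
})

test_that("annotation tables read back with FASTA cross-check", {
  ann <- data.frame(position = 1:4, aa = c("M", "K", "D", "A"),
                    ss = c("C", "H", "H", "C"), exposed = c(0, 1, 1, 0))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKDA"), fa)
  got <- readResidueAnnotations(f, fasta = fa)
  expect_equal(got$aa, ann$aa)
  writeLines(c(">p1", "MKDV"), fa)
  expect_error(readResidueAnnotations(f, fasta = fa), "disagrees")
})
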