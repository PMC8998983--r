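test_that("generated compounds all parse and are seeded", {
  s1 <- genCompounds(60, seed = 21)
  s2 <- genCompounds(60, seed = 21)
  expect_identical(s1, s2)
  expect_false(identical(s1, genCompounds(60, seed = 22)))
  expect_equal(length(genCompounds(1, seed = 1)), 1)
  for (s in s1) {
    g <- parseSmiles(s)
    expect_gte(atomCount(g), 1)
    expect_lte(nchar(s), 40)
  }
  # grammar stays inside the toy element set
  expect_true(all(unlist(lapply(s1, function(s) {
    parseSmiles(s)@elements %in% c("C", "N", "O")
  }))))
})

test_that("generated proteins annotate and encode within the channel cap", {
  ps <- genProteins(40, seed = 31)
  expect_identical(ps, genProteins(40, seed = 31))
  for (ann in ps) {
    expect_gt(nrow(ann), 0)
    expect_true(all(ann$ss %in% c("H", "E", "C")))
    w <- spsWords(encodeSPS(ann))
    expect_lte(length(w), 150)
    tokenize(w, spsVocabulary())        # must fit max length 152
  }
  succeed()
})

test_that("labels equal the mechanism exactly when noise is zero", {
  ds <- tinyDataset(nPairs = 30, noiseSd = 0, seed = 41)
  expect_equal(sampleCount(ds), 30)
  mech <- provenance(ds)$mechanism
  expect_equal(samples(ds)$label, mech$clean)
  # recompute the mechanism from raw features
  w <- mech$weights
  df <- samples(ds)
  recomputed <- vapply(seq_len(nrow(df)), function(i) {
    f <- triCPI:::.compoundFeatures(df$smiles[i])
    p <- triCPI:::.proteinFeatures(strsplit(df$sps[i], " ")[[1]])
    w[["hetero"]] * f[["hetero"]] + w[["ring"]] * f[["ring"]] +
      w[["alpha"]] * p[["alpha"]] + w[["basic"]] * p[["basic"]]
  }, 1)
  expect_equal(df$label, recomputed)
})

test_that("label variance decomposes into mechanism plus noise", {
  cfg <- synthConfig(nCompounds = 150L, nProteins = 40L, nPairs = 5000L,
                     noiseSd = 0.3, seed = 51)
  ds <- genDataset(cfg)
  mech <- provenance(ds)$mechanism
  labelVar <- var(samples(ds)$label)
  expect_equal(labelVar, var(mech$clean) + 0.3^2, tolerance = 0.05)
})

test_that("datasets are reproducible under the seed and split cleanly", {
  cfg <- synthConfig(nCompounds = 20L, nProteins = 8L, nPairs = 100L,
                     noiseSd = 0.2, seed = 61)
  d1 <- genDataset(cfg)
  d2 <- genDataset(cfg)
  expect_identical(samples(d1), samples(d2))
  parts <- splitDataset(d1, valFraction = 0.1, seed = 7)
  expect_equal(sampleCount(parts$train), 90)
  expect_equal(sampleCount(parts$val), 10)
  key <- function(d) paste(samples(d)$compound_id, samples(d)$protein_id)
  expect_length(intersect(key(parts$train), key(parts$val)), 0)
  expect_setequal(c(key(parts$train), key(parts$val)), key(d1))
  # clean labels stay aligned through the split
  expect_equal(provenance(parts$val)$mechanism$clean +
                 (samples(parts$val)$label -
                    provenance(parts$val)$mechanism$clean),
               samples(parts$val)$label)
})

test_that("dataset bundles write the table, corpora and manifest", {
  ds <- tinyDataset(nPairs = 12, seed = 71)
  dir <- tempfile()
  writeDatasetBundle(ds, dir)
  expect_true(file.exists(file.path(dir, "cpi.csv")))
  expect_true(file.exists(file.path(dir, "smiles_corpus.txt")))
  expect_true(file.exists(file.path(dir, "sps_corpus.txt")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$noise_sd, 0)
  expect_equal(man$weights$ring, 1)
  back <- readCPITable(file.path(dir, "cpi.csv"))
  expect_equal(sampleCount(back), 12)
})
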