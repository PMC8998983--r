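# triCPI

Multi-channel neural regression of compound-protein binding affinity in R.

## The problem

Estimating how strongly a small molecule binds a protein target is a central
step in virtual screening and drug repositioning.  `triCPI` regresses a
real-valued affinity on the log10 IC50 scale (lower = stronger inhibition)
from three complementary views of a compound-protein pair:

* the compound's **SMILES string**, tokenized and encoded by a 2-layer GRU
  with additive attention and a 1D CNN readout;
* the protein's **structural property sequence (SPS)** — one 4-letter word
  per secondary-structure segment encoding structure class, solvent
  exposure, dominant physicochemical class and segment length (72 words;
  76 with the start/end/pad/unused specials) — encoded the same way;
* the compound's **2D molecular graph**, processed by a degree-filtered
  graph convolution: per layer L = 1..R and atom a,

      v    = r_a + sum_{u in N(a)} r_u
      r_a' = sigma( v * H[L, clamp(|N(a)|, 1, 5)] )

  with five filters per layer selected by the atom's neighbor count,
  followed by attention pooling over atoms.

An optional fourth channel (bidirectional GRU over the raw amino-acid
sequence) gives the extended variant.  Channel vectors are concatenated
(sequence part first) and a fully connected head predicts the affinity;
training minimizes mean squared error.  The SMILES/SPS channels can be
warm-started by GRU seq2seq autoencoders pretrained on unlabeled corpora.
Evaluation uses RMSE and R² (1 − SS_res/SS_tot), and `screenCompounds()`
ranks a compound library against one target, strongest (lowest predicted
log IC50) first.

All neural components run on a reverse-mode autodiff tape implemented inside
the package and verified against finite differences; no external
deep-learning framework is required.

## Worked example

```r
library(triCPI)

## seeded synthetic study: 300 labeled pairs, known mechanism + noise
ds <- genDataset(synthConfig(nCompounds = 60, nProteins = 15,
                             nPairs = 300, noiseSd = 0.3, seed = 1))
parts <- splitDataset(ds, valFraction = 0.1, seed = 1)

## small three-channel model, trained end to end
cfg <- channelConfig(dims = list(smiles = 32, sps = 32, graph = 32),
                     convFilters = 32, kernel = 3, headHidden = 64)
model <- trainUnified(parts$train, config = cfg,
                      epochs = 20, lr = 3e-3, batchSize = 64, seed = 1)

evaluateModel(model, parts$val)
#> $rmse
#> [1] 0.4312331
#> $r2
#> [1] 0.6952064
#> $r2_alt
#> [1] 0.499002
#> $n
#> [1] 30

## rank five candidate compounds against one protein
prot <- samples(parts$val)$sps[1]
screenCompounds(model, list(sps = prot),
                c("OCCN", "CCCC", "C1CCCC1", "NC(CO)CN", "CCC"))
#>   rank compound_id   smiles     score status
#> 1    1           5      CCC 0.3777342     ok
#> 2    2           2     CCCC 0.5105114     ok
#> 3    3           1     OCCN 1.0549998     ok
#> 4    4           4 NC(CO)CN 1.3529844     ok
#> 5    5           3  C1CCCC1 1.3975545     ok
```

The held-out RMSE (0.43) sits well below the label standard deviation
(about 1) and R2 = 0.70 says the model explains most of the mechanism
variance even at this small training size (270 pairs).  In the screen,
scores are predicted log10 IC50, so *lower* is *stronger* and rank 1 goes
to the plain alkane `CCC`: the synthetic mechanism adds a positive label
contribution per O/N atom and for ring presence, so heteroatom-rich and
cyclic compounds are (correctly) predicted to bind this target more weakly.
Unparsable SMILES are kept in the ranking with `status = "failed"` rather
than silently dropped.

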