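# coevodist

Estimation of inter-residue distance distributions directly from a
multiple sequence alignment (MSA), for structural bioinformaticians who
work on contact/distance prediction and want a self-contained, desk-scale
implementation of the end-to-end co-evolution architecture — encoder,
outer-product aggregator and 2D residual distance estimator — together
with the surrounding pipeline: PSICOV-style sequence reweighting,
contact metrics, a distance-potential structure realizer, and a fully
synthetic benchmark so nothing needs to be downloaded.

## The model in brief

An MSA with target length *L* and *K* homologs is represented as *K*
pairwise target–homolog alignments, each position a 41-element binary
vector (20 target channels, 20 homolog channels, 1 gap). A 1D
convolutional residual encoder embeds every homolog row independently
into C channels per residue, X_k ∈ R^{C×L}. With PSICOV weights
w_k (inverse count of ≥80%-identical neighbours, M_eff = Σ w_k), the
co-evolution aggregator forms

    f(i)   = (1/M_eff) Σ_k w_k X_k(i)
    g(i,j) = (1/M_eff) Σ_k w_k [X_k(i) ⊗ X_k(j)]
    h(i,j) = concat(f(i), f(j), g(i,j)),   D = 2C + C²  (4224 at C = 64)

and a 2D dilated residual network maps h to a 37-bin distance
distribution per pair (bins (0, 2.5], (2.5, 3.0], …, (19.5, 20.0],
(20, ∞)). Contact probability is the mass below 8 Å. Distograms convert
to smooth DFIRE-style pair potentials, minimized at CA level to realize
coordinates. Ablation variants (`no_R`, `no_E_R`, `no_OP`) reproduce the
contribution analysis of the three stages.

## Worked example

```r
library(coevodist)

# a synthetic benchmark target: toy fold + coupled MSA (L = 48, K = 256)
tgt <- generateToyTarget(L = 48, K = 256, seed = 7)
msa <- targetMsa(tgt)
mEff(sequenceWeights(msa))
#> [1] 191.9684

# model-free check that the planted co-evolution is recoverable
mi <- msaMutualInformation(msa)
contactPrecision(mi, targetContacts(tgt), fraction = 5, "long")$precision
#> [1] 1

# a small trained model (see the vignette for the study configuration)
cfg <- toyModelConfig()
model <- buildVariant("full", cfg$enc, cfg$head, seed = 1)
trained <- trainModel(model, lapply(1:20, function(s)
  generateToyTarget(seed = s)), trainConfig(steps = 100, seed = 1))
dg <- modelPredict(trained$model, msa)
ppc(contactProbability(dg))

# realize coordinates from an idealized distogram and score the recovery
coords <- generateToyStructure(20, seed = 3, compactness = 0.6)
dgSharp <- sharpDistogram(coords)
fold <- realizeStructure(distogramToPotential(dgSharp), dgSharp, seed = 1)
distanceMatrixRms(fold$coords, coords)
#> [1] 0.001002347
```

The `mEff` value says roughly 192 of the 256 rows are effectively
independent at the 80% identity threshold; the mutual-information
precision 1 means all of the top-10 long-range MI pairs are true
contacts; the final number is the RMS disagreement (in Å) between the
realized and true pairwise distances — recovery to well under an
Ångström.

A command-line wrapper over the same functions ships in
`inst/cli/coevodist.R` with `simulate`, `train`, `predict`, `evaluate`
and `fold` subcommands.

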