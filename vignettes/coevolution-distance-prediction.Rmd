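---
title: "Estimating inter-residue distances from residue co-evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating inter-residue distances from residue co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

Residue pairs that are close in a folded protein tend to mutate in a
correlated way across the protein family, so a multiple sequence alignment
(MSA) carries a noisy image of the contact map. Classical direct-coupling
analysis compresses the MSA into pairwise column statistics — a covariance
matrix or a Potts model — before looking for couplings, and that compression
is lossy: two alignments can agree on every single-column and every
pairwise statistic yet differ in their higher-order structure (the package's
`generateParityCounterexample()` constructs exactly such a pair). This
package implements the alternative end-to-end route: learn the co-evolution
statistic itself, directly from the alignment.

The pipeline has three learned stages plus a fixed reweighting step:

1. **Pairwise encoding** (`encodePairwise()`). An MSA with target length
   $L$ and $K$ homologs is treated as $K$ pairwise target–homolog
   alignments. Every position of every pair becomes a 41-element binary
   vector: 20 one-hot channels for the target residue, 20 for the homolog
   residue and one gap channel. The channel order is fixed by
   `aaAlphabet` (`ARNDCQEGHILKMFPSTWYV`, gap last) so encodings are
   reproducible.

2. **Sequence reweighting** (`sequenceWeights()`). Following the PSICOV
   convention, homolog $k$ receives weight $w_k = 1/n_k$ where $n_k$
   counts the homologs (including $k$) with at least 80% sequence
   identity to it, and $M_\mathrm{eff} = \sum_k w_k$ is the effective
   alignment depth. Identity is computed over all $L$ target columns
   with the gap treated as an ordinary character — deterministic, and
   the convention used by the reweighting literature this follows.

3. **MSA encoder** (`buildEncoder()`, `encodeMsa()`). A 1D convolutional
   residual network embeds each homolog row independently into $C$
   channels per residue ($X_k \in \mathbb{R}^{C\times L}$). Reference
   scale is 8 pre-activation residual blocks (two batch-norms, two
   kernel-3 convolutions, ELU) at $C = 64$, i.e. 16 convolution layers
   and a receptive field of $1 + 16\cdot 2 = 33$ residues
   (`receptiveField(16, 3)`). The 41-to-$C$ input projection is a
   kernel-1 convolution counted separately from the blocks, which keeps
   the receptive-field arithmetic exact.

4. **Co-evolution aggregator** (`aggregateH()`). Per residue,
   $f(i) = \frac{1}{M_\mathrm{eff}}\sum_k w_k X_k(i)$; per residue pair,
   the weighted average outer product
   $g(i,j) = \frac{1}{M_\mathrm{eff}}\sum_k w_k\,[X_k(i)\otimes X_k(j)]$.
   The pair feature is the concatenation
   $h(i,j) = \mathrm{concat}(f(i), f(j), g(i,j))$ with
   $D = 2C + C^2$ channels — 4224 at $C=64$
   (`aggregatedChannels(64)`). Because the sum over homologs is
   associative, `aggregateH()` streams over homolog chunks: peak memory
   is independent of $K$, and the result is invariant to the chunk size.
   When the encoder is bypassed and $X_k$ is the raw one-hot encoding,
   $g$ reduces exactly to the weighted column pair-frequency table, and
   subtracting $f\otimes f$ gives the classical DCA covariance — the
   bridge that makes the covariance baseline (`msaCovariance()`) an
   independent oracle for the aggregator.

5. **Distance estimator** (`buildHead()`, `predictDistogram()`). A 2D
   dilated residual network (reference scale 72 blocks, 96 channels;
   "shallow" variant 36 blocks) maps $h$ to 37 logits per pair. Distance
   is discretized into 37 left-open intervals:
   $(0, 2.5], (2.5, 3.0], \dots, (19.5, 20.0], (20, \infty)$
   (`binSpec()`), turning regression into classification. Logits are
   symmetrized by averaging the $(i,j)$ and $(j,i)$ entries before the
   softmax, which keeps the per-pair normalization exact. The contact
   probability of a pair is the summed mass of the bins at or below
   8 Å — the first 12 bins (`contactProbability()`).

## Ablation variants

`buildVariant()` assembles the contribution-analysis models: `full`
(encoder + aggregator + 2D head), `no_R` (per-pair linear classifier
instead of the 2D head), `no_E_R` (additionally drops the encoder, so the
aggregator works on raw 41-channel encodings — the covariance-equivalent
baseline), and `no_OP` (drops the outer-product block, leaving
$h(i,j) = \mathrm{concat}(f(i), f(j))$ with $D = 2C$).

# Training

`trainModel()` minimizes the masked 37-way cross-entropy with Adam
(constant learning rate). The optimizer is deliberately unremarkable: the
architecture, not the optimization schedule, is the subject here. Per
step, the MSA is re-subsampled to at most `maxMsaSample` rows (a form of
data augmentation as well as a memory cap; the reference setup caps at
1000) and a random crop of at most `cropSize` × `cropSize` (default 128)
consecutive-residue pairs is drawn when $L$ exceeds the crop. Pairs with
$|i-j|\le 1$ or missing coordinates are masked out of the loss. Training
is bit-reproducible under a fixed seed in single-threaded execution.
Batch-norm statistics treat the $K$ homolog rows (times positions) as the
batch axis — the rows are exchangeable samples of the same alignment —
and prediction always runs in evaluation mode with frozen running
statistics.

# The synthetic benchmark

Everything is testable without downloads. `generateToyTarget()` builds:

* **A toy structure**: a self-avoiding chain with exact 3.8 Å bonds, a
  centripetal compactness bias, and a 3.2 Å clash floor
  (`generateToyStructure()`). At the default `compactness = 0.55` a 48-mer
  has on the order of 20 long-range contacts (|i−j| ≥ 24) out of 300
  candidate long-range pairs, so the chance level of long-range top-L/5
  precision is about 0.07. The bias is annealed away while a placement
  keeps clashing, which keeps growth robust across the whole compactness
  range while preserving monotonicity (more compact ⇒ more long-range
  contacts).

* **A coupled MSA** (`generateCoupledMsa()`): Gibbs samples from a
  pairwise sequence model. A sparse set of coupling edges is chosen from
  the contact map — separation ≥ 6, at most 2 edges per column, largest
  separations first — mimicking the sparse strong couplings that drive
  real co-evolution analysis. Each edge carries two favoured letter
  pairs, the target pair and a random alternative pair, rewarded with
  coupling strength $J$ (default 2, in log-odds units). Coupled columns
  put equal conservation fields on their two favoured letters, so both
  pair modes are genuinely occupied across homologs and the columns are
  *variable* — as co-evolving sites are — while uncoupled columns mutate
  i.i.d. at rate 0.35. Each homolog row is an independent chain
  (random initialization, 100 burn-in sweeps); a single thinned chain is
  available but mixes poorly between pair modes on coupled graphs, which
  is why independent chains are the default. The defaults were fixed
  once, by the benchmark-realism requirement that planted contacts be
  recoverable by model-free mutual-information ranking (median long-range
  top-L/5 precision above 0.5) while the alignment keeps a healthy
  effective depth ($M_\mathrm{eff}$ well above 100 at $K = 256$):
  stronger couplings percolate modes across edge paths and collapse
  $M_\mathrm{eff}$; weaker ones are not recoverable.

* **The moment-matched counterexample**
  (`generateParityCounterexample()`): two alignments whose three
  designated columns realize the even- versus odd-parity patterns of a
  two-letter code, each pattern exactly $K/4$ times. All single-column
  compositions and pairwise joint frequencies — hence the covariance
  matrices — are *exactly* equal, while the three-way joints have
  disjoint support (total variation 1). Any predictor that is a function
  of first- and second-order statistics (in particular the `no_E_R`
  feature path) provably produces identical output for both alignments.
  The construction needs $K \equiv 0 \pmod 4$ for exact matching. The
  remaining columns are identical filler, long enough (default $L = 20$)
  that the sequence weights also coincide.

On mutual information: the plug-in MI estimator is biased upward by
roughly $(r-1)(c-1)/2K$ nats for columns with $r$ and $c$ observed
letters, which at $K = 256$ swamps the planted signal for 20-letter
columns. `msaMutualInformation()` therefore subtracts this first-order
(Miller–Madow) term by default, with the average-product correction
available as well — both standard practice in MI-based contact ranking.

## What the benchmark does and does not emulate

It emulates: target-coordinate alignments, sequence redundancy (handled
by reweighting), planted pairwise couplings at spatial contacts,
conservation, and optional gaps. It does **not** emulate phylogenetic
tree structure, indel patterns, secondary-structure regularities
(helices/strands and their diagonal contact patterns), or biochemically
realistic substitution preferences. Consequently, passing the toy
ablation shows that the architecture can extract higher-order co-mutation
signal end-to-end; it does not certify performance on real families. One
concrete difference matters for the ablation ordering: on real proteins a
2D residual network can exploit geometric contact-map patterns even
without pair statistics, an advantage the pattern-free toy maps do not
offer to the outer-product-free variant.

# Structure realization

`distogramToPotential()` converts distograms to smooth pair potentials in
the distance-scaled reference-state (DFIRE) spirit:
$E_{ij}(d) = -\log\frac{p_{ij}(\mathrm{bin}(d)) + \varepsilon}
{p_{ij}(\text{last bin}) + \varepsilon}$, cubic-spline smoothed over the
bin centers, flat beyond 20 Å, with $\varepsilon = 10^{-4}$; the last,
open bin acts as the no-information reference, so a uniform distribution
yields an identically zero potential. `realizeStructure()` minimizes the
summed potential plus harmonic 3.8 Å chain-bond restraints with L-BFGS
from several restarts. The first restarts start from a classical-scaling
(distance-geometry) embedding of the modal distances, the rest from
random walks; since distances are blind to chirality, both enantiomers of
every start are refined and the lower-energy one kept. Recovery
experiments use `sharpDistogram()`, which discretizes a narrow Gaussian
(σ = 0.5 Å) around the true distances: fully concentrated single-bin
distograms would give potential wells with no gradient beyond a quarter
Ångström, which no continuous minimizer can find from a generic start.
When comparing a realized structure against ground truth, the
distance-matrix RMS is chirality-blind, while the Kabsch RMSD
(`kabschRmsd()`, proper rotations only) is reported for the better of the
two enantiomers.

# Numerical and design choices

* Bin boundaries are left-open, right-closed; d = 2.5 Å falls in bin 1.
* Top-$k$ contact cuts use $k = \mathrm{round}(L/\text{denominator})$,
  minimum 1, with ties broken lexicographically by $(i,j)$ — fully
  deterministic ranking.
* "Long range" is $|i-j| \ge 24$, medium 12–23, short 6–11; pairs with
  $|i-j| \le 1$ are excluded from every metric.
* Nonstandard residues (B, Z, X, U, O) encode as an all-zero amino-acid
  block rather than invented pseudo-counts.
* The target is kept as its own first homolog row by default, so a
  single-sequence MSA degrades gracefully ($K \ge 1$, all weights well
  defined).
* Accumulations (aggregator, batch-norm statistics) run in double
  precision.
* Dilations cycle through (1, 2, 4, 8) by default — the common practice
  for dilated contact-map networks; the schedule is configurable.
* Residue indices are 1-based in every user-facing structure (R
  convention); compiled kernels use 0-based offsets internally.

# The toy-scale study configuration

The reference architecture (C = 64, 72-block head) and training corpus
(tens of thousands of domains) are far beyond a desk-scale package check.
The packaged study (`toyModelConfig()`, `ablationStudy()`) therefore uses
an encoder with 1 residual block at C = 8, a head with 2 blocks at 16
channels (dilations 1, 2), 60 training targets and 30 disjoint evaluation
targets of L = 48 and K = 256, per-step subsampling to 32 rows, Adam at
5·10⁻³ for 400 steps, and 5 replicate seeds. These sizes were chosen once
as the smallest configuration at which the full model's learning curve
clearly separates from both ablations; the vignette's ordering claims are
medians over all (seed × evaluation-target) cells. With fewer training
targets the full model memorizes target-sequence patterns instead of
generalizing — visible as a train/evaluation precision gap — which is why
the training set is three times larger than a naive split of the
30-target benchmark would give.

# Known limitations

* The per-pair linear classifier of `no_E_R` is a weaker reader of the
  covariance-style features than a full 2D network would be; it is the
  faithful "aggregator only" ablation, not the strongest possible
  covariance baseline.
* Gibbs sampling with independent chains leaves residual correlation
  between the planted modes of edges that share a column.
* The CA-level realizer recovers geometry from good distograms but makes
  no claim about full-atom refinement.
* At toy scale the ablation margins are a few tenths of precision and
  seed-noisy; the full-versus-ablation gap is robust, the relative order
  of the two weak ablations is not always.
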