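---
title: "Detecting microRNA target sites from duplex-structure features"
author: "MINNTarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microRNA target sites from duplex-structure features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MicroRNAs repress messenger RNAs by base-pairing with short sites, usually in
the 3'UTR. Recognition is dominated by the seed region (microRNA positions
~2-8), but non-canonical sites with imperfect seeds and 3'-compensatory
pairing are common in crosslinking data. Purely thermodynamic predictors
(minimum-free-energy hybridization) accept far too many sites, because many
3'UTR windows can form a stable duplex without being functional; purely
sequence-based deep models are hard to interpret. The approach implemented
here sits between the two: it *learns* which base pairs — by position within
the duplex and by pair type — distinguish validated target sites from
thermodynamically plausible decoys, predicts an explicit duplex secondary
structure from those learned preferences, and feeds structure-derived feature
images into a small convolutional classifier.

All samples are fixed-size: a microRNA of 18-25 nt, right-padded with `-` to
25 symbols, against a 25-nt candidate target site (CTS). Site windows are
stored in the 3'-to-5' orientation of the mRNA, so that microRNA position
*i* faces site position *i* — the natural antiparallel geometry written as
two index-aligned strings. Positions are 0-based everywhere.

## The base-pairing preference model

Every possible canonical pairing between the two strands is a binary
feature: 25 x 25 positions x 6 pair types (AU, CG, GC, GU, UA, UG) = 3,750
single-pair features; double base pairs restricted to target-start offsets
`d = j - i` in [-2, 2] give 25 x 5 x 36 = 4,500; triples with `d` in [-1, 1]
give 25 x 3 x 216 = 16,200 — 24,450 bits in total (`featureCount()`,
`encodeFeatures()`). Runs that would cross position 24 on either strand have
no feasible bit; the index space keeps the full printed size and those bits
are permanently zero.

A single sigmoid output neuron over these bits (`trainPreference()`) is
fitted with minibatch Adam on binary cross-entropy. The weights are
zero-initialized: a one-layer model has no symmetry to break, and zero
initialization makes training exactly reproducible from the shuffle seed
alone. Defaults are 5 epochs and batch 128 (the grid optimum for this model;
`gridSearchPreference()` searches epochs {5, 10, 20, 30, 40} x batch
{32, 64, 128, 256} by validation AUPRC, ties toward the smaller
configuration). The learning rate (1e-3) and optimizer are package choices
and configurable; class reweighting is deliberately not applied.

The learned weights, viewed positionally, form the DP scoring dictionary
(`scoreDict()`, `scoreLookup()`). The bias is excluded — a constant offset
per matched run would bias the DP toward structures with more runs
regardless of evidence. Runs of length 2-3 whose offset falls outside the
double/triple feature window score as the sum of their single-pair weights,
which exist at every position combination; this keeps the DP total defined
over the whole table without inventing weights for features that were never
trained.

## The duplex dynamic program

`fillDPTables()` fills a 25 x 25 scoring table S1, backpointer table BT1 and
free-energy table MFE1 over prefixes of the two strands:

    S1[i][j] = max( S1[i-1][j],                      # skip a microRNA base
                    S1[i][j-1],                      # skip a site base
                    S1[i-k][j-k] + w(run ending at (i, j), k) ),  k = 1..3

with row and column 0 fixed at zero. Because case three requires the
predecessor cell to exist, no run can pair position 0 of either strand —
matching the observation that the first nucleotide of the microRNA is buried
in Argonaute and unavailable for pairing. Every pair of a run must be
canonical (GU wobble included) and pad-free. Ties take a fixed precedence
(diag-3 > diag-2 > diag-1 > skip-microRNA > skip-site), which favors longer
matched runs and makes backtracking deterministic; any fixed order is valid
since ties carry equal weight.

`backtrackDuplex()` reconstructs the optimal structure; its total weight is
recomputed from the run decomposition and must equal `S1[24][24]` exactly
(asserted in the tests to machine precision).

### Free energies

`duplexDg37()` evaluates a structure at 37 degrees C as

    dG37 = +4.09 (intermolecular initiation)
         + sum of nearest-neighbor stacks over gap-free adjacent pairs
         + bulge initiation per one-sided gap
         + internal-loop initiation per two-sided gap
         + 0.45 per helix terminus closed by an AU/UA/GU/UG pair

Only the category-level terms above enter: sequence-dependent terminal
mismatches, loop-asymmetry corrections and coaxial stacking are deliberately
omitted. Consequences of that reading, all covered by tests: a bulge
interrupts stacking even at size 1; a lone pair is a helix whose two termini
coincide, so a weak lone pair is penalized twice; an empty structure has no
initiation event and dG = 0. The GU end penalty follows the standard Turner
convention of treating GU/UG termini like AU/UA ones, although the term is
usually named after AU alone. Loop tables cover sizes 1-30 and are extended
with the Jacobson-Stockmayer form `dG(n) = dG(30) + 1.07856 * log(n/30)`
(1.75 * RT at 310 K); internal loops of size 1 cannot occur and their table
entry exists only for totality. The stacking and loop values are the Turner
2004 set, shipped as plain TSV under `inst/extdata/` (Watson-Crick stacks at
their published two-decimal values; GU stacks at the 0.1 kcal/mol resolution
of the distributed parameter set).

MFE1 is defined cell-wise as the energy of the structure backtracked from
that cell. It is filled incrementally during the DP sweep by tracking, per
cell, the energy and last paired position of its backtracked structure;
stacking a new run removes the previous terminal penalty and adds the
junction stack, a gapped run adds the loop term and opens a new helix. The
incremental fill is validated against the direct evaluator on random cells —
the definition is the direct evaluation, the incremental scheme is only an
O(n^2) shortcut.

## The four input channels

`buildStack()` derives four 25 x 25 matrices per sample (microRNA on rows,
site on columns):

* `mx1` — the predicted structure: the base-pair probability of each
  predicted pair at its (r, c) cell, zero elsewhere;
* `dps` — the full DP scoring table (all substructure weights);
* `dpm` — the MFE table (thermodynamic stability of those substructures);
* `bp` — the base-pair probability of *every* cell, canonical and
  non-canonical, from the rRNA-derived frequency table.

The probability table was estimated from base-pair counts in human rRNA
crystal structures and is embedded as data (`basePairProbTable()`); the pad
symbol never pairs and yields 0.

The channels have incompatible natural ranges (probabilities in [0, 1], DP
weights unbounded, energies in tens of kcal/mol), so a per-channel min-max
scaler is fitted on the training split, stored with the model, and applied
before every prediction (`fitChannelScaler()`). Scaling is on by default;
`minnConfig(scale = FALSE)` feeds raw channels for strict fidelity to a
description that never mentions input scaling. A constant channel falls back
to the identity with a warning.

## The multi-input classifier

`trainMinn()` builds four parallel branches with identical architecture —
three rounds of 3x3 same-padding convolution (filters 32/64/128), ReLU, 2x2
max-pooling and dropout — whose flattened outputs are concatenated into a
dense head (128, then 64 units, dropout 0.25, one sigmoid output). With
floor pooling the spatial plan per branch is 25 -> 12 -> 6 -> 3; same
padding plus floor pooling is the only plan that keeps three pooling stages
feasible on a 25 x 25 input, and is adopted as the package's reading of the
architecture diagram. Only the 3x3 kernel of the selected architecture is
implemented; the kernel and layer counts were architecture-search decisions,
not tunables of the method.

Training is minibatch Adam (learning rate 1e-3, a documented package choice)
on binary cross-entropy for exactly `epochs` epochs — no early stopping; the
history always has one row per epoch. Defaults are 20 epochs and batch 256,
the grid optimum; `gridSearchMinn()` mirrors the search over epochs
{5, 20, 30, 40} x batch {32, 64, 128, 256, 512}. The forward/backward pass
is implemented in vectorized base R (im2col convolution over BLAS matrix
products) and is verified against finite-difference gradients in the test
suite. All randomness (initialization, shuffling, dropout) flows from the
config seed, so training is bit-reproducible; prediction is deterministic
and chunked, so batch composition cannot change results.

The classification threshold is chosen on validation predictions at the
precision/recall intersection (below) and stored with the model.
`scanUtr()` slides a 25-nt window across a 3'UTR (0-based half-open
coordinates), featurizes each window with the ScoreDict stored in the model,
and reports probabilities and calls at the stored threshold.

## Dataset construction and the synthetic corpus

`extractPositive()` cuts the 25-nt validated window; `generateNegatives()`
draws shuffled non-overlapping windows from the same UTR (excluding the
positive site) and keeps up to `maxN = 10` whose DP-predicted duplex has
dG37 < 0 — decoys that are thermodynamically plausible yet not validated
sites. The original construction used an external hybridization tool for
this filter; this package deliberately uses its own DP + energy model
instead, so the filter and the features share one thermodynamic view and no
external dependency is required. Because no preference model exists before
a corpus does, filtering uses a fixed built-in dictionary
(`stabilityScoreDict()`): a run scores the negated Turner stacking energy of
its internal steps minus a 0.6 opening cost, which makes the DP behave like
a generic stability folder (contiguous helices, no isolated weak pairs).
The 0.6 cost approximates the per-helix loop/initiation burden on the
energy scale; it was chosen once, by that argument, when the generator was
designed. Under it roughly a third of random 25-nt windows against a random
microRNA pass the dG < 0 filter, so a 300-nt UTR comfortably yields the
requested decoys.

`synthCorpus()` emulates the study design without downloads: random
microRNAs of 20-25 nt; one implanted site per 300-nt UTR that is the
index-aligned complement of the microRNA with a perfect seed (positions
1-7), 3'-compensatory pairing of the last four unpadded positions with
probability 0.5, and up to two random mismatches in the middle; negatives
drawn by the procedure above; implant coordinates recorded as ground truth.
Its defaults (100 positives, up to 5 decoys each, 300-nt UTRs — about 600
samples) are the study conditions of the package's own end-to-end checks,
split 2/3 : 1/6 : 1/6 into train/validation/test.

What the generator does *not* emulate: real 3'UTR base composition and
repeat structure, CLASH/reporter-assay noise, non-canonical seeds (G-bulge
or wobble seeds), expression context, or multiple sites per UTR. Passing
the end-to-end tests therefore demonstrates that the pipeline is implemented
coherently and can recover a planted, seed-driven signal — it says nothing
about accuracy on biological corpora, whose headline numbers require the
scraped experimental datasets and are out of scope here.

## Evaluation protocol

`prCurve()` evaluates precision, recall and specificity at 100 thresholds
traversed from 1 down to 0. The grid is the evenly spaced values k/99: a
nominal step of 0.01 would give 101 points, and the printed optimal
thresholds (0.2121 = 21/99, 0.3232 = 32/99, 0.9899 = 98/99) pin the grid to
exactly 100. A sample is called positive when its score is >= the threshold.
When nothing is called positive, precision is defined as 1 (and NPV as 1
when nothing is called negative) — the usual PR-curve convention, which also
implies that a literally constant scorer evaluates to (1 + prevalence)/2
under the fixed-grid trapezoid; the random-classifier baseline ("AUPRC of a
random scorer equals the positive prevalence") holds for random continuous
scores and is asserted that way in the tests.

`auprc()` is the trapezoid sum over the grid exactly as traversed,
`sum((R[i+1] - R[i]) * (P[i+1] + P[i]) / 2)`, clipped to [0, 1].
`optimalThreshold()` picks the grid threshold minimizing |P - R|, breaking
ties toward the larger F1 and then the smaller threshold.

`bootstrapCompare()` resamples the test set with replacement at full size
(default 1000 iterations), recomputes both methods' AUPRC per resample, and
reports the mean difference, the one-sided p-value as the proportion of
resamples with difference <= 0 (identical scorers therefore give exactly
p = 1 under this convention), 95% percentile confidence intervals per
method, and both conventions of relative difference (mean-difference-based
and point-estimate-based — published relative differences mix the two).
Single-class resamples are redrawn and counted.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at reduced
size, a deliberate package choice so the whole analysis reruns in minutes on
one core: the ~600-sample corpus above, the preference model at its default
5 x 128, and the classifier at filters 8/16/32, dense 32/16, 10 epochs,
batch 32. The printed full architecture (32/64/128, dense 128/64, 20 epochs,
batch 256) remains the package default for real use. Other numerical
choices: DP and backtrack identities are asserted to machine precision
(1e-12); the AUPRC implementation must agree with an independent trapezoid
to 1e-9; energies to 1e-10; the finite-difference gradient check to 1e-5
relative error.

## Known limitations

* The preference model generalizes weakly at small corpus sizes (positional
  features are sample-specific); its role here is to supply DP weights, not
  to classify on its own.
* The energy model is intentionally category-level; absolute dG values
  differ from full nearest-neighbor implementations that include terminal
  mismatches and asymmetry terms.
* The DP forbids crossing pairs, intramolecular folding and pseudoknots, and
  enumerates no suboptimal structures.
* Scanning evaluates every window independently; overlapping calls are not
  merged into site-level predictions.
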