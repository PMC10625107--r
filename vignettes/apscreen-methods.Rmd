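---
title: "Screening self-assembling oligopeptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening self-assembling oligopeptides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

apscreen implements a screening stack for short self-assembling peptides:
score definitions built on the aggregation propensity (AP), a
transformer-based regression network (TRN) that predicts AP from sequence,
sequence-space sampling and enumeration, aggregation-law statistics, and a
transferability analysis for concatenated and mixed two-pentapeptide systems.
This vignette explains the models, the tunable parameters, and the design
decisions taken where the methodology left genuine choices open.

## Aggregation propensity and the corrected scores

In coarse-grained molecular dynamics (CGMD) screens of peptide self-assembly,
the aggregation propensity of a simulated box of peptides is the ratio of the
solvent-accessible surface area at the start and end of the run,

$$\mathrm{AP} = \frac{\mathrm{SASA}_{initial}}{\mathrm{SASA}_{final}},$$

so AP > 1 means surface was buried, i.e. the peptides clustered.
`ap_from_sasa()` consumes such SASA pairs; the simulations themselves are out
of scope for this package, which treats AP labels as input (or generates them
with the built-in surrogate, below).

Hydrophilicity is summarized by the Wimley–White whole-residue scale:
$\log P = \sum_{i=1}^{n} \Delta G_{\mathrm{woct},i}$, the summed free energy
of transfer from water to *n*-octanol (kcal/mol) over the $n$ residues, with
the charged side-chain forms for D, E, K, R and neutral histidine, as
appropriate at neutral pH. The constants ship as a versioned CSV
(`inst/extdata/wimley_white_octanol.csv`).

Primed quantities denote min–max normalization to $[0,1]$. For $\log P'$ the
bounds are the *theoretical* length-$n$ extremes — homopolymers of the most
hydrophobic (W) and most hydrophilic (D) residues — rather than the empirical
range of any sample. This convention is pinned by the test suite: all ten
published per-pentapeptide $\log P'$ values in the worked-example table
reproduce to ±0.001 under it, which would not hold for sample-based bounds.
It also makes $\log P'$ comparable across peptide lengths.

Two corrected scores bias the raw (normalized) prediction $\mathrm{AP}'$
toward soluble aggregators:

$$\mathrm{AP_{H}} = \mathrm{AP}'^{\,2} \cdot \log P'^{\,0.5}, \qquad
\mathrm{AP_{HC}} = \mathrm{AP_{H}} \cdot
\exp\!\left(-\frac{(\log P' - \mu)^2}{2\sigma^2}\right),$$

with $\mu = 0.4113$ and $\sigma^2 = 0.0657$ the mean and variance of
$\log P'$ among experimentally validated aggregating pentapeptides. These are
configuration constants (`hc_params()`), not fitted by the package: the
underlying experimental set is not distributed with it. $\mathrm{AP_{HC}}$ is
zero at $\log P' = 0$, equals $\mathrm{AP_H}$ exactly at $\log P' = \mu$, and
suppresses the fully soluble extreme ($\log P' = 1$) by more than an order of
magnitude — the property tests assert annihilation at both extremes and
unimodality in $\log P'$.

For $\mathrm{AP}'$ itself the normalization population is caller-specified
(`normalize_scores()`), because the defining population of the published
primed values is not recoverable; the constants used are persisted with every
score set and written into every output file header.

## Sequence space and Latin-hypercube sampling

Sequences are strings over the 20 standard amino acids, length 1–10. The
pentapeptide space holds $20^5 = 3.2$ million sequences; decapeptides
$20^{10}$; unordered two-component mixtures of a base space of size $N$ add
$N(N+1)/2$ systems, which takes penta-to-deca screening beyond $10^{13}$
candidate systems.

Latin-hypercube sampling on a categorical product space is not uniquely
defined. `lhs_sample()` treats each position as one continuous LHS dimension
(stratified sampling via `lhs::randomLHS`), then maps each coordinate
$u \in [0,1)$ to residue $\lfloor 20u \rfloor$ of the alphabetically ordered
alphabet. The choice has two consequences that the tests rely on: marginal
balance is exact whenever the sample size is a multiple of 20 (8000 samples
put every residue exactly 400 times at every position), and the draw is fully
reproducible from one integer seed. Duplicate strings can still occur
(stratification constrains positions, not joint identity); they are kept, to
preserve the marginal balance, and flagged in an attribute.

Mixed systems are order-insensitive (`A+B` is `B+A`); the canonical form
sorts the two components lexicographically. Training data for mixtures is
instead kept in both orders via swap augmentation (`augment_mixed()`), which
duplicates labels and skips self-pairs, so the network sees both encodings of
each system rather than a canonicalized one.

## The synthetic label surrogate

CGMD label generation is replaced by a synthetic oracle
(`surrogate_ap()`) so the whole pipeline is testable offline. The surrogate
is a deterministic residue/position model plus seeded Gaussian noise:

* a residue-by-position weight table (20 × 10) whose residue ordering plants
  the qualitative structure CGMD screens report: aromatics (F, Y, W)
  contribute most, then aliphatic hydrophobics and cysteine (C, I, L, V),
  then polarizable H, S, T, then M, P, with charged residues and N, Q, A, G
  suppressing aggregation; positional preferences (aromatics mid/C-terminal,
  aliphatics near termini, S/T N-terminal, P at positions 1–2) are planted
  at smaller magnitude;
* a bonus of 0.06 per adjacent aromatic pair (a stand-in for π-stacking);
* a penalty of 0.03 per unit of absolute net side-chain charge
  (K/R +1, D/E −1, H neutral, termini excluded — the zwitterionic terminal
  pair cancels for a free peptide);
* for mixtures, the mean of the component scores plus a boost
  $0.12\,|q_1||q_2|$ when the components carry opposite net charge — the
  planted analogue of salt-bridge-driven co-assembly;
* Gaussian noise with standard deviation 0.05, and clipping to $[0.8, 2.6]$,
  which brackets the AP values printed for real CGMD systems.

The base offset 1.4 and weight magnitudes were chosen once so that labels
span roughly 0.9–2.4 with a standard deviation near 0.2, comparable to the
empirical spread of CGMD AP values, and were not revisited afterwards. Noise
for system $i$ is derived from `(seed, i)` with a counter construction, so a
label does not depend on evaluation order or batch composition.

What the surrogate does *not* emulate: simulation-to-simulation variability
beyond i.i.d. noise, finite-box and concentration effects, morphology, any
secondary-structure dependence, and the true nonlinear epistasis of real
aggregation. Consequently, passing tests demonstrate that the pipeline —
sampling, encoding, training, evaluation, law extraction — functions and
recovers planted structure; they do not validate predictions of real CGMD
labels, and the published headline accuracies (MAE ≈ 0.05, R² 0.85–0.92
against CGMD) are explicitly not reproduction targets here.

`make_transfer_fixture()` samples pentapeptide pairs with a configurable
fraction (default 0.9) of opposite-charge combinations of magnitudes 1–2,
mirroring a screening set enriched for charge complementarity. Under the
default noise, the planted boost makes the mixture AP exceed the component
average in roughly 94% of pairs; at zero noise the excess equals the planted
boost exactly, which the acceptance suite asserts.

## The regression network

The TRN is a token-level transformer encoder with an MLP decoder, written
directly on matrix primitives with hand-derived backward passes (verified
against numerical gradients in the test suite):

* vocabulary: 20 residues, the `+` mixture connector, and a blank
  placeholder used to pad short sequences to the model length — the
  placeholder has its own embedding row and is never interpreted as a
  residue;
* embedding plus fixed sinusoidal positional encoding (the canonical choice
  for this architecture family; the methodology names positional encoding
  without a variant);
* post-norm encoder blocks: self-attention and feed-forward sublayers, each
  with a residual connection followed by layer normalization;
* decoder: the encoder output flattened position-wise into one vector, then
  linear layers with batch normalization (placed after each linear map,
  before the activation), leaky-rectifier activations (slope 0.01) and
  dropout, ending in a single AP output. Mean pooling is available as a
  configuration alternative (`pooling = "mean"`) because "compressing to a
  1D vector" is ambiguous; flattening is the default since it preserves
  positional information for the very short sequences involved.

The full preset matches the reference architecture: 512-dim embedding, 6
blocks, 8 heads with 64-dim K/Q/V, feed-forward width 2048, MLP
[512, 256, 64, 32, 1]. The scaled preset keeps the identical topology at
desk scale — 64-dim embedding, 2 blocks, 4 heads of 16, feed-forward 256,
MLP [64, 32, 16, 8, 1] — and is the default for tests, examples and the
acceptance experiments.

Training follows the reference protocol (`trn_train_config()`): plain SGD
(no momentum, schedule or weight decay) at learning rate 0.2, batch size
512, 200 epochs, MSE loss (the protocol reports MAE/R² but does not name the
training loss; MSE is the standard regression default), a validation quarter
split off the training data by a seeded shuffle, best-epoch selection by
validation MAE, and metric averaging over 10 seeds. One integer seed
determines initialization, split, batch order and dropout masks, so runs are
exactly repeatable.

Desk-scale experiments override three protocol knobs, as recorded in
`trn_learning_curve()`'s defaults: 30 epochs, batch size 256, dropout 0, and
3 seeds instead of 10. The learning rate stays at the protocol's 0.2. These
sizes keep the full sample-efficiency experiment (training sizes 1000, 5000
and 8000 from a 10 000-peptide labelled pool, with the 2000-peptide
complement as the shared test set) within minutes on one CPU while leaving
the scaled network enough updates to converge on the surrogate task; the
acceptance suite requires seed-averaged test R² ≥ 0.85 at 8000 training
samples and strict monotonicity across the three sizes.

Numerical details worth recording: batch-norm running statistics use
momentum 0.1 and are what inference consumes (training batches use batch
statistics); minibatches of fewer than two samples are skipped because batch
normalization is undefined there; divergence (non-finite validation MAE)
stops training and returns the best parameters seen; attention key biases
are retained although softmax renders them gradient-free (they shift all
scores of a query equally).

## Aggregation laws and transferability

`partition_ranges()` divides normalized scores into quartile ranges
A = [0, 0.25), B = [0.25, 0.5), C = [0.5, 0.75), D = [0.75, 1], half-open
with D closed at 1 and boundary ties going upward.
`composition_by_range()` reports residue percentages per range either summed
over positions (denominator: residue occurrences) or per position
(denominator: sequences); both are provided because either weighting is a
defensible reading of published composition figures, and they differ only in
aggregation. The acceptance suite labels the complete length-3 factorial
space (8000 sequences, noiseless surrogate) and checks that aromatics are
enriched in range D relative to range A and that the aromatic group leads
the top range — i.e. the statistics recover the planted ordering.

`transfer_records()` assembles, for each pentapeptide pair, the component
APs, their average $\mathrm{AP}_{avepen}$, the concatenated-decapeptide AP,
the mixture AP and the deltas against the average; `transfer_analysis()`
summarizes the fraction of positive mixing deltas, median and maxima,
the delta correlation, and the selection filter used in the worked example
($\mathrm{AP}_{deca} > 1.5$ and $\Delta_{deca} > 0.4$). Top tables break
ties by delta descending then lexicographic sequence, so reports are
deterministic. Reported values round half away from zero
(`round_report()`), matching the printed tables; base R's half-to-even would
disagree at exact decimal halves (e.g. an average of 1.1045).

## Known limitations

* The surrogate's simplicity is deliberate; any accuracy statement is about
  recovering planted structure, not about real peptide physics.
* The full-preset network is provided and configurable but training it at
  the reference protocol is a compute-scale exercise, not part of the test
  suite.
* Scoring-population choice for $\mathrm{AP}'$ normalization materially
  affects downstream range statistics; the package forces the caller to own
  that choice and records it in every artifact.
* pH is fixed at neutral by the shipped hydrophilicity constants; no
  protonation-state modelling is attempted.
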