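---
title: "Modelling y-ion intensities in beam-type CID spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling y-ion intensities in beam-type CID spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Beam-type collision-induced dissociation (QTOF, QqQ, HCD) fragments a
protonated peptide along its backbone; the C-terminal fragments — y ions —
dominate the observable spectrum at higher collision energies. Predicting
the *relative intensities* of these y ions from sequence alone matters most
for targeted assays (SRM/MRM), where a handful of intense transitions must
be picked per peptide before any spectrum has been acquired.

`yfrag` models a peptide precursor (sequence of 6–15 canonical residues,
charge 2–3, collision energy) and predicts a 42-slot intensity vector: y1
through y14, each at fragment charge 1–3, with slot
$(k, z) \mapsto 3(k-1) + z$. Slots that cannot exist for a given precursor —
fragments at least as long as the peptide, or more highly charged than the
precursor — are encoded as $-1$; feasible but unobserved slots are $0$;
observed peaks are base-peak normalized to $(0, 1]$.

## Data preparation

Libraries arrive as MSP text (`Name:`, optional `Comment:` with a `CE=` key,
`Num peaks:`, then `m/z <tab> intensity <tab> annotation` lines). The
cleaning pipeline is:

1. `strip_modifications()` — modified residues are collapsed to their
   canonical letter; the peptide is treated as unmodified.
2. `drop_b_ions()` — every peak that is not a y ion representable by the
   42-slot tensor (z ≤ 3, k ≤ 14, k < peptide length) is removed.
3. `deduplicate()` — one spectrum per (sequence, charge): the copy with the
   most peaks wins; ties keep the earliest source. The same sequence at a
   different charge state is a different peptide.
4. `filter_min_peaks()` — spectra with fewer than three annotated y peaks
   are dropped. We read the "fewer than three" criterion as peaks per
   spectrum (the quantity whose distribution the pipeline reports); the
   threshold is a parameter for users who prefer replicate-spectrum counts.

The pipeline is idempotent, and `read_msp()`/`write_msp()` round-trip
losslessly, so cleaned libraries can be persisted as MSP.

## Features and encoding

Three input channels feed the model:

* **Sequence**: a 15×20 one-hot matrix (rows beyond the peptide length are
  zero). The residue order is alphabetical over one-letter codes.
* **Scalars**: collision energy, precursor charge, length, and proline
  count, scaled to comparable ranges (CE/100, charge/3, length/15,
  prolines/15). Proline count earns its place because the exploratory
  statistics below show proline dominating cleavage behaviour.
* **Sliding windows**: every 4-mer becomes one column of a 4×12 matrix of
  residue codes (alphabetical rank / 20), so local sequence context enters
  through a convolutional path. A one-hot 4-mer variant (80×12) is
  available behind a flag.

## The network

The predictor combines three paths (all sizes configurable via
`model_config()`):

* the one-hot sequence runs through a **bidirectional GRU encoder**
  (hidden 128 per direction by default) followed by scaled **dot-product
  attention** with the final encoder state as query;
* the scalar features run through two dense relu layers;
* the window matrix runs through **three 3×3 convolutions** (16→32→64
  channels by default, 'same' padding, no pooling — the image is only
  4×12) and a linear projection.

The dense and convolutional outputs are concatenated and merged with the
encoder states by a matrix product: the merge computes
$u_t = (h_t W_m) \odot (f W_g)$, i.e. each encoder state is multiplied by a
feature-dependent matrix $W_m\,\mathrm{diag}(f W_g)$. We chose this
rank-constrained bilinear form over materializing a per-sample
$2H \times d$ projection because it is algebraically the same kind of merge
while keeping every operation a plain batched matrix product. The merged
sequence is decoded by a **second GRU** (initialized from the encoder
summary and first attention context), a second dot-product attention layer
follows, and linear layers form the prediction.

Two deliberate departures from a naive left-to-right reading, both
motivated by the chemistry:

* **C-terminal anchoring.** y ions are indexed from the C terminus, so
  inside the model the one-hot rows (and window columns) are right-aligned:
  the cleavage that produces $y_k$ then sits between rows
  $L_{max}-k$ and $L_{max}-k+1$ for *every* peptide length. Without this,
  the mapping from sequence position to output slot shifts with length and
  must be relearned for every $L$.
* **Position-tied readout.** The prediction layers read, for each fragment
  length $k$, the two decoder states flanking its own cleavage row
  (together with the attention context and feature vector) through a
  shared relu layer, then a per-$k$ linear output emits the three charge
  slots. This ties each output slot to the part of the sequence that
  physically determines it.

The output is linear (targets include $-1$); predictions for users are
clamped at zero by default (`predict_intensities(clamp = TRUE)`).

Dropout (default 0.1) is applied after the second attention layer; it is
the one regularizer the architecture description calls for, and its
probability was left configurable because the architecture description does not fix
it.

## Training

`train_model()` uses minibatch Adam at learning
rate 0.01 with a reduce-on-plateau schedule on the validation loss (mode
min, factor 0.1, patience 7, relative improvement threshold $10^{-4}$). The
default loss is the plain mean squared error over all 42 slots — including
the $-1$ slots, matching the fill-then-MSE description — with a masked
variant (`mask_infeasible = TRUE`) provided as the defensible alternative;
in our simulations the literal variant trains slightly better. A top-k
weighted loss (`loss = "topk"`) adds `weight ×` the MSE over each sample's
three highest-target slots, the altered objective that trades overall
correlation for highest-peak accuracy.

The recipe leaves the stopping rule open; we run at most 100 epochs with
early stopping after 15 non-improving epochs (twice the scheduler
patience), batch size 256, and always return the checkpoint with the lowest
validation loss. `kfold_split()` partitions by shuffled index into ten
folds (validation sets disjoint, exhaustive, sizes within one);
`cross_validate()` trains one model per fold and scores each on a common
held-out set by the median without-zero Pearson correlation. Which fold
model to release is scored by that same statistic, since no other
selection criterion presents itself.

All gradients come from an in-package reverse-mode autodiff tape whose
fused layers (GRU step, attention, convolution, site head, weighted MSE)
are hand-derived and verified against central finite differences in the
test suite. Given a seed, builds, training runs and forward passes are
bit-reproducible on one platform.

## Evaluation statistics

* `pcc_without_zero()` — Pearson correlation over the slots where the
  database spectrum has a peak; `pcc_with_zero()` — over all feasible
  slots, zeros filled in. The two agree exactly when every feasible slot
  holds a peak.
* `highest_peak_accuracy()` — exact argmax match, predicted top-1 within
  the database top 3, and predicted top 2 within the database top 3, over
  peptides; database ties break by slot order.
* `psm_grouping()` — the simplified peptide-spectrum-match test: peptides
  whose precursors fall within ±0.5 Th and that share at least three
  product ions within ±0.5 Th are linked; groups are connected components
  of the link graph (a design choice: cliques
  would be the stricter alternative, and on our simulated libraries the two differ
  only in rare chains). `psm_match_accuracy()` then asks whether each
  predicted spectrum best matches its own database spectrum within its
  group — best by highest correlation, with ties broken by lowest MSE.
* `y_ion_mz()`/`precursor_mz()` use monoisotopic residue masses, water
  18.010565 Da and proton 1.007276 Da; tolerances are absolute Th.

## Exploratory highest-peak statistics

`highest_peak()` and its derived tables describe where the most intense y
ion falls: the flanking-residue matrix (+1 × −1 counts; emitted as counts
with row/column normalizations as options since no single
normalization is canonical), the charge-retention profile over a −4..+4
window, the precursor-length × fragment-length co-occurrence, the
+1-abundance comparison between length−2 fragments and the rest (with a
two-proportion z statistic per residue and a robust modified-z outlier
rule at 3.5), and the top-two intensity gap stratified by proline at +1.
Highest peaks at the terminal cleavage (no −2 residue) are excluded from
the window tables.

## The simulator

`simulate_library()` draws peptides (uniform residue frequencies, tryptic
C-terminal K/R by default, lengths 6–15, charges 2:3 at 0.7:0.3) and
assigns each cleavage a log-intensity score

$$s_k = \beta_P [+1 = P] + \beta_{2} [k = L-2] + \beta_{4} [k = L-4] +
\beta_{ali} [-1 \in \{A,V,L,I\}] + \beta_{acid} [-1 \in \{D,E\}] +
\varepsilon,\quad \varepsilon \sim N(0, \sigma^2),$$

with intensities $e^{s_k}$ normalized to base peak 1, an exponential link
chosen only for positivity. Fragment charges retain the precursor charge
with probability 0.05, raised by 0.4 when the fragment contains proline;
each peak is then lost with dropout probability 0.1. The default effect
sizes ($\beta_P = 2$, $\beta_2 = 1.5$, $\beta_4 = 0.7$,
$\beta_{ali} = \beta_{acid} = 0.6$, $\sigma = 0.3$) are chosen so that the
simulated libraries reproduce the *qualitative* enrichments seen in real
QTOF libraries — proline clearly dominant at +1, a pronounced mode at
fragment length $L-2$ with a weaker one at $L-4$, more than half of
charge-retaining fragments containing proline — at magnitudes a mass
spectrometrist would call strong but not caricatured. Presets
(`make_fixture()`): `"flat"`, `"realistic"`, `"proline-only"`,
`"length-only"`.

What the simulator does **not** emulate: b ions and neutral losses, noise
peaks at arbitrary m/z, isotope envelopes, retention time, modified
residues, realistic amino-acid usage, or instrument-dependent CE response
(the simulated CE is drawn independently of the intensities). Tests that
pass on simulated data therefore certify the pipeline, the statistics and
the model's ability to learn cleavage-site-driven intensity structure —
not spectrum-level accuracy on real libraries.

## Desk-scale experiment sizes

The package's own experiments (test suite and `scripts/acceptance.R`) use
a deliberately reduced setting chosen to keep a full cross-validated run
in the tens of minutes on a single CPU: 2,000 training peptides with 500
held out, the `desk_model_config()` architecture (GRU hidden 32, 4/8/8-
channel CNN, no dropout) and `desk_train_config()` (30 epochs, batch 128).
Under these conditions the 10-fold models reach a held-out median
without-zero correlation above 0.9 with cross-fold spread well under 0.05,
and the best fold's highest-peak accuracy sits within a few points of the
generative optimum (an oracle that knows the true effect sizes reaches a
median correlation of about 0.96 on the same data — the residual gap is
the simulator's intensity noise and charge-assignment randomness).

## Numerical choices and degenerate inputs

* Correlations of constant vectors are undefined and returned as `NA`,
  excluded from medians.
* Ties everywhere break deterministically toward the smaller slot index
  (highest peaks, decoded peak ordering, database top-3).
* Spectra that lose every peak during cleaning are removed by the
  minimum-peak filter; empty libraries summarize to `NA` means with an
  `undefined` flag.
* Peaks claiming infeasible slots (e.g. a fragment charge above the
  precursor's) are data errors and raise immediately, naming the peak.
* Full-precision (17 significant digit) text serialization is used for
  encoded tables so CSV round trips are bit-exact.

## Known limitations

The model is desk-validated on simulated libraries only; nothing here
claims accuracy on NIST-scale real data, which would require large real
training corpora. Peptides outside length 6–15, fragment charges above 3,
b ions, neutral losses and modified residues are out of scope by design.
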