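---
title: "Two-stage RNA secondary structure prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage RNA secondary structure prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `foldboost`, the
assumptions behind it, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions taken
where the design was genuinely open.

## The two-stage model

### Stage 1: per-nucleotide pairing-probability labeling

The input to Stage 1 is an $l \times 10$ tensor: the one-hot encoded
sequence (fixed column order A, C, G, U) stacked with six binary
*pairedness tracks*, one per member of a panel of single-sequence
structure predictors. Track $i$ has a 1 at position $j$ exactly when
member $i$ pairs position $j$ in its predicted structure. The panel
defaults to six in-repo engines chosen to embody genuinely different
decision rules — maximum pairing (Nussinov), pair-only MFE, MFE with
stacking, maximum-expected-accuracy decoding at $\gamma = 1$ and
$\gamma = 6$, and MFE with the GU wobble disabled — and any member can be
replaced by an adapter that reads an external tool's dot-bracket/CT
output. The track stacking order is frozen in the panel configuration and
serialized into every checkpoint, so predictions are reproducible.

The network is an encoder–interaction–decoder stack:

1. **Feature extraction.** Two 1D convolutions with kernel size 3 and
   stride 2. Output position $i$ reads input positions $2i-1$, $2i$,
   $2i+1$ with zero boundary, giving $\lceil l/2 \rceil$ positions per
   layer; after two layers the sequence is at quarter resolution.
2. **Mutual interactions.** Two residual multi-head self-attention
   blocks: $X' = X + \mathrm{MHA}(X)$, then $A = X' + \mathrm{FF}(X')$
   with a two-layer position-wise feed-forward map. Heads use scaled
   dot-product attention on per-head projections of dimension
   $d_{\mathrm{model}}/n_{\mathrm{heads}}$; the head outputs are
   concatenated without an output projection. No positional encoding is
   added anywhere — positional information enters only through the
   convolutions — so the attention stack in isolation is
   permutation-equivariant (and is tested to be).
3. **Decoding.** Two stride-2 transpose convolutions (explicitly: the
   input is interleaved with zero rows, then convolved at stride 1 with a
   size-3 kernel, doubling the length), followed by a $d_2 \times 1$
   weight vector shared across positions and a sigmoid, giving one
   pairing probability per position. For odd lengths the two
   ceil-halvings followed by two doublings can overshoot $l$; the decoded
   signal is cropped to the first $l$ positions.

Each convolution/transpose-convolution is followed by ReLU and then batch
normalization — in that order. Activation-then-normalization is
unconventional, but it is the literal reading of the architecture this
package implements, and it is applied consistently; the finite-difference
gradient checks cover it. The two attention blocks do not share weights.

### Stage 2: SHAPE-like soft-constrained folding

Chemical probing reagents preferentially modify flexible, unpaired
backbones, so probing reactivity is inversely related to pairing. Stage 2
inverts the Stage-1 probabilities into SHAPE-like scores $S = 1 - Y$ and
maps them to pseudoenergies with the Deigan linear form
$\Delta G(s) = m \ln(s + 1) + b$, added once per paired *nucleotide*
(twice per pair) inside the folding dynamic program. The default
$(m, b) = (1.8, -0.6)$ kcal/mol are the widely used defaults of
SHAPE-directed folding in the RNAstructure family; both are exposed per
run. `write_shape_file()` emits the two-column `position score` dialect
so externally installed folders can optionally consume the same
constraints.

The default constrained optimizer is the in-repo Zuker-style engine; any
function registered with `register_folder()` can be swapped in, which is
how the optimizer-robustness experiment is run.

## The folding engines

The engines use a deliberately small energy model: one energy per
canonical pair type (defaults: GC/CG $-3$, AU/UA $-2$, GU/UG $-1$
kcal/mol-like), a stacking bonus ($-1$) for adjacent pairs, and a minimum
hairpin loop of 3 nt. This is not a nearest-neighbor Turner model and is
not meant to be one — the engines exist to provide six cheap, diverse,
fully reproducible panel members and a constrained optimizer, with
adapters available wherever real tool output is preferred.

Numerical and algorithmic choices:

- The MFE recursion is the classic $V/W$ pair: $V(i,j)$ is the optimum
  given $(i,j)$ paired, with interior term
  $\min(W(i+1,j-1),\ V(i+1,j-1) + \mathrm{stack})$. This form is exactly
  optimal only when stacking is a bonus, so `energy_model()` enforces
  `stack_bonus <= 0`. Correctness is tested against exhaustive
  enumeration of all nested structures on random sequences up to 12 nt,
  with and without random SHAPE constraints.
- Tie-breaking is frozen at matrix-fill time (pairing beats leaving a
  position unpaired; the smallest 5' index wins among pairing branches),
  so tracebacks are deterministic and never re-test floating-point
  equality.
- The partition function behind the MEA engine is a McCaskill-style
  inside–outside recursion over a *pair-only* Boltzmann ensemble
  ($RT = 0.6163$ kcal/mol at 37 °C): the stacking bonus is not part of
  this ensemble. Including stacking in the outside recursion is
  substantially more error-prone, and the MEA members are panel
  diversity, not a thermodynamic reference. The pair probabilities are
  verified against Boltzmann-weighted enumeration to $10^{-9}$.
- Per-nucleotide rescaling keeps the partition function finite for long
  sequences; the scale cancels exactly in every probability ratio. The
  outside recursion enumerates immediate enclosing pairs and is
  $O(l^4)$ — acceptable at the lengths the MEA engine serves.

## Training

The loss is the sum over real (non-padded) positions of a weighted binary
cross-entropy with positive-class weight 1.8; padded positions contribute
exactly zero loss and zero gradient (checked by finite differences
through the network). Probabilities are clamped to
$[10^{-7}, 1 - 10^{-7}]$ inside the loss rather than raising on
saturation. For optimization the per-batch gradient is normalized by the
number of real positions.

The learning-rate schedule is cosine decay from the base rate to a
$10^{-13}$ floor across the first phase, then per-epoch multiplication by
$10^{-10}$; scheduling is per-epoch. The reference preset is 250 epochs
(227 cosine + 23 exponential), batch 512, padding target 512, 25
cross-validation folds. The base learning rate is not pinned by the
architecture; $10^{-3}$ (the Adam convention) is the reference default,
and Adam runs with conventional $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$. Model selection returns the final-epoch parameters;
the recorded partial-loss/partial-F1 curves (threshold 0.5) are for
monitoring, not early stopping.

Cross-validation is family-wise: `assign_folds()` deals whole families to
folds after a seeded shuffle, so structurally related sequences never
straddle a split. All sampling in the package is a pure function of its
seed; runs are bit-reproducible on CPU.

### Desk-scale preset

The desk preset exists so the full pipeline — corpus generation,
training, prediction, evaluation — runs in about a minute on one CPU. It
shrinks the channel plan to 16/32 (4 heads) /64/32/16, trains 30 epochs
(28 cosine + 2 exponential) with batch 8, base rate 0.02 and padding
target 64, and reduces the dropout rates to 0.05 (residual) and 0.1
(convolutional). The reference rates (0.1/0.4) were tuned for a network
with hundreds of redundant channels; dropping 40% of 32 channels destroys
most of the forward signal of a few-thousand-parameter network, which a
single-example overfitting check makes visible immediately. The reference
channel plan (256/512 with 16 heads, feed-forward 1024, decoder 512/256)
is available as `network_config()`'s defaults; the unpinned counts
(`n1`, `d1`) were chosen symmetric to the pinned ones.

## The synthetic family generator

`generate_family()` emulates what matters about curated structural
families for this pipeline: a group of sequences that share one nested
secondary structure and diverge in primary sequence. A random nested
structure is drawn from a recursive helix/loop grammar (helix length
geometric with minimum 2 and continuation probability 0.3; hairpin loops
at least 3 nt, with small random offsets producing bulges and internal
loops; multiloop branching with probability 0.25). A seed sequence is
built to be compatible (complementary bases at paired positions, GC-rich
pair-type distribution with 10% GU wobble, random loop residues), and
members are derived by seeded point mutations in which paired positions
mutate *compensatorily* — both partners are replaced by a fresh canonical
pair — so every member still folds on the family structure.

What the generator does **not** emulate: sequence-dependent loop
energetics, pseudoknots, noncanonical pairs, covariation statistics of
real alignments, and — importantly — thermodynamic realism: the true
structures are draws from a grammar, not minima of any energy model, so
the panel engines agree with the truth far less than real tools agree
with curated structures. Passing end-to-end tests on this corpus
therefore demonstrates that the machinery works and that Stage-1 learning
extracts real signal from the encoding; it does not certify accuracy on
real RNA.

Dataset handling mirrors family-wise benchmark construction: stratified
train/test splitting that preserves the representative-length
distribution (bins of 50 nt, largest-remainder allocation, bin edges
$[0, 50), [50, 100), \ldots$ by the longest member of each family),
capping of training families at 5 members, balanced per-bin test
sampling, and a global-identity contamination screen (Needleman–Wunsch,
match 1 / mismatch 0 / gap $-1$, identity = matches / alignment length,
threshold 0.85) standing in for CD-HIT, with an option hook for
delegating to an external binary.

## Evaluation conventions

Pair-level metrics count exact $(i,j)$ matches — no one-position slip
tolerance. Degenerate cases are pinned for determinism: precision is 1
when nothing is predicted, recall is 1 when the reference has no pairs,
F1 is 1 when both structures are empty and 0 when exactly one is. The
labeling metrics use the same formulas on per-position confusion counts
at threshold 0.5. The consensus baseline is the unanimity AND of the six
tracks. League tables rank tools within each test set by median F1 with
min-tie competition ranking (tied tools share the better rank), then
summarize each tool by the median of its per-set ranks and the median of
its per-set median F1s.

## The desk-scale experiment, and a limitation

`run_synthetic_benchmark()` generates 60 families (lengths 24–64 nt, 4
members, mutation rate 0.1), holds out a stratified 20% of families,
trains the desk network, and evaluates on the held-out members
(`scripts/acceptance.R` is a thin driver around it). Two findings are
stable across seeds:

- **Stage-1 labeling beats the unanimity consensus** on held-out
  families (e.g. median F1 0.679 vs 0.628 at seed 1) — the network
  learns more from the six tracks plus sequence than the all-agree rule
  extracts.
- **The boosted pipeline does not beat the strongest single engine at
  this scale** (e.g. median pair F1 0.462 vs 0.519 at seed 1, with the
  optimizer-swap delta under 1 point). The mechanism is visible in the
  diagnostics: the trained probabilities are *calibrated* but
  low-contrast — on a task where the per-position evidence supports only
  ~0.68 labeling F1, a proper scoring rule keeps $Y$ near the base rate,
  so $S = 1 - Y$ spans a narrow band and the Deigan term
  $m\ln(S+1) + b$ differentiates paired from unpaired positions by well
  under the energy of a single base pair. Oracle experiments in the test
  suite show the same Stage-2 machinery recovering designed structures
  exactly when the constraints are sharp. Closing the gap requires a
  Stage-1 whose accuracy (and hence confidence) is substantially above
  the panel's own — achievable with real tools and real families, but
  not under the generator's deliberately hard, grammar-random truth
  structures.

Other known limitations: nested structures only (pseudoknots and
noncanonical pairs are rejected at parse time by design); the toy energy
model is not a substitute for nearest-neighbor thermodynamics; training
at the reference preset (512-wide attention, batch 512) is implemented
but not routinely exercised on CPU; and sequences at or beyond the
padding target draw a warning in prediction, reflecting that training
never saw such lengths.
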