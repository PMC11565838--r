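---
title: "Preferential masking for antibody language models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preferential masking for antibody language models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmlm)
```

# Motivation

Antibody variable domains are mosaics of two very different kinds of
sequence. The framework regions (FR1–FR4) and, to a lesser degree, CDR1
and CDR2 are *templated*: they are copied from a small set of germline
V/D/J genes and are nearly identical across the repertoire. The third
complementarity-determining region (CDR3) is *non-templated*: it spans
the V(D)J junction, where random nucleotide trimming and insertion make
it the most diverse part of the molecule and the main determinant of
antigen specificity.

A masked language model (MLM) trained with uniform masking spends most
of its capacity learning to copy germline: the vast majority of masked
positions are templated and quickly become trivial to predict.
`abmlm` implements *preferential masking*: CDR3 positions are masked at
an elevated rate and all other residue positions at a compensated lower
rate, so that training concentrates on the hard, information-rich part
of the sequence while the expected number of masked tokens per sequence
is unchanged.

# The masking model

## Probability matrices

For a tokenized pair, let $\hat p$ be the fraction of residue tokens
(excluding all special and padding tokens) that lie in either chain's
CDR3. With base rate $b = 0.15$ and CDR3 rate $c = 0.25$,
`maskingProbs()` assigns

* probability $c$ to every CDR3 residue position,
* probability $(b - c\hat p)/(1-\hat p)$ to every other residue
  position,
* probability $0$ to special and padding positions.

The residue-position mean is then exactly
$\hat p\,c + (1-\hat p)\frac{b - c\hat p}{1-\hat p} = b$,
i.e. the matrix preserves the 15% average masking rate *identically*,
for any sequence composition with $\hat p < b/c = 0.6$. Above that
fraction the compensated rate would be negative; it is clamped to zero
with a warning, and the degenerate case $\hat p = 1$ is an error.

```{r}
tok <- encodePair(paste(rep("QVK", 30), collapse = ""),
                  paste(rep("DIQ", 25), collapse = ""))
pr <- maskingProbs(tok, maskingParams("preferential"))
residue <- tok@chainOfToken != "special"
mean(pr@probs[residue])          # exactly the base rate
unique(pr@probs[residue])        # two rates: compensated and CDR3
```

Note the average is defined over residue positions only. Padding length
is arbitrary (it depends on the longest sequence the model accepts, not
on the antibody), so including pads in the average would make the
"average masking rate" depend on padding and break the identity.

## Dynamic selection and 80/10/10 corruption

Probability matrices are precomputed once per dataset
(`precomputeProbs()`, optionally persisted) because they depend only on
the annotation, not on the training step. Masking itself is *dynamic*:
every epoch draws a fresh independent Bernoulli selection per position
(`drawSelection()`). Of the selected positions, 80% are replaced by
`<mask>`, 10% by a random residue token, and 10% are kept unchanged;
all selected positions contribute to the loss, unselected positions
carry an `NA` ignore label (`corruptTokens()`). Random replacements are
drawn from the 21 residue tokens so the structural layout of the
encoding can never be corrupted; whole-vocabulary sampling is available
behind an explicit flag.

`mlmCollator()` wraps selection and corruption in a closure whose
randomness is derived from (seed, epoch, batch), so any batch can be
reproduced in isolation while masks still differ across epochs.

# The synthetic repertoire generator

Real paired repertoires cannot ship with the package, so all examples
and tests run on a synthetic generator whose statistical structure
mirrors the templated/non-templated dichotomy:

* `buildGermlineLibrary()` draws a small library of V/D/J germline
  alleles per chain with fixed FR/CDR segmentation; FR segments are
  strongly conserved across alleles, CDR1/CDR2 moderately variable.
* `recombinePair()` assembles a heavy chain (V–D–J with junctional
  trimming and random N-insertions) and a light chain (V–J), producing
  a junction-spanning CDR3 whose length varies per sequence.
* `applySHM()` applies somatic hypermutation as independent
  per-position substitutions with a CDR-biased rate (memory cells
  receive mutations, naive cells do not).
* `generateRepertoire()` yields a `PairedRepertoire` with ground-truth
  region columns for every record, plus donor and cell-type metadata.

Because the generator knows the true region of every residue, the
alignment-based annotation (`buildRegionMask()`) can be validated
against ground truth, and region-stratified losses/accuracies need no
external annotation tool.

`plantSpecificityMotif()` creates binary specificity tasks by writing a
fixed motif into the heavy CDR3 of a random half of the repertoire —
the only place where class signal exists by construction.

# Tokenization

The 26-token vocabulary is five specials (`<pad>`, `<mask>`, `<unk>`,
`<cls>`, `<eos>`), the 20 amino acids, and `X`. A pair is encoded as

```
<cls> HEAVY <cls> <cls> LIGHT <eos>
```

padded to a fixed length of 320 with no truncation: sequences that do
not fit raise an error rather than silently losing residues. Region and
chain labels are carried per token so that masking, stratified
evaluation and attribution can all be expressed per region.

# The encoder and its numerics

`buildEncoder()` constructs a pre-layer-norm transformer encoder in
pure R: multi-head self-attention with rotary position embeddings on
queries and keys, exact-GELU feedforward sublayers, a final layer norm
and a linear MLM head. The default desk preset (2 layers, 4 heads,
hidden 64, feedforward 128) trains in minutes on one CPU; a full-scale
preset (32 layers, 20 heads, hidden 960, feedforward 3840, ~350M
parameters) is constructible for shape/count verification but is not
intended to be trained here.

Numerical choices worth stating explicitly:

* Gradients are hand-derived and verified against central finite
  differences in the test suite (relative error at the 1e-6 level for
  parameters, 1e-9 for hidden-state gradients).
* Optimization is Adam with decoupled weight decay; biases and
  layer-norm parameters are excluded from decay.
* The learning-rate schedule is linear warmup followed by linear decay
  to zero.
* Rotary embeddings use the half-split formulation with base 10000;
  they preserve per-pair norms and depend only on relative position,
  both asserted in tests.
* Softmax and cross-entropy are computed in the max-shifted form, so
  training does not overflow for extreme logits.

Validation during `trainMLM()` always uses a *fixed uniform* corruption
of the validation set (same seed for every evaluation and for every
training strategy). Preferential and uniform runs are therefore
compared on identical footing, and validation loss differences cannot
come from different masks.

# Classifiers and attribution

Two classifier protocols are provided:

* `trainClassifierHead()` — the frozen-base protocol: pooled final
  hidden states (cls token or mean) feed a single linear softmax head;
  a checksum asserts the base was not modified.
* `fineTuneClassifier()` — end-to-end fine-tuning of the encoder plus a
  cls-pooled head.

`attcatScores()` implements AttCAT-style attribution: for each layer,
the inner product of the post-block hidden state with the gradient of
the target-class logit with respect to that state, weighted by the
attention that token receives (mean over heads and query positions, or
the cls-row variant), summed over layers. Scores are standard-scaled
per sequence **over residue positions only**: the cls token receives
the pooled logit gradient directly, so its raw impact exceeds every
residue impact by orders of magnitude, and including it in the scaling
statistics would compress all residue scores toward a common constant.
Special positions carry `NA` in the normalized vector.

A practical finding reproduced by the test suite: with a frozen base,
the pooled feature is a fixed function of sequence composition, and
attribution of a linear head spreads over whatever tokens project onto
the head weights — it is faithful to the classifier but diffuse over
regions, even when the classifier demonstrably uses a planted motif.
Concentration of attribution in the motif-bearing region (heavy CDR3)
emerges once the encoder itself is trained on the classification signal
via `fineTuneClassifier()`. The acceptance suite encodes exactly this
protocol on a controlled task (single germline allele per segment, no
somatic mutation, motif planted in heavy CDR3) in which the junction is
provably the only class-discriminative sequence.

`selectOrderedSequences()` provides a reproducible reading of
"systematically chosen" attribution examples: sequences are stratified
by confidence decile of the averaged classifier probability, sampled
per decile, and returned in ascending probability order.

# Evaluation utilities

`binaryMetrics()` computes accuracy, ROC AUC (midrank form, tie-aware),
average precision (step-function area by default, trapezoid optional),
F1 and MCC; `binaryMetricsAcrossFolds()` adds fold means and standard
errors; `stratifiedKFold()` yields label-balanced folds;
`pairedTBonferroni()` performs per-region paired t-tests with
Bonferroni correction over the 14 chain-by-region cells.

# Limitations

* Everything is desk-scale: the pure-R encoder is orders of magnitude
  slower than a GPU implementation, and the default presets (hundreds
  of sequences, a few hundred optimization steps) are chosen to show
  directional effects, not converged language models.
* The repertoire generator is a statistical caricature: real V(D)J
  recombination has allele-specific recombination biases, indels under
  SHM, and isotype effects that are not modelled.
* Classifier heads are binary only.
* Attribution supports the two AttCAT attention-pooling variants but no
  other explanation families; faithfulness is validated against
  finite-difference oracles, not against biological ground truth beyond
  the planted-motif construction.
* The package never reads real antibody data and ships none.
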