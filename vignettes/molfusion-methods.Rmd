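---
title: "Structure-property multimodal modeling with molfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-property multimodal modeling with molfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

molfusion treats a molecule as a pair of "sentences": its SMILES string,
tokenized into BPE subwords, and its property vector (PV) -- a fixed-order
list of P scalar descriptors, z-scored with corpus statistics, in which any
position may be replaced by a learned [UNK] embedding meaning "value
unspecified". Each modality is read by its own transformer encoder
(self-attention over the framed sequence, with a learned [CLS] summary token
at position 0), and a single weight-shared fusion encoder cross-attends one
modality's features to the other's, alternating which side supplies the
queries.

Pre-training combines four objectives, summed with unit weights:

* **Contrastive alignment.** The projected, L2-normalized [CLS] features of
  a matched SMILES/PV pair should be similar; mismatched pairs dissimilar.
  Similarities are temperature-scaled softmaxes over the other-modality
  candidates of the batch plus a FIFO queue of recent momentum-model
  features (both intermodal directions and both intramodal directions;
  the four cross-entropies are averaged with a factor 1/2).
* **Next-word prediction (NWP).** With a causal mask on the SMILES side
  (unimodal and fusion self-attention), the fusion output at position t
  predicts token t+1, conditioned on the full (bidirectionally encoded,
  partially masked) PV.
* **Next-property prediction (NPP).** The mirror task on the PV side with a
  squared-error loss; positions whose value was masked as [UNK] contribute
  nothing, so the model is never penalized for properties it was told are
  unknown.
* **SMILES-PV matching (SPM).** A two-way head on the concatenated fused
  [CLS] features classifies matched vs mismatched pairs; negatives are
  mined per anchor with probability proportional to the in-batch
  intermodal similarity (positives excluded), which concentrates training
  on the confusable pairs.

A momentum teacher -- an exponential moving average of the student with
coefficient lambda = 0.995 -- supplies soft pseudo-labels for the
contrastive and NWP targets, mixed with the one-hot labels at weight alpha,
ramped linearly from 0 to 0.4 over the first epoch. One-hot labels treat
queue entries (which come from earlier batches) as negatives. The teacher
also feeds the contrastive queues.

Because both generative objectives are part of pre-training, the trained
model decodes in both directions with no further fine-tuning: SMILES
conditioned on a partial PV (greedy, temperature-1 stochastic, or beam
search, default width 2), and a full PV from a SMILES, one property at a
time, left to right, each predicted value re-entering the input as a known
value. Generation quality is scored by validity (parseable fraction),
uniqueness (distinct canonical forms among valid), novelty (unique forms
absent from the pre-training corpus), and the normalized RMSE between the
controlled property targets and the descriptors recomputed from the
generated molecules, averaged over controlled properties on the z-scale.

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| P (property count) | 53 (full panel) / 12 (toy preset) | registry order is frozen per model |
| BPE vocabulary | 300 subwords | specials + observed characters + merges |
| hidden dim / heads | 64 / 4 (desk preset) | `model_config()` scales to BERT-base if desired |
| unimodal / fusion layers | 2 / 2 (desk), 6 / 6 (reference recipe) | |
| batch size | 96 (schedule default); 8 in the desk-scale runs | |
| optimizer | AdamW, weight decay 0.02, grad-norm clip 5 | decay on weight matrices only |
| learning rate | warmup to 1e-4, cosine to 1e-5 (reference recipe) | desk preset: 1e-3 to 1e-4, same 10:1 shape, sized for a 64-dim model |
| [UNK] mask rate | 0.5 | per position, per step |
| alpha | 0 -> 0.4 over epoch 1 | pseudo-label mixing |
| lambda | 0.995 | EMA teacher |
| queue capacity | 24,576 (default); 256 at desk scale | per modality |
| tau | init 0.07, learnable, clamped to [1e-3, 0.5] | contrastive temperature |

## Design choices where the design was open

* **Dual encoder passes.** The contrastive/matching objectives need
  bidirectional [CLS] features while NWP/NPP need causal features; each
  step therefore runs every unimodal encoder twice (shared weights, masks
  differing). This is the standard resolution for dual-stream models that
  mix contrastive and autoregressive objectives.
* **Pre-norm blocks.** Blocks are pre-norm (LN, sublayer, residual) with a
  final LN per encoder, chosen for optimization stability in small,
  short-schedule models; dropout defaults to 0 at desk scale and is a
  config switch.
* **Value encoding.** One shared linear layer encodes every property value;
  the positional embedding alone identifies which property a position
  carries. [CLS]_P is a learned embedding, not a value.
* **Queues store teacher features**, and the anchor's own teacher feature
  is the positive candidate in the intramodal directions, following the
  momentum-distillation convention this family of models cites.
* **One hard negative per anchor per direction** (so a batch of B yields B
  positives and 2B negatives for the matching head).
* **Cross-attention is never causally masked**: the conditioning modality
  is fully known at decode time, so only query-side self-attention carries
  the causal restriction.
* **Beam search** uses raw joint log-probability without length
  normalization; finished hypotheses are held and compared against live
  ones. Sequences that hit the length cap without [SEP] are returned as-is
  and almost always count as invalid -- they are not silently dropped.
* **Tokenizer ties** in pair frequency are broken by the lexicographic
  order of the merged string, making retraining bit-identical. The base
  alphabet is exactly the characters observed in the corpus; two-letter
  atoms are learned as merges, not seeded.
* **Normalization** uses the population (1/n) standard deviation, floored
  at 1e-8; statistics are serialized next to the vocabulary so checkpoints
  are self-describing.

## The descriptor registry

The default panel has 53 descriptors: Open Babel properties (molar mass,
logP, TPSA, molar refractivity, H-bond donors/acceptors, atom/bond/rotor
counts, ...) plus lexical counts on the canonical SMILES (per-element atom
counts, aromatic counts, ring closures, branches, components, charges) and
simple derived quantities (fractions, per-atom ratios, a cyclomatic ring
count). It is a documented default of this package -- the registry is fully
configurable, order included, and any user function SMILES -> number can be
added. Descriptors are deterministic, stereochemistry-blind (an explicit
non-goal), and computed in batch through the `obabel` CLI with per-molecule
title tracking so invalid inputs are detected without breaking alignment.
The 12-descriptor `toy_registry()` preset keeps desk-scale experiments
cheap.

## What the toy generator emulates -- and what it does not

`generate_toy_corpus()` assembles molecules by concatenating short, valid
SMILES fragments (chains, rings, heteroatom substituents; ~10% of emitted
molecules are two-component "salt-style" strings so the tokenizer sees the
`.` separator), validating every candidate with the parser. This reproduces
the *shape* of a pre-training corpus -- variable lengths, shared
substructures, a learnable subword statistics -- at a few thousand
molecules, but not the chemical diversity of tens of millions of real
structures: fragment reuse makes the corpus far more redundant, descriptors
span a narrower range, and drug-likeness is not attempted. Toy reactions
are esterification-style joins that exercise the seq2seq machinery only.
Passing tests therefore demonstrate that the machinery is correct and that
the objectives optimize and transfer at small scale; they say nothing about
reaching published large-scale benchmark numbers, which require the
full-size corpus and model.

## Numerical choices and degenerate inputs

Attention masks are additive with -1e30 for forbidden positions; a query
row with no permitted key is an error. Softmaxes subtract the row maximum.
Batches are stacked ragged (no padding) under block-diagonal masks.
Gradients are reverse-mode through a small tape; the multi-head attention
core is a single fused op with a hand-derived backward, validated against
finite differences. Invalid SMILES are rejected with errors naming the
string (single-molecule entry points) or skipped with a counted warning
(corpus fitting). A constant descriptor hits the sigma floor and triggers
a warning rather than dividing by zero. Zero-norm projections refuse to
L2-normalize. Degenerate decoding (a model that emits [SEP] immediately)
yields the empty string, which the metrics count as invalid.

## Problem sizes used by the test-suite and acceptance runs

The shipped end-to-end runs use a 2,000-molecule corpus, a
64-dimensional, 2+2-layer model with P = 12, batch 8, 500 optimizer steps
(the acceptance script scales to 1,000 molecules / 300 steps), 20-pair
reaction memorization, and 100 held-out molecules for property prediction.
These sizes were chosen as the smallest at which convergence, generation
validity and cross-modal transfer are reliably observable.

## Known limitations

* Stereochemistry is invisible to the default descriptors, so stereoisomers
  collapse to the same PV (a stated non-goal).
* The scaffold splitter identifies scaffolds by canonical colored-graph
  labeling (elements + bond orders) of the pruned ring-and-linker graph;
  this is compatible with Bemis-Murcko grouping but is a graph key, not a
  scaffold SMILES.
* The R implementation favors clarity over throughput: it is intended for
  desk-scale models, method development, and exact oracle testing, not for
  the multi-GPU pre-training regime.
* QED is not in the default registry (no installed backend computes it);
  any external implementation can be registered as a custom descriptor.
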