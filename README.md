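# molfusion

Dual-stream multimodal transformer for molecular structure and properties,
in pure R.

## The problem

Chemists routinely need both directions of the structure-property map:
predicting descriptor panels from a structure, and proposing structures
that satisfy partial property specifications ("molar mass near 150, two
rings, the rest unconstrained"). molfusion treats the two as translation
between languages. A molecule is represented twice: as a SMILES string
tokenized into BPE subwords, and as a **property vector (PV)** — a
fixed-order list of P scalar descriptors, z-scored with corpus statistics,
any subset of which may be masked as `[UNK]` ("unspecified").

Two transformer encoders (one per modality) produce `[CLS]`-summarized
feature sequences; a weight-shared fusion encoder cross-attends one
modality to the other. Pre-training jointly optimizes

- a queue-based **contrastive loss** aligning projected `[CLS]` features of
  matched SMILES/PV pairs (temperature-scaled softmax over in-batch and
  queued momentum-teacher candidates, intermodal and intramodal),
- **next-word prediction** (causal SMILES decoding conditioned on the PV),
- **next-property prediction** (causal scalar regression conditioned on the
  SMILES, `[UNK]` targets excluded),
- a **matching head** over positives and similarity-proportional hard
  negatives,

with an EMA momentum teacher (lambda = 0.995) supplying soft pseudo-labels
mixed at weight alpha (ramped 0 to 0.4 over the first epoch):

    L = L_contrastive + L_NWP + L_NPP + L_SPM

The pre-trained model then generates SMILES from partial PVs (greedy /
stochastic / beam decoding), predicts full PVs from SMILES
autoregressively, exposes property-to-subword cross-attention maps, and
fine-tunes for scalar prediction ( `[CLS]_S` + MLP head) or forward/retro
reaction seq2seq — all from one checkpoint.

Everything runs self-contained: descriptors come from an Open Babel backed
registry (53-descriptor default panel, fully configurable), and
deterministic toy-corpus/reaction generators stand in for large corpora at
desk scale.

## Worked example

```r
library(molfusion)

corpus <- generate_toy_corpus(toy_corpus_spec(2000, seed = 7))
cfg <- model_config(hidden_dim = 64, n_heads = 4, n_layers_unimodal = 2,
                    n_layers_fusion = 2, n_properties = 12, vocab_size = 1,
                    contrastive_dim = 32)
sch <- pretrain_schedule(total_steps = 500, batch_size = 8,
                         queue_capacity = 256, lr_peak = 1e-3,
                         lr_end = 1e-4)
ck <- pretrain(corpus, cfg, sch, registry = toy_registry(),
               vocab_size = 300, seed = 42)

# property prediction for a molecule the model has not seen
generate_pv("CC(=O)OCC", ck)[c("MW", "logP", "atoms")]

# molecules conditioned on molar mass ~ 120, everything else [UNK]
pv <- condition_pv(c(MW = 120), ck)
set.seed(1)
gen <- generate_smiles(pv, ck, generation_config("stochastic", max_len = 60),
                       n_samples = 50)
generation_metrics(gen, smiles_canonical(corpus))
```

On this 2,000-molecule toy corpus the 500-step run drives the combined
objective down by about 20% (first-50 vs last-50 step mean; re-scoring the initial
against the final parameters on identical batches at a fixed label mix
shows a 41% improvement), molar-mass predictions on 100 held-out molecules
correlate with the truth at Pearson r = 0.84, and 20 of 20 unconditionally
sampled strings parse as valid molecules. The `generation_metrics()` call prints validity / uniqueness /
novelty fractions as defined by valid/generated, distinct-canonical/valid,
and not-in-corpus/unique.

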