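---
title: "KB-refined weak supervision for drug-protein relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KB-refined weak supervision for drug-protein relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbrelex)
```

## The problem and the procedure

Biomedical relation extraction (BioRE) classifies the semantic relation
between two entities mentioned in text -- here, a chemical/drug and a
gene/protein co-occurring in one sentence of a PubMed-style abstract, using
the 13 DrugProt relation types (`relation_labels()`) plus a `NONE` sentinel
for co-occurring pairs with no asserted relation. Hand-labelled corpora for
this task are small and expensive, which motivates *weak supervision*:
train a model on the available gold data, let it label a large unlabelled
corpus, and train on those pseudo-labels.

Model-generated labels are noisy, and so are labels distantly projected
from a knowledge base (a sentence mentioning a KB-related pair need not
express the relation). The system implemented here combines the two
signals to cancel part of both noise sources. It has three phases:

1. **Build the augmented dataset.** A classifier trained on the gold
   corpus predicts a label for every within-sentence chemical x gene
   candidate pair of an unlabelled document pool. Each prediction is then
   checked against a chemical-gene knowledge base (a CTD-style interaction
   table): the KB is used *only* as a pair-presence test, never for the
   relation type, because the KB's labelling schema differs from the
   corpus's. A prediction is kept iff it *agrees* with the KB:
   positive-label predictions whose pair is present, and `NONE`
   predictions whose pair is absent. Sequences without agreement are
   dropped ([refine()]).
2. **Weak pretraining.** A fresh classifier is fitted on the kept,
   weakly labelled examples.
3. **Fine-tuning.** Its parameters are transferred
   ([export_params()]/[import_params()]) and training continues on the
   original human-labelled examples.

The package implements every stage behind explicit contracts -- corpus and
KB readers, sentence splitting and entity marking, the KB index and
agreement filter, a reference classifier, the two-phase trainer, the
DrugProt-semantics scorer, prediction ensembling -- plus a seeded synthetic
corpus generator so the full pipeline can be exercised and validated
without downloading any licensed resource.

### The agreement rule for NONE predictions

The filtering rule for positive predictions (keep iff the pair is in the
KB) forces a decision for `NONE` predictions that pair-presence checking
alone does not determine. We adopt the symmetric rule: `NONE` predictions
are kept only when the pair is *absent* from the KB. The rationale is that
a `NONE` prediction on a KB-listed pair is exactly the case where the two
signals disagree -- the KB asserts a relation exists between the entities
somewhere, so the model's negative call is suspect -- and the accounting of
kept versus dropped pair combinations in the system this package models
implies negatives were filtered as well. The refinement never rewrites a
label; it only keeps or drops, and the `RefineReport` breakdown
(model positive/negative x KB present/absent) makes the four cells
auditable.

## Input conventions

* **Offsets.** `full_text` is title and abstract joined by a single tab;
  all entity offsets are 0-based, end-exclusive character indices into it.
  This convention is asserted on load: every mention must slice
  `full_text` to exactly its surface string, and violations are load
  errors naming the mention.
* **Sentence splitting** is a plug-in contract (text in, ordered
  non-overlapping offset windows out). The built-in `rule_splitter()`
  breaks after sentence-final punctuation followed by whitespace and at
  the title/abstract tab; any external splitter (e.g. a wrapper around a
  neural sentence segmenter) can be substituted. Mentions straddling a
  window boundary after splitting are dropped and counted, not errors.
* **Entity linking.** KB lookups need normalized identifiers. Mentions
  carry an optional `norm_id`; when absent, the case-folded,
  whitespace-collapsed surface form is matched against the KB's name
  columns ([build_kb_index()] keeps name-to-id maps for this). Unlinkable
  pairs count as "unlinked" and fail the presence test.

## Entity marking

Four marking methods render the candidate pair into the input sequence:

| method | example |
|---|---|
| `NONE` | `Alendronate was a slow-binding inhibitor of PTPmeg1.` |
| `MASK` | `CHEM was a slow-binding inhibitor of GENE.` |
| `WRAP_TYPE` | `CHEM Alendronate CHEM was ... of GENE PTPmeg1 GENE.` |
| `WRAP_TYPE_SE` | `CHEM-S Alendronate CHEM-E was ... of GENE-S PTPmeg1 GENE-E.` |

`WRAP_TYPE_SE` (distinct start/end tokens per type, entities not
anonymized) is the default, matching the configuration that performed best
in the ablations of the modelled system; the marker strings are
configurable and are declared to the classifier as atomic vocabulary
items (asserted at configuration time). One sequence carries one pair:
other mentions in the sentence stay raw text, because the classifier
scores a single pair per input. Marking is invertible for `WRAP_TYPE_SE`
-- deleting the four markers and their padding spaces restores the
sentence byte-for-byte -- which the test suite property-checks.

Two deliberate conventions where the design was open: for overlapping or
nested spans, markers are inserted at descending positions with the
chemical markers outside on exact ties, which keeps the output
deterministic and invertible; and sentences longer than
`max_sequence_chars` (default 1000 characters, effectively off for
abstract-length sentences) are truncated symmetrically around the pair
span with a logged count.

## The reference classifier

The classification contract is: marked sequence in, normalized
per-label score vector out, argmax label with ties resolved toward the
lower enum index in `relation_labels()`. `NONE` is a 14th predicted class
rather than a threshold on the positives, matching the confusion-matrix
framing in which `NONE` predictions are a real outcome (and generate no
false positives in scoring).

The shipped backbone is deliberately desk-scale: a multinomial logistic
model over hashed token n-gram features (unigrams and bigrams, default
16384 buckets plus an intercept) of the marked sequence, trained by
mini-batch SGD. Marker tokens participate as ordinary features, so their
weights are trainable parameters -- the desk-scale analogue of trainable
marker-token embeddings in a transformer. Transformer backbones attach
through the same `relex_fit()`/`predict()`/`export_params()` contract;
nothing downstream of the contract changes.

The learning-rate schedule is the linear warmup/decay scheduler with warm
rate $w = 0.05$: $\mathrm{lr}(s) = \eta\, s/(wT)$ for $s \le wT$, then
$\eta\,(T-s)/((1-w)T)$, reaching $\eta$ exactly once at $s = wT$ and 0 at
$s = T$. Tunables and defaults: `peak_lr` ($\eta$, default 0.5 --
appropriate for count features in a linear model; transformer-scale rates
like 2e-5 belong to transformer adapters), `max_steps` ($T$, default
300), `batch_size` (32), `warm_rate` (0.05), `hash_dim` (16384), `ngram`
(2), `l2` (0). Fitting is deterministic given data order, configuration
and seed; checkpoints can be snapshotted every `checkpoint_every` steps
(default cadence 2000 in the training orchestration, the smallest
published interval) and `select_checkpoint()` picks the best development
micro-F1 with earliest-step ties.

## Training orchestration

`pretrain_finetune()` runs phase 2 and 3 and logs the phase boundaries.
With an empty augmented set it degrades to single-phase training with a
warning; with zero fine-tune steps it is a pure transfer and reproduces
the phase-1 model's predictions exactly (a tested identity).

`resplit_train_dev()` implements the train+dev merging strategy: the
union of training and development document ids is split into $k = 10$
disjoint partitions and each partition serves once as the development set
of a reorganized pair. Partitioning is at the *document* level -- all
sequences from one abstract stay together -- the conservative reading that
avoids leaking sentences of one abstract across the split. Stratification
by relation type is not attempted (whether the original used it is
unstated); the partition laws (disjointness, coverage, seed
reproducibility) are property-tested.

## Evaluation semantics

`evaluate_relations()` scores with DrugProt tuple-match semantics: a
prediction `(pmid, arg1, arg2, type)` is a true positive iff an identical
gold tuple exists; a wrongly typed pair costs one FP of the predicted
type and one FN of the gold type; `NONE` predictions generate no FP;
multiple gold types per pair are allowed. Micro-averaged scores sum
TP/FP/FN over the 13 positive types. Zero-denominator precision or recall
is reported as 0, the common challenge-scorer convention. Duplicate
identical prediction tuples are de-duplicated with a warning, making the
scorer invariant to prediction order and duplication (both
property-tested against a brute-force set-intersection oracle).
`confusion_relations()` counts (gold, predicted) label cells per pair key
with `NONE` rows/columns for misses and spurious pairs, and can omit the
`NONE` prediction column for rendering. `diff_reports()` returns
cell-wise differences between two reports in percentage points;
`dev_report_pair()` ships a published baseline/weak-supervision report
pair as a worked input for it.

## The synthetic corpus generator

`generate_fixtures()` emulates the three inputs the pipeline needs --
abstracts with character-exact entity annotations, gold relations, and a
CTD-style KB -- under full experimental control:

* Positive sentences are built from per-type trigger templates (two to
  three phrasings per type with type-specific trigger vocabulary);
  negative sentences use neutral co-occurrence templates and appear with
  probability `p_negative_cooccurrence` (default 0.3). Triggers are
  unambiguous by construction so that a desk-scale classifier can learn
  them and directional experiments are stable; the only injected
  ambiguity is the negative co-occurrence.
* The label distribution defaults to the DrugProt training-split
  proportions recomputed from the published per-type counts
  (`drugprot_label_distribution()`), *including* the three rare types
  below 0.3%, so the rare-class behaviour of the task is represented.
* Each distinct planted positive pair enters the KB independently with
  probability `kb_coverage` (default 0.9); `kb_noise` (default 50) extra
  pairs never expressed in the text are added with out-of-corpus
  supporting PMIDs. Bernoulli inclusion per distinct pair makes the
  expected instance-level kept-positive fraction after refinement equal
  `kb_coverage` exactly, which the acceptance suite checks to within
  three standard errors over seeds.
* Bundles are byte-deterministic given the configuration. Splits can
  share a lexicon (`lexicon_seed`) while keeping disjoint PMID ranges
  (`pmid_start`), the way real corpus splits share vocabulary.

What the generator does *not* emulate: linguistic variety beyond the
templates, discontinuous or nested gold entities, document-level or
cross-sentence relations, entity-linking ambiguity (surfaces map 1:1 to
norm ids), and realistic trigger/label ambiguity. Passing the recovery
experiment on this corpus therefore demonstrates that the pipeline's
plumbing, filtering and transfer mechanics behave as designed -- not that
the system reaches any particular accuracy on real biomedical text.

## The acceptance experiment

`run_weak_experiment()` wires the whole system together at a size chosen
to run comfortably on one CPU: a labelled split of 30 documents, a weak
pool ten times that size (300 documents), and a 100-document development
split, all sharing one lexicon; KB coverage 0.9 with 50 noise pairs;
pretraining for 600 steps and both baseline and fine-tuning for 300
steps. The quantities it returns -- baseline and two-phase development
micro-F1, the kept-positive fraction under a perfect classifier, and the
refine report -- are exactly what `scripts/acceptance.R` recomputes over
ten seeds. The labelled split is kept deliberately small relative to the
weak pool because that is the regime weak supervision targets: the
baseline undersamples the template/entity combinations, while the
KB-filtered pool supplies broader, mostly-correct coverage for
pretraining. The per-seed improvement of the two-phase system is modest
relative to seed-to-seed variance — weak-supervision gains are small by
nature, here as in the full-scale systems this package models — so the
directional check is evaluated at fixed seeds and the mean gain is the
more stable summary.

## Known limitations

* The reference backbone is a bag-of-n-grams linear model; it cannot
  represent long-range syntax, and its ceiling on real corpora is far
  below transformer backbones. It exists to make every downstream stage
  testable and transferable, not to be competitive.
* KB agreement checks pair presence only, so type-confusion errors on
  KB-listed pairs survive filtering (by design, since the KB and corpus
  schemas are incommensurable); only presence/absence noise is reduced.
* The dictionary tagger ([tag_entities_dictionary()]) is exact-match
  only -- no abbreviation expansion, no overlapping-mention resolution --
  and is intended for synthetic or pre-normalized text, standing in for
  external neural NER services, which are consumed as given annotations.
* Scoring assumes at most one prediction per (pair, type); systems
  emitting ranked multi-label output must expand to tuples first.
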