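# kbrelex

Knowledge-base-refined weak supervision for drug–protein relation
extraction.

## What this package is for

Biomedical relation extraction (BioRE) assigns one of the 13 DrugProt
relation types (INHIBITOR, SUBSTRATE, AGONIST, …) — or no relation — to a
chemical/drug and a gene/protein mentioned together in one sentence.
Gold-annotated corpora for this task are small, so a common strategy is
*weak supervision*: a model trained on the gold data labels a large
unlabelled corpus, and training continues on those pseudo-labels. Those
labels are noisy; this package implements the refinement that filters them
against a chemical–gene knowledge base (a CTD-style interaction table)
before they are used.

The core rule is an **agreement filter** over model predictions. For a
candidate pair with predicted label $\hat y$ and KB pair-presence indicator
$k \in \{0, 1\}$ (presence only — relation types are never compared,
because KB and corpus schemas differ):

$$\text{keep} \iff (\hat y \ne \text{NONE} \land k = 1)\ \lor\ (\hat y = \text{NONE} \land k = 0)$$

Sequences without agreement are dropped. The kept examples form the
augmented dataset used in a three-phase scheme: (1) build the augmented
dataset, (2) pretrain a sequence classifier on it, (3) transfer the weights
and fine-tune on the original human-labelled corpus. Evaluation uses
DrugProt micro-F1 semantics: a prediction tuple *(pmid, arg1, arg2, type)*
is a true positive iff an identical gold tuple exists, with
$F_1 = 2PR/(P+R)$ from TP/FP/FN summed over the 13 positive types.

The package is aimed at BioRE practitioners and method developers who want
the full pipeline — DrugProt/CTD-style IO, sentence splitting, entity-marker
encoding, KB indexing and agreement filtering, two-phase training,
ensembling, scoring — as testable, seedable R functions, with a synthetic
corpus generator so everything runs end to end without licensed downloads.
The shipped classifier backbone is a desk-scale hashed n-gram softmax
model; transformer backbones attach through the same
fit/predict/export-parameters contract.

## Worked example

Generate a seeded synthetic corpus, train, weakly label, KB-filter, and
score:

```r
library(kbrelex)

bundle <- generate_fixtures(fixture_config(n_docs = 40, seed = 7))
bundle
#> <fixture_bundle> 40 documents, 181 planted pairs ( 130 positive ), 162 KB rows

pairs <- preprocess_corpus(bundle$docs, method = "WRAP_TYPE_SE")
pairs$marked[1]
#> CHEM-S zoljatone CHEM-E was administered while GENE-S QXW7 GENE-E expression was monitored.

model <- relex_fit(relex_model(classifier_config(max_steps = 200, seed = 1)),
                   pairs$marked, pairs$label)
preds <- as_predictions(pairs, predict(model, pairs$marked))

res <- refine(preds, build_kb_index(bundle$kb))
res$report
#> <refine_report> input: 181  kept: 162  dropped: 19  unlinked: 0
#>           kb
#> model      present absent
#>   positive     119     11
#>   negative       8     43

evaluate_relations(planted_truth(bundle), preds)
#> <eval_report> micro P/R/F1 = 100.00/100.00/100.00 (%) over 130 gold tuples
```

Reading the refine report: of 181 predictions, the 119 positive-label
predictions whose pair is in the KB and the 43 NONE predictions whose pair
is absent are kept (162 = 119 + 43); the 11 positives missing from the KB
(the KB covers 90% of planted pairs by default) and the 8 NONE calls on
KB-listed pairs are dropped. The perfect training-set F1 reflects the
deliberately unambiguous trigger templates of the generator — see the
vignette for what that does and does not demonstrate.

The two-phase experiment (weak pretraining then fine-tuning versus the
labelled-only baseline, with a 10x weak pool) is one call:

```r
run_weak_experiment(seed = 1)
```

A command-line interface mirroring the pipeline stages
(`gen-fixtures`, `preprocess`, `train`, `predict`, `refine`,
`build-augmented`, `pretrain-finetune`, `resplit`, `evaluate`,
`ensemble`) is installed at `system.file("cli", "kbrelex",
package = "kbrelex")`.

## Package layout

| module | contents |
|---|---|
| `R/formats_io.R` | DrugProt corpus, CTD-style KB, and prediction file IO with strict offset validation |
| `R/preprocess.R` | sentence splitting (pluggable), span projection, pair enumeration, entity marking |
| `R/kb_refine.R` | KB pair index, agreement filter, dev-overlap exclusion |
| `R/classifier.R` | reference backbone, LR schedule, parameter export/import |
| `R/training.R` | two-phase training, checkpoints, document-level resplit |
| `R/evaluation.R` | micro/per-type P/R/F1, confusion matrices, report diffs |
| `R/ensemble.R` | soft-vote / majority combination |
| `R/fixtures.R` | seeded synthetic corpus + KB generator |
| `R/cli.R`, `R/config.R` | subcommand CLI and layered configuration |
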