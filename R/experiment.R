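# End-to-end weak-supervision experiment on synthetic corpora: compares a
# classifier trained on the labelled split alone against the two-phase
# system (weak pretraining on the KB-refined augmented pool, then
# fine-tuning on the labelled split), both scored on a held-out development
# split. Used by the acceptance checks and reproducible from a single seed.

#' Run one seeded weak-supervision experiment
#'
#' Generates three corpus splits sharing one chemical/gene lexicon but with
#' disjoint PMID ranges: a small labelled split, a weak-labelling pool
#' `weak_multiple` times its size, and a development split. The KB is the
#' weak pool's own KB (coverage `kb_coverage` of its planted positive
#' pairs plus `kb_noise` unexpressed pairs). The baseline model is fitted
#' on the labelled split only; the two-phase model first predicts labels on
#' the weak pool, keeps the KB-agreeing predictions as the augmented
#' dataset, pretrains on it, and fine-tunes on the labelled split. Both
#' models are scored against the development split's planted truth.
#'
#' @param seed Integer seed controlling every random choice in the run.
#' @param n_labelled Number of documents in the labelled split.
#' @param weak_multiple Weak-pool size as a multiple of `n_labelled`.
#' @param n_dev Number of development documents.
#' @param kb_coverage,kb_noise,p_negative_cooccurrence Generator settings
#'   for all three splits (see [fixture_config()]).
#' @param pretrain_steps,finetune_steps,baseline_steps Optimization steps
#'   for the respective fits.
#' @param pretrain_lr,finetune_lr,baseline_lr Peak learning rates for the
#'   respective fits (all default to the backbone default; exposed so the
#'   fine-tuning rate can be lowered independently when adapting a
#'   pretrained model).
#' @param marking Marking method used throughout.
#' @return List with `baseline_f1`, `two_phase_f1` (development micro-F1),
#'   `kept_positive_fraction` (fraction of the weak pool's planted positive
#'   instances kept by KB refinement when the predictions are the planted
#'   truth itself, i.e. under a perfect classifier), `n_augmented`,
#'   `refine_report`, and the split sizes.
#' @export
run_weak_experiment <- function(seed, n_labelled = 30, weak_multiple = 10,
                                n_dev = 100, kb_coverage = 0.9,
                                kb_noise = 50,
                                p_negative_cooccurrence = 0.3,
                                pretrain_steps = 600, finetune_steps = 300,
                                baseline_steps = 300, pretrain_lr = 0.5,
                                finetune_lr = 0.5, baseline_lr = 0.5,
                                marking = "WRAP_TYPE_SE") {
  s0 <- as.integer(seed) * 10L
  mk_cfg <- function(n_docs, sub_seed, pmid_start) {
    fixture_config(n_docs = n_docs, kb_coverage = kb_coverage,
                   kb_noise = kb_noise,
                   p_negative_cooccurrence = p_negative_cooccurrence,
                   seed = s0 + sub_seed, lexicon_seed = s0,
                   pmid_start = pmid_start)
  }
  labelled_b <- generate_fixtures(mk_cfg(n_labelled, 1L, 1000001L))
  weak_b <- generate_fixtures(mk_cfg(n_labelled * weak_multiple, 2L,
                                     2000001L))
  dev_b <- generate_fixtures(mk_cfg(n_dev, 3L, 3000001L))

  labelled <- preprocess_corpus(labelled_b$docs, method = marking)
  weak <- preprocess_corpus(weak_b$docs, method = marking)
  dev <- preprocess_corpus(dev_b$docs, method = marking)
  dev_gold <- planted_truth(dev_b)

  # baseline: labelled split only
  base_cfg <- classifier_config(max_steps = baseline_steps,
                                peak_lr = baseline_lr, seed = s0 + 4L)
  baseline <- relex_fit(relex_model(base_cfg), labelled$marked,
                        labelled$label)
  base_eval <- evaluate_relations(
    dev_gold, as_predictions(dev, predict(baseline, dev$marked)))

  # weak labelling + KB refinement
  kb_index <- build_kb_index(weak_b$kb)
  weak_preds <- as_predictions(weak, predict(baseline, weak$marked))
  refined <- refine(weak_preds, kb_index)
  akey <- pair_key_str(refined$augmented$pmid, refined$augmented$arg1,
                       refined$augmented$arg2)
  wkey <- pair_key_str(weak$pmid, weak$arg1, weak$arg2)
  augmented <- tibble::tibble(
    marked = weak$marked[match(akey, wkey)],
    label = refined$augmented$label
  )

  # two-phase: pretrain on augmented, fine-tune on labelled
  pre_cfg <- classifier_config(max_steps = pretrain_steps,
                               peak_lr = pretrain_lr, seed = s0 + 5L)
  fine_cfg <- classifier_config(max_steps = finetune_steps,
                                peak_lr = finetune_lr, seed = s0 + 6L)
  two <- pretrain_finetune(augmented, labelled, pre_cfg, fine_cfg)
  two_eval <- evaluate_relations(
    dev_gold, as_predictions(dev, predict(two$model, dev$marked)))

  # refinement recovery under a perfect classifier: feed the planted truth
  # of the weak pool through the same KB filter
  man <- weak_b$manifest
  perfect <- tibble::tibble(pmid = man$pmid, arg1 = man$arg1,
                            arg2 = man$arg2, label = man$label,
                            chem_id = man$chem_id, gene_id = man$gene_id)
  perfect_ref <- refine(perfect, kb_index)
  n_pos <- sum(perfect$label != "NONE")
  kept_pos <- sum(perfect_ref$augmented$label != "NONE")

  list(
    baseline_f1 = base_eval$micro$f1,
    two_phase_f1 = two_eval$micro$f1,
    kept_positive_fraction = if (n_pos > 0) kept_pos / n_pos else NA_real_,
    n_augmented = nrow(augmented),
    refine_report = refined$report,
    sizes = c(labelled = nrow(labelled), weak = nrow(weak),
              dev = nrow(dev))
  )
}
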