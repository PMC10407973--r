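# Three-phase orchestration: weak pretraining on the KB-refined augmented
# dataset, weight transfer, and fine-tuning on the human-labelled original
# dataset; plus the document-level train+dev resplit strategy and
# checkpoint selection.

#' Checkpoint record
#'
#' @param step Optimization step at which the snapshot was taken.
#' @param params Exported classifier parameters ([export_params()]).
#' @param dev_f1 Development micro-F1 measured at save time (may be `NA`).
#' @return A list of class `checkpoint`.
#' @export
make_checkpoint <- function(step, params, dev_f1 = NA_real_) {
  structure(list(step = as.integer(step), params = params,
                 dev_f1 = as.numeric(dev_f1)),
            class = "checkpoint")
}

#' Select the best checkpoint by development F1
#'
#' Returns the checkpoint with maximal `dev_f1`; ties resolve to the
#' earliest step.
#'
#' @param checkpoints Non-empty list of [make_checkpoint()] records with
#'   `dev_f1` set.
#' @return The selected `checkpoint`.
#' @export
select_checkpoint <- function(checkpoints) {
  if (length(checkpoints) == 0) stop("no checkpoints to select from",
                                     call. = FALSE)
  f1 <- vapply(checkpoints, function(c) c$dev_f1, numeric(1))
  steps <- vapply(checkpoints, function(c) c$step, integer(1))
  if (anyNA(f1)) stop("all checkpoints must carry dev_f1", call. = FALSE)
  best <- which(f1 == max(f1))
  checkpoints[[best[which.min(steps[best])]]]
}

#' Two-phase training: weak pretrain, transfer, fine-tune
#'
#' Phase 1 fits a classifier on the augmented (weakly labelled) examples;
#' its parameters are exported and imported into a fresh model which is
#' then fine-tuned on the original human-labelled examples. With an empty
#' augmented set the function falls back to single-phase training with a
#' warning. Setting `finetune_cfg$max_steps = 0` yields pure transfer: the
#' returned model predicts identically to the phase-1 model.
#'
#' @param augmented Tibble with columns `marked` (input sequence) and
#'   `label`, typically the output of [refine()] joined back onto marked
#'   candidate pairs.
#' @param original Tibble with columns `marked` and `label`: the
#'   human-labelled training examples.
#' @param pretrain_cfg,finetune_cfg [classifier_config()]s for the two
#'   phases.
#' @return List with `model` (the fine-tuned [relex_model()]), `phase1`
#'   (the pretrained model) and `log` (tibble of phase boundaries and step
#'   counts).
#' @export
pretrain_finetune <- function(augmented, original, pretrain_cfg,
                              finetune_cfg) {
  stopifnot(nrow(original) > 0)
  if (is.null(augmented) || nrow(augmented) == 0) {
    warning("empty augmented set; falling back to single-phase training",
            call. = FALSE)
    model <- relex_fit(relex_model(finetune_cfg), original$marked,
                       original$label)
    log <- tibble::tibble(phase = "finetune", n_examples = nrow(original),
                          steps = finetune_cfg$max_steps)
    return(list(model = model, phase1 = NULL, log = log))
  }
  phase1 <- relex_fit(relex_model(pretrain_cfg), augmented$marked,
                      augmented$label)
  params <- export_params(phase1)
  model <- relex_fit(relex_model(finetune_cfg), original$marked,
                     original$label, init = params)
  log <- tibble::tibble(
    phase = c("pretrain", "finetune"),
    n_examples = c(nrow(augmented), nrow(original)),
    steps = c(pretrain_cfg$max_steps, finetune_cfg$max_steps)
  )
  list(model = model, phase1 = phase1, log = log)
}

#' Document-level train/dev resplit plan
#'
#' Merges the training and development document id sets and splits them
#' into `k` disjoint partitions at the document level (all sequences from
#' one abstract stay together). Each of the `k` train/dev pairs uses one
#' partition as the development set and the remaining `k - 1` as training.
#' The plan is reproducible from `seed`.
#'
#' @param train_ids,dev_ids Character vectors of document ids (PMIDs).
#' @param k Number of partitions (default 10).
#' @param seed Integer seed.
#' @return Object of class `resplit_plan`: `k`, `seed`, `partitions` (list
#'   of id vectors) and `pairs` (list of `list(train_ids, dev_ids)`).
#' @export
resplit_train_dev <- function(train_ids, dev_ids, k = 10, seed = 0) {
  ids <- unique(c(as.character(train_ids), as.character(dev_ids)))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > length(ids)) {
    stop("k (", k, ") exceeds the number of documents (", length(ids), ")",
         call. = FALSE)
  }
  restore <- local_seed(as.integer(seed))
  on.exit(restore())
  shuffled <- sample(ids)
  fold <- rep_len(seq_len(k), length(ids))
  partitions <- split(shuffled, fold)
  names(partitions) <- NULL
  pairs <- lapply(seq_len(k), function(i) {
    list(train_ids = sort(unlist(partitions[-i], use.names = FALSE)),
         dev_ids = sort(partitions[[i]]))
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 partitions = lapply(partitions, sort), pairs = pairs),
            class = "resplit_plan")
}

#' @export
print.resplit_plan <- function(x, ...) {
  cat("<resplit_plan>", x$k, "partitions over",
      length(unlist(x$partitions)), "documents (seed", x$seed, ")\n")
  invisible(x)
}
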