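# Published DrugProt corpus statistics and a bundled pair of development-set
# result tables, shipped as plain-text inputs for arithmetic checks and as
# defaults for the synthetic-corpus generator.

ref_path <- function(file) {
  system.file("extdata", file, package = "kbrelex", mustWork = TRUE)
}

read_ref_tsv <- function(file) {
  readr::read_tsv(ref_path(file), show_col_types = FALSE, progress = FALSE)
}

#' Published per-type relation counts of the DrugProt corpus
#'
#' Returns the per-type data-point counts and printed percentages of the
#' DrugProt training and development splits, as distributed with the
#' corpus. Note the printed percentages are rounded to one decimal and two
#' rows are internally inconsistent with their counts at that precision
#' (train INHIBITOR and dev SUBSTRATE); recompute from counts when exact
#' shares are needed.
#'
#' @return Tibble with columns `type`, `train_count`, `train_pct`,
#'   `dev_count`, `dev_pct`.
#' @export
drugprot_relation_counts <- function() {
  read_ref_tsv("drugprot_relation_counts.tsv")
}

#' Published dataset sizes: original DrugProt vs augmented
#'
#' The number of input sequences in the original DrugProt train/development
#' splits and in the KB-refined augmented training set.
#'
#' @return Tibble with columns `dataset`, `train`, `development`.
#' @export
drugprot_dataset_sizes <- function() {
  read_ref_tsv("drugprot_dataset_sizes.tsv")
}

#' Relation-type distribution of the DrugProt corpus
#'
#' Per-type proportions recomputed from the published counts (not the
#' rounded printed percentages). Used as the default label distribution of
#' the synthetic-corpus generator.
#'
#' @param split `"train"` or `"dev"`.
#' @return Named numeric vector over the 13 positive types, summing to 1.
#' @export
drugprot_label_distribution <- function(split = c("train", "dev")) {
  split <- match.arg(split)
  counts <- drugprot_relation_counts()
  x <- if (split == "train") counts$train_count else counts$dev_count
  stats::setNames(x / sum(x), counts$type)
}

#' Bundled development-set report pair (baseline vs weak-supervision)
#'
#' A published pair of development-set metric tables for a DrugProt
#' relation-extraction system: a baseline model trained on the original
#' corpus only, and the same architecture pretrained on a KB-refined weakly
#' labelled dataset before fine-tuning. Shipped as an example input for
#' [diff_reports()].
#'
#' @return List with `baseline` and `transfer`, both [as_eval_report()]
#'   objects.
#' @export
dev_report_pair <- function() {
  load1 <- function(file) {
    tab <- read_ref_tsv(file)
    micro <- tab[tab$type == "Micro-average", ]
    per <- tab[tab$type != "Micro-average", ]
    as_eval_report(per, list(precision = micro$precision,
                             recall = micro$recall, f1 = micro$f1))
  }
  list(baseline = load1("dev_report_baseline.tsv"),
       transfer = load1("dev_report_transfer.tsv"))
}
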