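# DrugProt scoring semantics: a prediction tuple (pmid, arg1, arg2, type) is
# a true positive iff an identical gold tuple exists; a wrongly typed pair
# costs one FP (predicted type) and one FN (gold type); NONE predictions
# generate no FP. Micro scores sum TP/FP/FN over the 13 positive types.

tuple_key <- function(pmid, arg1, arg2, type) {
  paste(pmid, arg1, arg2, type, sep = "\r")
}

pair_key_str <- function(pmid, arg1, arg2) {
  paste(pmid, arg1, arg2, sep = "\r")
}

#' Score predictions against gold relations
#'
#' @param gold Tibble of gold tuples with columns `pmid`, `rtype`, `arg1`,
#'   `arg2` (e.g. a [document_set()]'s `relations`). Multiple gold types per
#'   pair are allowed.
#' @param predictions Tibble with `pmid`, `arg1`, `arg2`, `label`.
#'   Duplicate identical prediction tuples are de-duplicated with a warning.
#' @return Object of class `eval_report`: `per_type` (tibble of TP/FP/FN and
#'   precision/recall/F1 per positive type, as proportions), `micro`,
#'   `confusion` (from [confusion_relations()]), `n_gold`, `n_pred`.
#'   Empty denominators yield 0 by convention.
#' @export
evaluate_relations <- function(gold, predictions) {
  assert_labels(gold$rtype, allow_none = FALSE)
  assert_labels(predictions$label)
  pos <- predictions[predictions$label != "NONE", ]
  pkey <- tuple_key(pos$pmid, pos$arg1, pos$arg2, pos$label)
  if (anyDuplicated(pkey)) {
    warning("duplicate identical prediction tuples de-duplicated",
            call. = FALSE)
    pos <- pos[!duplicated(pkey), ]
    pkey <- pkey[!duplicated(pkey)]
  }
  gkey <- tuple_key(gold$pmid, gold$arg1, gold$arg2, gold$rtype)
  gold <- gold[!duplicated(gkey), ]
  gkey <- gkey[!duplicated(gkey)]

  matched_pred <- pkey %in% gkey
  matched_gold <- gkey %in% pkey
  types <- positive_labels()
  tp <- unname(vapply(types, function(t)
    sum(matched_pred & pos$label == t), integer(1)))
  fp <- unname(vapply(types, function(t)
    sum(!matched_pred & pos$label == t), integer(1)))
  fn <- unname(vapply(types, function(t)
    sum(!matched_gold & gold$rtype == t), integer(1)))
  prf <- function(tp, fp, fn) {
    p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    list(p = p, r = r, f = f)
  }
  per <- prf(tp, fp, fn)
  per_type <- tibble::tibble(
    type = types, tp = tp, fp = fp, fn = fn,
    precision = per$p, recall = per$r, f1 = per$f
  )
  mi <- prf(sum(tp), sum(fp), sum(fn))
  structure(
    list(per_type = per_type,
         micro = list(precision = mi$p, recall = mi$r, f1 = mi$f,
                      tp = sum(tp), fp = sum(fp), fn = sum(fn)),
         confusion = confusion_relations(gold, predictions),
         n_gold = nrow(gold), n_pred = nrow(pos)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> micro P/R/F1 =",
      sprintf("%.2f/%.2f/%.2f (%%)", 100 * x$micro$precision,
              100 * x$micro$recall, 100 * x$micro$f1),
      "over", x$n_gold, "gold tuples\n")
  invisible(x)
}

#' Confusion counts between gold and predicted relation labels
#'
#' Counts (gold label, predicted label) cells per pair key, with `NONE`
#' standing in for "no gold relation" / "no positive prediction". For a key
#' with several gold types, types matched by an identical prediction count
#' on the diagonal and remaining gold types are paired with remaining
#' predicted labels in enum order (then `NONE`).
#'
#' @inheritParams evaluate_relations
#' @param omit_none_pred Drop the `NONE` prediction column from the
#'   returned matrix (the usual rendering for confusion heat maps).
#' @return Integer matrix with gold labels as rows, predicted labels as
#'   columns.
#' @export
confusion_relations <- function(gold, predictions, omit_none_pred = FALSE) {
  labs <- relation_labels()
  mat <- matrix(0L, nrow = length(labs), ncol = length(labs),
                dimnames = list(gold = labs, predicted = labs))
  gk <- pair_key_str(gold$pmid, gold$arg1, gold$arg2)
  pk <- pair_key_str(predictions$pmid, predictions$arg1, predictions$arg2)
  keys <- unique(c(gk, pk))
  g_by <- split(gold$rtype, factor(gk, levels = keys))
  p_by <- split(predictions$label, factor(pk, levels = keys))
  for (k in keys) {
    G <- unique(g_by[[k]])
    P <- unique(p_by[[k]])
    P <- P[P != "NONE"]
    if (length(P) == 0) P <- "NONE"
    if (length(G) == 0) {
      for (p in P) mat["NONE", p] <- mat["NONE", p] + 1L
      next
    }
    G <- G[order(label_index(G))]
    P <- P[order(label_index(P))]
    hit <- intersect(G, P)
    for (t in hit) mat[t, t] <- mat[t, t] + 1L
    Gr <- setdiff(G, hit)
    Pr <- setdiff(P, hit)
    for (g in Gr) {
      p <- if (length(Pr) > 0) Pr[1] else "NONE"
      if (length(Pr) > 0) Pr <- Pr[-1]
      mat[g, p] <- mat[g, p] + 1L
    }
    for (p in Pr) mat["NONE", p] <- mat["NONE", p] + 1L
  }
  if (omit_none_pred) mat <- mat[, colnames(mat) != "NONE", drop = FALSE]
  mat
}

#' Build an evaluation report from a printed-style metric table
#'
#' Constructs an `eval_report` from per-type precision/recall/F1 given in
#' percent (the format challenge scorers print), e.g. to diff two published
#' result tables with [diff_reports()]. TP/FP/FN counts are unavailable in
#' this form and set to `NA`.
#'
#' @param per_type Tibble with columns `type`, `precision`, `recall`, `f1`
#'   (percent).
#' @param micro Named list or vector with `precision`, `recall`, `f1`
#'   (percent).
#' @return An `eval_report`.
#' @export
as_eval_report <- function(per_type, micro) {
  stopifnot(all(c("type", "precision", "recall", "f1") %in% names(per_type)))
  per_type <- tibble::tibble(
    type = per_type$type, tp = NA_integer_, fp = NA_integer_,
    fn = NA_integer_,
    precision = per_type$precision / 100,
    recall = per_type$recall / 100,
    f1 = per_type$f1 / 100
  )
  structure(
    list(per_type = per_type,
         micro = list(precision = micro[["precision"]] / 100,
                      recall = micro[["recall"]] / 100,
                      f1 = micro[["f1"]] / 100,
                      tp = NA_integer_, fp = NA_integer_, fn = NA_integer_),
         confusion = NULL, n_gold = NA_integer_, n_pred = NA_integer_),
    class = "eval_report"
  )
}

#' Difference between two evaluation reports, in percentage points
#'
#' Computes `b - a` for every precision/recall/F1 cell, per type and micro,
#' expressed in percentage points (the "Difference" columns of challenge
#' result tables).
#'
#' @param report_a,report_b `eval_report` objects over the same label set.
#' @return List with `per_type` (tibble of per-type differences) and
#'   `micro` (named numeric vector).
#' @export
diff_reports <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "eval_report"),
            inherits(report_b, "eval_report"))
  if (!identical(report_a$per_type$type, report_b$per_type$type)) {
    stop("reports cover different label sets", call. = FALSE)
  }
  pt <- tibble::tibble(
    type = report_a$per_type$type,
    precision = 100 * (report_b$per_type$precision -
                         report_a$per_type$precision),
    recall = 100 * (report_b$per_type$recall - report_a$per_type$recall),
    f1 = 100 * (report_b$per_type$f1 - report_a$per_type$f1)
  )
  micro <- c(
    precision = 100 * (report_b$micro$precision - report_a$micro$precision),
    recall = 100 * (report_b$micro$recall - report_a$micro$recall),
    f1 = 100 * (report_b$micro$f1 - report_a$micro$f1)
  )
  list(per_type = pt, micro = micro)
}

#' Render an evaluation report as an aligned text table (percent)
#'
#' @param report An `eval_report`.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written.
#' @export
render_eval_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  pt <- report$per_type
  lines <- c(
    sprintf("%-24s %8s %8s %8s", "Type", "Prec(%)", "Rec(%)", "F1(%)"),
    sprintf("%-24s %8.2f %8.2f %8.2f", pt$type, 100 * pt$precision,
            100 * pt$recall, 100 * pt$f1),
    sprintf("%-24s %8.2f %8.2f %8.2f", "Micro-average",
            100 * report$micro$precision, 100 * report$micro$recall,
            100 * report$micro$f1)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write an evaluation report as machine-readable JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(per_type = report$per_type, micro = report$micro,
         n_gold = report$n_gold, n_pred = report$n_pred),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(report)
}
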