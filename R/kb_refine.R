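# Knowledge-base pair index and KB-agreement filtering of model predictions.
# The KB is used only to check the *presence* of a chemical-gene pair; relation
# types are never compared against KB action codes.

#' Default identifier normalizer: case-fold and collapse whitespace
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_id <- function(x) stringr::str_squish(tolower(x))

#' Build a chemical-gene pair-presence index
#'
#' Collapses KB records to the set of distinct normalized
#' (chemical id, gene id) pairs. Duplicate pairs merge and their supporting
#' PMIDs are unioned. When the records carry name columns, normalized
#' name-to-id maps are also built so that surface forms can be linked to KB
#' identifiers as a fallback.
#'
#' @param records A `kb_records` tibble from [read_kb()], or any tibble with
#'   `chem_id`, `gene_id` and a `pmids` list column.
#' @param normalizer Function applied to every identifier (and name) before
#'   indexing; the same normalizer is applied again at lookup time.
#' @return Object of class `kb_index` with elements `pairs` (character
#'   vector of pair keys), `pair_pmids` (named list), `doc_pmids` (character
#'   vector: union of all supporting PMIDs), `chem_name2id`, `gene_name2id`,
#'   `normalizer`.
#' @export
build_kb_index <- function(records, normalizer = normalize_id) {
  chem <- normalizer(records$chem_id)
  gene <- normalizer(records$gene_id)
  key <- pair_key(chem, gene)
  pmids <- if ("pmids" %in% names(records)) records$pmids else
    rep(list(character(0)), nrow(records))
  pair_pmids <- tapply(pmids, key, function(p) sort(unique(unlist(p))),
                       simplify = FALSE)
  pair_pmids <- lapply(pair_pmids, function(p) if (is.null(p)) character(0) else p)

  name_map <- function(names_col, ids) {
    if (is.null(names_col)) return(character(0))
    ok <- !is.na(names_col) & nzchar(names_col)
    if (!any(ok)) return(character(0))
    nm <- normalizer(names_col[ok])
    first <- !duplicated(nm)
    stats::setNames(ids[ok][first], nm[first])
  }

  structure(
    list(
      pairs = sort(unique(key)),
      pair_pmids = pair_pmids,
      doc_pmids = sort(unique(unlist(pmids))),
      chem_name2id = name_map(records[["chem_name"]], chem),
      gene_name2id = name_map(records[["gene_name"]], gene),
      normalizer = normalizer
    ),
    class = "kb_index"
  )
}

pair_key <- function(chem, gene) paste(chem, gene, sep = "\x1f")

#' @export
print.kb_index <- function(x, ...) {
  cat("<kb_index>", length(x$pairs), "pairs,",
      length(x$doc_pmids), "supporting PMIDs\n")
  invisible(x)
}

#' Test presence of a chemical-gene pair in the KB
#'
#' A pure membership test, vectorized over pairs. Unset (`NA` or empty)
#' identifiers always return `FALSE`; the `n_unlinked` attribute counts
#' them.
#'
#' @param index A [build_kb_index()] object.
#' @param chem_id,gene_id Character vectors of identifiers (normalized with
#'   the index's normalizer before lookup).
#' @return Logical vector; attribute `n_unlinked`.
#' @export
kb_has_pair <- function(index, chem_id, gene_id) {
  stopifnot(inherits(index, "kb_index"))
  chem <- as.character(chem_id)
  gene <- as.character(gene_id)
  unlinked <- is.na(chem) | is.na(gene) | !nzchar(chem) | !nzchar(gene)
  out <- logical(length(chem))
  if (any(!unlinked)) {
    key <- pair_key(index$normalizer(chem[!unlinked]),
                    index$normalizer(gene[!unlinked]))
    out[!unlinked] <- key %in% index$pairs
  }
  attr(out, "n_unlinked") <- sum(unlinked)
  out
}

# Resolve prediction rows to KB identifiers: prefer an explicit norm id,
# else map the (normalized) surface form through the KB name dictionaries.
resolve_kb_ids <- function(predictions, index) {
  n <- nrow(predictions)
  take <- function(id_col, surf_col, map) {
    ids <- if (id_col %in% names(predictions))
      as.character(predictions[[id_col]]) else rep(NA_character_, n)
    miss <- is.na(ids) | !nzchar(ids)
    if (any(miss) && surf_col %in% names(predictions) && length(map) > 0) {
      ids[miss] <- unname(map[index$normalizer(
        as.character(predictions[[surf_col]][miss]))])
    }
    ids
  }
  list(chem = take("chem_id", "chem_surface", index$chem_name2id),
       gene = take("gene_id", "gene_surface", index$gene_name2id))
}

#' Filter model predictions by KB agreement
#'
#' Implements the agreement rule used to build the augmented weakly
#' labelled dataset: a prediction is KEPT iff its label is a positive
#' relation type and the pair is present in the KB, or its label is `NONE`
#' and the pair is absent. All other predictions are dropped ("sequences
#' without agreement are dropped"). Labels are never rewritten -- the kept
#' examples carry the model's own label.
#'
#' @param predictions Tibble with `pmid`, `arg1`, `arg2`, `label`, plus
#'   `chem_id`/`gene_id` (and/or `chem_surface`/`gene_surface` for
#'   name-based fallback linking).
#' @param index A [build_kb_index()] object.
#' @return List with `augmented` (kept rows plus `model_label` and
#'   `kb_present` provenance columns) and `report` (class `refine_report`:
#'   `n_input`, `n_kept`, `n_dropped`, `n_unlinked`, and a 2x2 `breakdown`
#'   of model positive/negative by KB present/absent).
#' @export
refine <- function(predictions, index) {
  stopifnot(all(c("pmid", "arg1", "arg2", "label") %in% names(predictions)))
  assert_labels(predictions$label)
  ids <- resolve_kb_ids(predictions, index)
  present <- kb_has_pair(index, ids$chem, ids$gene)
  n_unlinked <- attr(present, "n_unlinked")
  positive <- predictions$label != "NONE"
  keep <- (positive & present) | (!positive & !present)

  breakdown <- matrix(
    c(sum(positive & present), sum(positive & !present),
      sum(!positive & present), sum(!positive & !present)),
    nrow = 2, byrow = TRUE,
    dimnames = list(model = c("positive", "negative"),
                    kb = c("present", "absent"))
  )
  augmented <- predictions[keep, ]
  augmented$model_label <- augmented$label
  augmented$kb_present <- as.logical(present[keep])
  report <- structure(
    list(n_input = nrow(predictions), n_kept = sum(keep),
         n_dropped = sum(!keep), n_unlinked = n_unlinked,
         breakdown = breakdown),
    class = "refine_report"
  )
  list(augmented = augmented, report = report)
}

#' @export
print.refine_report <- function(x, ...) {
  cat("<refine_report> input:", x$n_input, " kept:", x$n_kept,
      " dropped:", x$n_dropped, " unlinked:", x$n_unlinked, "\n")
  print(x$breakdown)
  invisible(x)
}

#' Write a refine report as text and JSON
#'
#' @param report A `refine_report` from [refine()].
#' @param txt_path,json_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_refine_report <- function(report, txt_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "refine_report"))
  if (!is.null(txt_path)) {
    lines <- c(
      paste0("n_input\t", report$n_input),
      paste0("n_kept\t", report$n_kept),
      paste0("n_dropped\t", report$n_dropped),
      paste0("n_unlinked\t", report$n_unlinked),
      paste0("positive_kb_present\t", report$breakdown["positive", "present"]),
      paste0("positive_kb_absent\t", report$breakdown["positive", "absent"]),
      paste0("negative_kb_present\t", report$breakdown["negative", "present"]),
      paste0("negative_kb_absent\t", report$breakdown["negative", "absent"])
    )
    writeLines(lines, txt_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_input = report$n_input, n_kept = report$n_kept,
           n_dropped = report$n_dropped, n_unlinked = report$n_unlinked,
           breakdown = list(
             positive = as.list(report$breakdown["positive", ]),
             negative = as.list(report$breakdown["negative", ])
           )),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(report)
}

#' Exclude documents overlapping a held-out PMID set
#'
#' Used to remove documents that also occur in the development set from the
#' weak-labelling pool, keeping the evaluation honest.
#'
#' @param ds A [document_set()].
#' @param holdout_pmids Character vector of PMIDs to exclude.
#' @return List with `docs` (the filtered [document_set()]) and
#'   `n_excluded`.
#' @export
exclude_dev_overlap <- function(ds, holdout_pmids) {
  stopifnot(inherits(ds, "document_set"))
  holdout_pmids <- as.character(holdout_pmids)
  keep <- !(ds$documents$pmid %in% holdout_pmids)
  kept_pmids <- ds$documents$pmid[keep]
  out <- document_set(
    ds$documents[keep, c("pmid", "title", "abstract")],
    ds$mentions[ds$mentions$pmid %in% kept_pmids, ],
    ds$relations[ds$relations$pmid %in% kept_pmids, ]
  )
  list(docs = out, n_excluded = sum(!keep))
}

#' Restrict a corpus to documents cited by the KB
#'
#' The weak-labelling pool is, by default, limited to documents that appear
#' as supporting references in the knowledge base; set `enabled = FALSE` to
#' keep all documents.
#'
#' @param ds A [document_set()].
#' @param index A [build_kb_index()] object.
#' @param enabled Logical flag.
#' @return A filtered [document_set()].
#' @export
restrict_to_kb_docs <- function(ds, index, enabled = TRUE) {
  if (!enabled) return(ds)
  keep <- ds$documents$pmid %in% index$doc_pmids
  kept_pmids <- ds$documents$pmid[keep]
  document_set(
    ds$documents[keep, c("pmid", "title", "abstract")],
    ds$mentions[ds$mentions$pmid %in% kept_pmids, ],
    ds$relations[ds$relations$pmid %in% kept_pmids, ]
  )
}
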