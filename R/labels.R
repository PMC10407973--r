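#' DrugProt relation labels
#'
#' The 13 DrugProt relation types in their canonical order, followed by the
#' sentinel `"NONE"` used for pairs with no asserted relation. The position of
#' a label in this vector is its enum index; all tie-breaking rules in the
#' package ("lower enum index wins") refer to this ordering.
#'
#' @format A character vector of length 14.
#' @export
#' @examples
#' relation_labels()
relation_labels <- function() {
  c(
    "INHIBITOR",
    "DIRECT-REGULATOR",
    "SUBSTRATE",
    "ACTIVATOR",
    "INDIRECT-UPREGULATOR",
    "INDIRECT-DOWNREGULATOR",
    "ANTAGONIST",
    "PRODUCT-OF",
    "PART-OF",
    "AGONIST",
    "AGONIST-ACTIVATOR",
    "SUBSTRATE_PRODUCT-OF",
    "AGONIST-INHIBITOR",
    "NONE"
  )
}

#' The 13 positive DrugProt relation types (without the NONE sentinel)
#' @return Character vector of length 13.
#' @export
positive_labels <- function() {
  setdiff(relation_labels(), "NONE")
}

# Enum index of a label vector; errors on unknown labels.
label_index <- function(x) {
  idx <- match(x, relation_labels())
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown relation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

assert_labels <- function(x, allow_none = TRUE) {
  ok <- relation_labels()
  if (!allow_none) ok <- positive_labels()
  bad <- setdiff(unique(x), ok)
  if (length(bad) > 0) {
    stop("invalid relation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
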