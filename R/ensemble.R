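# Combine prediction sets from several trained models into one.

#' Ensemble configuration
#'
#' @param mode `"soft_vote"` (average per-label score vectors, then argmax)
#'   or `"majority"` (most frequent label). Ties resolve toward the lower
#'   enum index in [relation_labels()].
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(mode = c("soft_vote", "majority")) {
  structure(list(mode = match.arg(mode)), class = "ensemble_config")
}

#' Combine member predictions into a single prediction set
#'
#' All members must cover exactly the same pair keys
#' (`pmid`, `arg1`, `arg2`); the combination is invariant to member order.
#' Soft voting requires `score_*` columns on every member and produces a
#' normalized mean score vector per pair.
#'
#' @param member_predictions List of prediction tibbles
#'   (see [write_predictions()] for the format).
#' @param cfg An [ensemble_config()].
#' @return A prediction tibble over the common pair keys.
#' @export
ensemble_predict <- function(member_predictions, cfg = ensemble_config()) {
  stopifnot(length(member_predictions) >= 1)
  keys <- lapply(member_predictions, function(p)
    sort(pair_key_str(p$pmid, p$arg1, p$arg2)))
  ref <- keys[[1]]
  for (i in seq_along(keys)[-1]) {
    if (!identical(keys[[i]], ref)) {
      missing <- c(setdiff(ref, keys[[i]]), setdiff(keys[[i]], ref))
      stop("member ", i, " pair keys are misaligned; differing keys: ",
           paste(utils::head(gsub("\r", "/", missing), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  # align every member on the sorted key order
  aligned <- lapply(member_predictions, function(p) {
    p[order(pair_key_str(p$pmid, p$arg1, p$arg2)), ]
  })
  base <- aligned[[1]][, c("pmid", "arg1", "arg2")]
  labs <- relation_labels()

  if (cfg$mode == "soft_vote") {
    sc <- score_columns()
    mats <- lapply(aligned, function(p) {
      if (!all(sc %in% names(p))) {
        stop("soft_vote requires per-label score columns on every member",
             call. = FALSE)
      }
      as.matrix(p[, sc])
    })
    mean_scores <- Reduce(`+`, mats) / length(mats)
    mean_scores <- mean_scores / rowSums(mean_scores)
    base$label <- labs[apply(mean_scores, 1, which.max)]
    out <- dplyr::bind_cols(base, tibble::as_tibble(mean_scores))
  } else {
    labmat <- vapply(aligned, function(p) p$label,
                     character(nrow(base)))
    labmat <- matrix(labmat, nrow = nrow(base))
    base$label <- apply(labmat, 1, function(v) {
      counts <- table(factor(v, levels = labs))
      labs[which.max(counts)]  # which.max takes the first (lowest enum) tie
    })
    out <- base
  }
  out
}
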