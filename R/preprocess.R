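# Sentence splitting, entity projection, candidate-pair enumeration and
# entity marking. All offsets are 0-based, end-exclusive, into the document's
# full_text (title + "\t" + abstract).

#' Default marker token set
#'
#' Marker strings used by [mark_entities()]. `chem_start`/`chem_end`/
#' `gene_start`/`gene_end` are the four wrap markers; `chem_mask`/`gene_mask`
#' replace the entity under the MASK method and double as the single wrap
#' token for WRAP_TYPE. Markers are registered with the classifier as atomic
#' vocabulary items.
#'
#' @return Named list of marker strings.
#' @export
marker_tokens <- function() {
  list(chem_start = "CHEM-S", chem_end = "CHEM-E",
       gene_start = "GENE-S", gene_end = "GENE-E",
       chem_mask = "CHEM", gene_mask = "GENE")
}

#' Marking methods
#' @return Character vector of the four supported marking methods:
#'   `NONE` (raw sentence), `MASK` (entities replaced by type tokens),
#'   `WRAP_TYPE` (same type token before and after the entity),
#'   `WRAP_TYPE_SE` (distinct start/end tokens per type).
#' @export
marking_methods <- function() c("NONE", "MASK", "WRAP_TYPE", "WRAP_TYPE_SE")

#' Built-in rule-based sentence splitter
#'
#' Returns sentence boundaries as 0-based, end-exclusive offset pairs over
#' `text`. Boundaries are placed after runs of sentence-final punctuation
#' (`.`, `!`, `?`) followed by whitespace, and at the tab that separates
#' title from abstract. Leading/trailing whitespace is excluded from each
#' window. Any function with this contract (text in, ordered offset matrix
#' out) can be passed wherever a `splitter` is accepted.
#'
#' @param text A single character string.
#' @return Integer matrix with columns `start`, `end`.
#' @export
rule_splitter <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar(text)
  if (n == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  # candidate break points: after [.!?]+ followed by whitespace, and at tabs
  m <- stringr::str_locate_all(text, "[.!?]+(?=\\s)")[[1]]
  breaks <- sort(unique(c(m[, "end"],
                          stringr::str_locate_all(text, "\t")[[1]][, "start"] - 1L,
                          n)))
  starts <- c(0L, breaks[-length(breaks)])
  out <- cbind(start = as.integer(starts), end = as.integer(breaks))
  # trim whitespace off both edges of each window
  trimmed <- lapply(seq_len(nrow(out)), function(i) {
    s <- out[i, 1]; e <- out[i, 2]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    c(s + lead, e - trail)
  })
  out <- do.call(rbind, trimmed)
  out <- out[out[, 1] < out[, 2], , drop = FALSE]
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

#' Split a document into sentence windows
#'
#' @param doc A one-row tibble (or list) with at least `pmid` and
#'   `full_text`, as held in a [document_set()]'s `documents` element.
#' @param splitter A splitter function following the [rule_splitter()]
#'   contract. Its output is validated: windows must be in range, ordered,
#'   and non-overlapping, otherwise a contract-violation error is raised.
#' @return Tibble with columns `pmid`, `sent_index` (0-based), `start`,
#'   `end`, `text`, and an empty `mentions` list column (filled by
#'   [project_entities()]).
#' @export
split_sentences <- function(doc, splitter = rule_splitter) {
  full_text <- doc$full_text[[1]]
  pmid <- doc$pmid[[1]]
  sp <- splitter(full_text)
  sp <- matrix(as.integer(sp), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  if (nrow(sp) > 0) {
    if (any(sp[, 1] < 0L) || any(sp[, 2] > nchar(full_text)) ||
        any(sp[, 1] >= sp[, 2])) {
      stop("splitter contract violation: window out of range or empty",
           call. = FALSE)
    }
    if (is.unsorted(sp[, 1], strictly = TRUE) ||
        any(sp[-1, 1] < sp[-nrow(sp), 2])) {
      stop("splitter contract violation: windows overlap or are unordered",
           call. = FALSE)
    }
  }
  tibble::tibble(
    pmid = rep(pmid, nrow(sp)),
    sent_index = seq_len(nrow(sp)) - 1L,
    start = sp[, 1],
    end = sp[, 2],
    text = substr(rep(full_text, nrow(sp)), sp[, 1] + 1L, sp[, 2]),
    mentions = rep(list(empty_mentions()), nrow(sp))
  )
}

#' Attach entity mentions to sentence windows
#'
#' Each mention fully contained in a window is attached to that window;
#' mentions straddling a window boundary are dropped and counted.
#'
#' @param doc One-row tibble with `pmid`, `full_text`.
#' @param windows Output of [split_sentences()] for the same document.
#' @param mentions Mentions tibble for this document.
#' @return `windows` with the `mentions` list column filled; attribute
#'   `n_dropped` holds the count of boundary-straddling mentions.
#' @export
project_entities <- function(doc, windows, mentions) {
  mentions <- mentions[mentions$pmid == doc$pmid[[1]], ]
  n_dropped <- 0L
  if (nrow(mentions) > 0 && nrow(windows) > 0) {
    # window index whose span contains the mention, NA if none
    widx <- vapply(seq_len(nrow(mentions)), function(i) {
      hit <- which(windows$start <= mentions$start[i] &
                     mentions$end[i] <= windows$end)
      if (length(hit) == 1) hit else NA_integer_
    }, integer(1))
    n_dropped <- sum(is.na(widx))
    for (w in seq_len(nrow(windows))) {
      sel <- which(!is.na(widx) & widx == w)
      m <- mentions[sel, ]
      windows$mentions[[w]] <- m[order(m$start, m$end, m$mention_id), ]
    }
  }
  attr(windows, "n_dropped") <- n_dropped
  windows
}

#' Enumerate within-sentence chemical x gene candidate pairs
#'
#' Produces the full cartesian product of CHEMICAL and GENE mentions
#' attached to a window, ordered by (chemical offset, gene offset).
#'
#' @param window A one-row slice of a projected windows tibble.
#' @return Tibble with one row per candidate pair: `pmid`, `sent_index`,
#'   `arg1`/`arg2` (chemical / gene mention ids), relative spans of both
#'   mentions within the sentence, surfaces, norm ids, and the sentence
#'   `text`.
#' @export
enumerate_pairs <- function(window) {
  m <- window$mentions[[1]]
  chems <- m[m$etype == "CHEMICAL", ]
  genes <- m[m$etype == "GENE", ]
  if (nrow(chems) == 0 || nrow(genes) == 0) return(empty_pairs())
  chems <- chems[order(chems$start, chems$mention_id), ]
  genes <- genes[order(genes$start, genes$mention_id), ]
  grid <- expand.grid(g = seq_len(nrow(genes)), c = seq_len(nrow(chems)))
  grid <- grid[order(grid$c, grid$g), ]
  s0 <- window$start[[1]]
  tibble::tibble(
    pmid = window$pmid[[1]],
    sent_index = window$sent_index[[1]],
    arg1 = chems$mention_id[grid$c],
    arg2 = genes$mention_id[grid$g],
    chem_start = chems$start[grid$c] - s0,
    chem_end = chems$end[grid$c] - s0,
    chem_surface = chems$surface[grid$c],
    chem_id = chems$norm_id[grid$c],
    gene_start = genes$start[grid$g] - s0,
    gene_end = genes$end[grid$g] - s0,
    gene_surface = genes$surface[grid$g],
    gene_id = genes$norm_id[grid$g],
    text = window$text[[1]]
  )
}

empty_pairs <- function() {
  tibble::tibble(
    pmid = character(), sent_index = integer(),
    arg1 = character(), arg2 = character(),
    chem_start = integer(), chem_end = integer(),
    chem_surface = character(), chem_id = character(),
    gene_start = integer(), gene_end = integer(),
    gene_surface = character(), gene_id = character(),
    text = character()
  )
}

#' Render the marked input sequence for one candidate pair
#'
#' Applies one of the four marking methods to the pair's sentence. Only the
#' selected pair's two mentions are touched; any other mentions in the
#' sentence remain raw text. For `WRAP_TYPE_SE` the original sentence is
#' recoverable by deleting the four marker tokens and their padding spaces.
#' Overlapping spans are handled deterministically: markers are inserted at
#' descending positions, and for identical spans the chemical markers end up
#' outside the gene markers.
#'
#' @param pair One-row slice of an [enumerate_pairs()] tibble.
#' @param method One of [marking_methods()].
#' @param tokens Marker token set, see [marker_tokens()].
#' @param max_chars Optional character cap: longer sentences are truncated
#'   symmetrically around the pair span before marking.
#' @return Object of class `marked_sequence`: list with `text`, `method`,
#'   `marker_vocab`, `truncated`.
#' @export
mark_entities <- function(pair, method = "WRAP_TYPE_SE",
                          tokens = marker_tokens(), max_chars = Inf) {
  method <- match.arg(method, marking_methods())
  text <- pair$text[[1]]
  cs <- pair$chem_start[[1]]; ce <- pair$chem_end[[1]]
  gs <- pair$gene_start[[1]]; ge <- pair$gene_end[[1]]
  n <- nchar(text)
  if (cs < 0 || ce > n || gs < 0 || ge > n) {
    stop("pair mentions are not contained in the sentence window",
         call. = FALSE)
  }
  truncated <- FALSE
  if (is.finite(max_chars) && n > max_chars) {
    span_lo <- min(cs, gs); span_hi <- max(ce, ge)
    pad <- max(0L, as.integer(max_chars) - (span_hi - span_lo))
    lo <- max(0L, span_lo - pad %/% 2L)
    hi <- min(n, span_hi + (pad - (span_lo - lo)))
    lo <- max(0L, hi - max(as.integer(max_chars), span_hi - span_lo))
    text <- substr(text, lo + 1L, hi)
    cs <- cs - lo; ce <- ce - lo; gs <- gs - lo; ge <- ge - lo
    truncated <- TRUE
  }

  out <- switch(
    method,
    NONE = text,
    MASK = replace_spans(text,
                         starts = c(cs, gs), ends = c(ce, ge),
                         with = c(tokens$chem_mask, tokens$gene_mask)),
    WRAP_TYPE = wrap_spans(text, cs, ce, gs, ge,
                           tokens$chem_mask, tokens$chem_mask,
                           tokens$gene_mask, tokens$gene_mask),
    WRAP_TYPE_SE = wrap_spans(text, cs, ce, gs, ge,
                              tokens$chem_start, tokens$chem_end,
                              tokens$gene_start, tokens$gene_end)
  )
  vocab <- switch(method,
                  NONE = character(0),
                  MASK = c(tokens$chem_mask, tokens$gene_mask),
                  WRAP_TYPE = c(tokens$chem_mask, tokens$gene_mask),
                  WRAP_TYPE_SE = c(tokens$chem_start, tokens$chem_end,
                                   tokens$gene_start, tokens$gene_end))
  structure(list(text = out, method = method, marker_vocab = vocab,
                 truncated = truncated),
            class = "marked_sequence")
}

#' @export
print.marked_sequence <- function(x, ...) {
  cat("<marked_sequence ", x$method, "> ", x$text, "\n", sep = "")
  invisible(x)
}

# Replace character spans (0-based, end-exclusive) with replacement strings,
# applied at descending start so earlier spans keep their offsets.
replace_spans <- function(text, starts, ends, with) {
  ord <- order(starts, decreasing = TRUE)
  for (i in ord) {
    text <- paste0(substr(text, 1, starts[i]), with[i],
                   substr(text, ends[i] + 1L, nchar(text)))
  }
  text
}

# Insert wrap markers around the chemical span (cs,ce) and gene span (gs,ge).
# Insertions are applied at descending positions; at equal start positions the
# chemical start marker is applied last (lands outside), at equal end
# positions the chemical end marker is applied first (lands outside).
wrap_spans <- function(text, cs, ce, gs, ge, c_s, c_e, g_s, g_e) {
  ins <- data.frame(
    pos = c(cs, ce, gs, ge),
    txt = c(paste0(c_s, " "), paste0(" ", c_e),
            paste0(g_s, " "), paste0(" ", g_e)),
    # order applied within equal pos: larger prio applied later => leftmost
    prio = c(2, 1, 1, 2),
    stringsAsFactors = FALSE
  )
  ord <- order(-ins$pos, ins$prio)
  for (i in ord) {
    text <- paste0(substr(text, 1, ins$pos[i]), ins$txt[i],
                   substr(text, ins$pos[i] + 1L, nchar(text)))
  }
  text
}

#' Preprocess a corpus into marked candidate-pair sequences
#'
#' Runs the full preprocessing chain over a [document_set()]: sentence
#' splitting, entity projection, candidate-pair enumeration, and entity
#' marking, and (when the document set carries gold relations) attaches the
#' gold label of each pair (`NONE` for co-occurring pairs with no gold
#' relation; pairs with several gold types keep the type whose enum index is
#' lowest for training purposes).
#'
#' @param ds A [document_set()].
#' @param method Marking method, see [marking_methods()].
#' @param tokens Marker token set.
#' @param splitter Sentence splitter function.
#' @param max_chars Character cap passed to [mark_entities()].
#' @return Tibble of candidate pairs with a `marked` text column and (if
#'   gold relations exist) a `label` column; attributes `n_dropped_mentions`
#'   and `n_truncated`.
#' @export
preprocess_corpus <- function(ds, method = "WRAP_TYPE_SE",
                              tokens = marker_tokens(),
                              splitter = rule_splitter, max_chars = Inf) {
  stopifnot(inherits(ds, "document_set"))
  n_dropped <- 0L
  n_trunc <- 0L
  res <- vector("list", nrow(ds$documents))
  for (d in seq_len(nrow(ds$documents))) {
    doc <- ds$documents[d, ]
    win <- split_sentences(doc, splitter)
    win <- project_entities(doc, win, ds$mentions)
    n_dropped <- n_dropped + attr(win, "n_dropped")
    pw <- lapply(seq_len(nrow(win)), function(w) enumerate_pairs(win[w, ]))
    res[[d]] <- dplyr::bind_rows(pw)
  }
  pairs <- dplyr::bind_rows(res)
  if (nrow(pairs) == 0) {
    pairs <- empty_pairs()
    pairs$marked <- character(0)
  } else {
    marked <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      ms <- mark_entities(pairs[i, ], method = method, tokens = tokens,
                          max_chars = max_chars)
      marked[i] <- ms$text
      n_trunc <- n_trunc + ms$truncated
    }
    pairs$marked <- marked
  }
  if (nrow(ds$relations) > 0) {
    gold <- ds$relations
    gold$ord <- label_index(gold$rtype)
    gold <- gold[order(gold$ord), ]
    key <- paste(gold$pmid, gold$arg1, gold$arg2, sep = "\r")
    first <- !duplicated(key)
    lab <- stats::setNames(gold$rtype[first], key[first])
    pk <- paste(pairs$pmid, pairs$arg1, pairs$arg2, sep = "\r")
    pairs$label <- unname(lab[pk])
    pairs$label[is.na(pairs$label)] <- "NONE"
  } else if (nrow(pairs) > 0 || TRUE) {
    pairs$label <- rep(NA_character_, nrow(pairs))
  }
  attr(pairs, "n_dropped_mentions") <- n_dropped
  attr(pairs, "n_truncated") <- n_trunc
  pairs
}

#' Exact-match dictionary entity tagger
#'
#' A minimal gazetteer tagger for unlabelled text: finds exact,
#' word-boundary-delimited occurrences of lexicon surface forms in each
#' document's `full_text` and returns them as entity mentions with the
#' lexicon's normalized ids. Intended for corpora without existing entity
#' annotations; it does not attempt abbreviation expansion or fuzzy matches.
#'
#' @param ds A [document_set()] (mentions may be empty).
#' @param lexicon Tibble with columns `surface`, `etype`, `norm_id`.
#' @return A new [document_set()] with the tagged mentions attached.
#' @export
tag_entities_dictionary <- function(ds, lexicon) {
  stopifnot(all(c("surface", "etype", "norm_id") %in% names(lexicon)))
  out <- vector("list", nrow(ds$documents))
  for (d in seq_len(nrow(ds$documents))) {
    doc <- ds$documents[d, ]
    hits <- list()
    for (i in seq_len(nrow(lexicon))) {
      pat <- paste0("(?<![A-Za-z0-9])",
                    stringr::str_replace_all(lexicon$surface[i],
                                             "([\\W])", "\\\\\\1"),
                    "(?![A-Za-z0-9])")
      loc <- stringr::str_locate_all(doc$full_text, pat)[[1]]
      if (nrow(loc) > 0) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          pmid = doc$pmid, etype = lexicon$etype[i],
          start = loc[, 1] - 1L, end = loc[, 2],
          surface = lexicon$surface[i], norm_id = lexicon$norm_id[i]
        )
      }
    }
    h <- dplyr::bind_rows(hits)
    if (nrow(h) > 0) {
      h <- h[order(h$start, h$end, h$etype), ]
      h$mention_id <- paste0("T", seq_len(nrow(h)))
    } else {
      h <- empty_mentions()
    }
    out[[d]] <- h
  }
  document_set(ds$documents, dplyr::bind_rows(out), ds$relations)
}
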