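#' @importFrom rlang .data
NULL

# ---- DocumentSet ------------------------------------------------------------

#' Construct a validated DocumentSet
#'
#' A DocumentSet bundles abstracts, entity mentions, and (optionally) gold
#' relations in the DrugProt layout. The document text used for all character
#' offsets is `full_text`, formed by joining title and abstract with a single
#' tab; offsets are 0-based and end-exclusive.
#'
#' @param documents Tibble with columns `pmid`, `title`, `abstract`.
#' @param mentions Tibble with columns `pmid`, `mention_id`, `etype`
#'   (`"CHEMICAL"` or `"GENE"`), `start`, `end`, `surface`, and optionally
#'   `norm_id` (a normalized knowledge-base identifier).
#' @param relations Tibble with columns `pmid`, `rtype`, `arg1`, `arg2`,
#'   where `arg1`/`arg2` are mention ids of a CHEMICAL and a GENE mention in
#'   the same document. May be `NULL` for unlabelled corpora.
#'
#' @return An object of class `document_set` with elements `documents`
#'   (including the derived `full_text` column), `mentions`, `relations`.
#' @export
document_set <- function(documents, mentions = NULL, relations = NULL) {
  documents <- tibble::as_tibble(documents)
  stopifnot(all(c("pmid", "title", "abstract") %in% names(documents)))
  documents$pmid <- as.character(documents$pmid)
  if (any(!nzchar(documents$pmid))) {
    stop("empty pmid in documents", call. = FALSE)
  }
  if (anyDuplicated(documents$pmid)) {
    stop("duplicate pmid in documents: ",
         paste(unique(documents$pmid[duplicated(documents$pmid)]),
               collapse = ", "), call. = FALSE)
  }
  if (!"full_text" %in% names(documents)) {
    documents$full_text <- paste(documents$title, documents$abstract,
                                 sep = "\t")
  }
  documents <- dplyr::arrange(documents, .data$pmid)

  if (is.null(mentions)) {
    mentions <- empty_mentions()
  }
  mentions <- tibble::as_tibble(mentions)
  if (!"norm_id" %in% names(mentions)) mentions$norm_id <- NA_character_
  mentions <- mentions[, c("pmid", "mention_id", "etype", "start", "end",
                           "surface", "norm_id")]
  mentions$pmid <- as.character(mentions$pmid)
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  validate_mentions(documents, mentions)
  mentions <- dplyr::arrange(mentions, .data$pmid, .data$start, .data$end,
                             .data$mention_id)

  if (is.null(relations)) {
    relations <- empty_relations()
  }
  relations <- tibble::as_tibble(relations)
  relations <- relations[, c("pmid", "rtype", "arg1", "arg2")]
  relations$pmid <- as.character(relations$pmid)
  validate_relations(documents, mentions, relations)
  relations <- dplyr::arrange(relations, .data$pmid, .data$arg1, .data$arg2,
                              .data$rtype)

  structure(
    list(documents = documents, mentions = mentions, relations = relations),
    class = "document_set"
  )
}

empty_mentions <- function() {
  tibble::tibble(pmid = character(), mention_id = character(),
                 etype = character(), start = integer(), end = integer(),
                 surface = character(), norm_id = character())
}

empty_relations <- function() {
  tibble::tibble(pmid = character(), rtype = character(),
                 arg1 = character(), arg2 = character())
}

validate_mentions <- function(documents, mentions) {
  if (nrow(mentions) == 0) return(invisible(TRUE))
  bad_type <- setdiff(unique(mentions$etype), c("CHEMICAL", "GENE"))
  if (length(bad_type) > 0) {
    stop("unknown entity type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  ft <- documents$full_text[match(mentions$pmid, documents$pmid)]
  missing <- is.na(ft)
  if (any(missing)) {
    stop("entity row references unknown pmid: ",
         paste(unique(mentions$pmid[missing]), collapse = ", "),
         call. = FALSE)
  }
  n <- nchar(ft)
  bad_span <- mentions$start < 0L | mentions$end <= mentions$start |
    mentions$end > n
  if (any(bad_span)) {
    stop("mention span out of range for mention_id ",
         paste(mentions$mention_id[bad_span], collapse = ", "),
         call. = FALSE)
  }
  sliced <- substr(ft, mentions$start + 1L, mentions$end)
  mismatch <- sliced != mentions$surface
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop("surface/offset mismatch for mention_id ",
         mentions$mention_id[i], " in pmid ", mentions$pmid[i],
         ": expected ", encodeString(mentions$surface[i], quote = '"'),
         ", sliced ", encodeString(sliced[i], quote = '"'),
         call. = FALSE)
  }
  dup <- duplicated(mentions[, c("pmid", "mention_id")])
  if (any(dup)) {
    stop("duplicate mention_id within document: ",
         paste(unique(mentions$mention_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_relations <- function(documents, mentions, relations) {
  if (nrow(relations) == 0) return(invisible(TRUE))
  assert_labels(relations$rtype, allow_none = FALSE)
  mkey <- paste(mentions$pmid, mentions$mention_id, sep = "\r")
  etype_of <- stats::setNames(mentions$etype, mkey)
  a1 <- etype_of[paste(relations$pmid, relations$arg1, sep = "\r")]
  a2 <- etype_of[paste(relations$pmid, relations$arg2, sep = "\r")]
  bad <- is.na(a1) | is.na(a2) | a1 != "CHEMICAL" | a2 != "GENE"
  if (any(bad)) {
    i <- which(bad)[1]
    stop("relation row ", i, " (pmid ", relations$pmid[i],
         ") does not resolve to a CHEMICAL arg1 and GENE arg2 mention",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.document_set <- function(x, ...) {
  cat("<document_set>", nrow(x$documents), "documents,",
      nrow(x$mentions), "mentions,", nrow(x$relations), "gold relations\n")
  invisible(x)
}

#' @export
format.document_set <- function(x, ...) {
  sprintf("<document_set: %d docs, %d mentions, %d relations>",
          nrow(x$documents), nrow(x$mentions), nrow(x$relations))
}

# ---- DrugProt corpus reading/writing ---------------------------------------

read_tsv_strict <- function(path, col_names) {
  readr::read_tsv(path, col_names = col_names, quote = "", na = character(),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a DrugProt-style corpus
#'
#' Reads the standard three-file DrugProt distribution layout: an abstracts
#' file (`pmid`, `title`, `abstract`), an entities file (`pmid`, `mention_id`,
#' `etype`, `start`, `end`, `surface`, optional `norm_id`), and optionally a
#' relations file (`pmid`, `rtype`, `Arg1:<id>`, `Arg2:<id>`). All files are
#' headerless tab-separated UTF-8 text. Entity offsets index into
#' `full_text = title + "\t" + abstract`, 0-based and end-exclusive, and are
#' validated against the entity surface string on load.
#'
#' @param abstracts_path,entities_path,relations_path File paths;
#'   `relations_path` may be `NULL` for unlabelled corpora.
#' @return A [document_set()].
#' @export
read_drugprot <- function(abstracts_path, entities_path,
                          relations_path = NULL) {
  docs <- if (file.size(abstracts_path) == 0) {
    tibble::tibble(pmid = character(), title = character(),
                   abstract = character())
  } else {
    read_tsv_strict(abstracts_path, c("pmid", "title", "abstract"))
  }
  ents <- if (file.size(entities_path) == 0) tibble::tibble() else
    read_tsv_strict(entities_path, FALSE)
  if (nrow(ents) == 0) {
    ents <- empty_mentions()
  } else {
    if (ncol(ents) < 6) {
      stop("entities file must have at least 6 tab-separated columns",
           call. = FALSE)
    }
    names(ents)[1:6] <- c("pmid", "mention_id", "etype", "start", "end",
                          "surface")
    if (ncol(ents) >= 7) {
      names(ents)[7] <- "norm_id"
      ents$norm_id[!nzchar(ents$norm_id) | ents$norm_id == "-"] <-
        NA_character_
    } else {
      ents$norm_id <- NA_character_
    }
  }
  unknown <- setdiff(unique(ents$pmid), docs$pmid)
  if (length(unknown) > 0) {
    i <- which(ents$pmid %in% unknown)[1]
    stop("entities row ", i, " references pmid ", ents$pmid[i],
         " absent from the abstracts file", call. = FALSE)
  }

  rels <- NULL
  if (!is.null(relations_path)) {
    rels <- if (file.size(relations_path) == 0) tibble::tibble() else
      read_tsv_strict(relations_path, FALSE)
    if (nrow(rels) > 0) {
      if (ncol(rels) < 4) {
        stop("relations file must have 4 tab-separated columns",
             call. = FALSE)
      }
      names(rels)[1:4] <- c("pmid", "rtype", "arg1", "arg2")
      rels$arg1 <- sub("^Arg1:", "", rels$arg1)
      rels$arg2 <- sub("^Arg2:", "", rels$arg2)
      unknown <- setdiff(unique(rels$pmid), docs$pmid)
      if (length(unknown) > 0) {
        i <- which(rels$pmid %in% unknown)[1]
        stop("relations row ", i, " references pmid ", rels$pmid[i],
             " absent from the abstracts file", call. = FALSE)
      }
      rels <- rels[, c("pmid", "rtype", "arg1", "arg2")]
    } else {
      rels <- empty_relations()
    }
  }
  document_set(docs, ents, rels)
}

#' Write a DocumentSet in the DrugProt three-file layout
#'
#' @param ds A [document_set()].
#' @param abstracts_path,entities_path,relations_path Output paths;
#'   `relations_path` may be `NULL` to skip writing relations.
#' @return `ds`, invisibly.
#' @export
write_drugprot <- function(ds, abstracts_path, entities_path,
                           relations_path = NULL) {
  stopifnot(inherits(ds, "document_set"))
  readr::write_tsv(ds$documents[, c("pmid", "title", "abstract")],
                   abstracts_path, col_names = FALSE, escape = "none",
                   quote = "none")
  ents <- ds$mentions
  ents$norm_id <- ifelse(is.na(ents$norm_id), "-", ents$norm_id)
  readr::write_tsv(ents, entities_path, col_names = FALSE, escape = "none",
                   quote = "none")
  if (!is.null(relations_path)) {
    rels <- ds$relations
    rels$arg1 <- paste0("Arg1:", rels$arg1)
    rels$arg2 <- paste0("Arg2:", rels$arg2)
    readr::write_tsv(rels, relations_path, col_names = FALSE,
                     escape = "none", quote = "none")
  }
  invisible(ds)
}

# ---- Knowledge-base table ---------------------------------------------------

#' Column map for CTD-style chemical-gene interaction tables
#'
#' Defaults follow the public CTD chem-gene export. Only the chemical id,
#' gene id and PMIDs columns are required in the file; name and action
#' columns are carried when present (the action text is never interpreted).
#'
#' @param chem_id,gene_id,pmids,chem_name,gene_name,action Column names in
#'   the input file.
#' @param pmid_sep Delimiter separating multiple PMIDs inside one cell.
#' @return A named list used by [read_kb()].
#' @export
kb_col_map <- function(chem_id = "ChemicalID", gene_id = "GeneID",
                       pmids = "PubMedIDs", chem_name = "ChemicalName",
                       gene_name = "GeneSymbol",
                       action = "InteractionActions", pmid_sep = "|") {
  list(chem_id = chem_id, gene_id = gene_id, pmids = pmids,
       chem_name = chem_name, gene_name = gene_name, action = action,
       pmid_sep = pmid_sep)
}

#' Read a CTD-style chemical-gene interaction table
#'
#' Reads a tab-separated table with a header row. One record is returned per
#' input row (rows sharing a chemical-gene pair are *not* merged here;
#' de-duplication happens in [build_kb_index()]). Rows with an empty chemical
#' or gene id are skipped; the number skipped is reported in the
#' `n_skipped` attribute and as a message.
#'
#' @param path Path to the table.
#' @param col_map Column mapping from [kb_col_map()].
#' @return A tibble of class `kb_records` with columns `chem_id`, `gene_id`,
#'   `pmids` (list column of character vectors), `chem_name`, `gene_name`,
#'   `action`; attribute `n_skipped`.
#' @export
read_kb <- function(path, col_map = kb_col_map()) {
  tab <- readr::read_tsv(path, quote = "", na = character(),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c(col_map$chem_id, col_map$gene_id, col_map$pmids)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("KB table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    chem_id = tab[[col_map$chem_id]],
    gene_id = tab[[col_map$gene_id]],
    pmids = stringr::str_split(tab[[col_map$pmids]],
                               stringr::fixed(col_map$pmid_sep)),
    chem_name = pick_col(tab, col_map$chem_name),
    gene_name = pick_col(tab, col_map$gene_name),
    action = pick_col(tab, col_map$action)
  )
  out$pmids <- purrr::map(out$pmids, function(p) p[nzchar(p)])
  keep <- nzchar(out$chem_id) & nzchar(out$gene_id)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_kb: skipped ", n_skipped,
            " row(s) with empty chemical or gene id")
  }
  out <- out[keep, ]
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("kb_records", class(out))
  out
}

pick_col <- function(tab, name) {
  if (!is.null(name) && name %in% names(tab)) tab[[name]] else
    rep(NA_character_, nrow(tab))
}

# ---- Predictions format -----------------------------------------------------

SCORE_PREFIX <- "score_"

#' Score column names for the full label set
#'
#' @return Character vector, one `score_<LABEL>` name per relation label.
#' @export
score_columns <- function() {
  paste0(SCORE_PREFIX, gsub("[^A-Za-z0-9]", ".", relation_labels()))
}

#' Write / read relation predictions
#'
#' Predictions are stored as tab-separated text with a header. Required
#' columns: `pmid`, `arg1`, `arg2`, `label`. Optional columns are preserved
#' on a round trip: per-label scores (`score_*`), normalized entity ids
#' (`chem_id`, `gene_id`), and provenance columns. Scores are written with
#' full precision (`read(write(p))` reproduces them to 1e-12).
#'
#' @param predictions Tibble with the columns above.
#' @param path Output path.
#' @return `write_predictions()` returns `predictions` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("pmid", "arg1", "arg2", "label") %in% names(predictions)))
  assert_labels(predictions$label)
  readr::write_tsv(predictions, path, col_names = TRUE, escape = "none",
                   quote = "none")
  invisible(predictions)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tab <- readr::read_tsv(path, quote = "", na = "NA",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("pmid", "arg1", "arg2", "label")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("predictions file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), relation_labels())
  if (length(bad) > 0) {
    stop("predictions file contains unknown label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  num_cols <- grep(paste0("^", SCORE_PREFIX), names(tab), value = TRUE)
  for (cc in num_cols) tab[[cc]] <- as.numeric(tab[[cc]])
  if ("kb_present" %in% names(tab)) {
    tab$kb_present <- as.logical(tab$kb_present)
  }
  tab
}
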