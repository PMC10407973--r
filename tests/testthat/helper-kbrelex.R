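# Shared fixtures and independent oracles for the test suite. All corpus
# fixtures are built in code; nothing is read from outside the package.

# A two-document toy corpus written in the DrugProt three-file layout.
# Returns the three file paths. Document 1 holds two sentences with one
# chemical and two genes; document 2 holds one chemical, plus gold
# relations covering both documents.
write_toy_corpus <- function(dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  abstracts <- file.path(dir, "abstracts.tsv")
  entities <- file.path(dir, "entities.tsv")
  relations <- file.path(dir, "relations.tsv")
  # full_text = title \t abstract; offsets are 0-based end-exclusive
  writeLines(c(
    "1001\tAspirin study.\tAspirin inhibited COX1. It also bound COX2.",
    "1002\tIbuprofen note.\tIbuprofen was tested."
  ), abstracts)
  # pmid  id  type  start  end  surface
  writeLines(c(
    "1001\tT1\tCHEMICAL\t15\t22\tAspirin",
    "1001\tT2\tGENE\t33\t37\tCOX1",
    "1001\tT3\tGENE\t53\t57\tCOX2",
    "1002\tT1\tCHEMICAL\t16\t25\tIbuprofen",
    "1001\tT4\tCHEMICAL\t0\t7\tAspirin"
  ), entities)
  writeLines(c(
    "1001\tINHIBITOR\tArg1:T1\tArg2:T2",
    "1001\tDIRECT-REGULATOR\tArg1:T1\tArg2:T3"
  ), relations)
  list(abstracts = abstracts, entities = entities, relations = relations)
}

# One-sentence document holding the classic worked marking example.
marking_example_doc <- function() {
  sent <- "Alendronate was a slow-binding inhibitor of PTPmeg1."
  docs <- tibble::tibble(pmid = "42", title = "Note.", abstract = sent)
  # full_text = "Note.\t" + sent ; abstract starts at offset 6
  off <- nchar("Note.") + 1L
  mentions <- tibble::tibble(
    pmid = "42",
    mention_id = c("T1", "T2"),
    etype = c("CHEMICAL", "GENE"),
    start = off + c(0L, 44L),
    end = off + c(11L, 51L),
    surface = c("Alendronate", "PTPmeg1"),
    norm_id = c(NA_character_, NA_character_)
  )
  document_set(docs, mentions)
}

# Brute-force KB-agreement oracle: re-evaluates the keep rule row by row.
oracle_refine_keep <- function(predictions, kb_pairs) {
  keep <- logical(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    chem <- predictions$chem_id[i]
    gene <- predictions$gene_id[i]
    present <- !is.na(chem) && !is.na(gene) && nzchar(chem) &&
      nzchar(gene) &&
      paste(tolower(chem), tolower(gene)) %in% kb_pairs
    keep[i] <- if (predictions$label[i] != "NONE") present else !present
  }
  keep
}

# Brute-force set-intersection scorer for micro precision/recall/F1.
oracle_micro <- function(gold, predictions) {
  g <- unique(paste(gold$pmid, gold$arg1, gold$arg2, gold$rtype))
  pos <- predictions[predictions$label != "NONE", ]
  p <- unique(paste(pos$pmid, pos$arg1, pos$arg2, pos$label))
  tp <- length(intersect(g, p))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}

# The pair-key string used to align prediction sets in tests (mirrors the
# package's internal alignment key).
pkey <- function(p) paste(p$pmid, p$arg1, p$arg2, sep = "\r")

# Random scored prediction tibble over given pair keys (used by ensemble
# and evaluation tests).
random_predictions <- function(n, seed, pmids = 3, args = 4) {
  set.seed(seed)
  labs <- relation_labels()
  base <- unique(tibble::tibble(
    pmid = as.character(sample.int(pmids, n, replace = TRUE)),
    arg1 = paste0("C", sample.int(args, n, replace = TRUE)),
    arg2 = paste0("G", sample.int(args, n, replace = TRUE))
  ))
  scores <- matrix(stats::runif(nrow(base) * length(labs)),
                   nrow = nrow(base))
  scores <- scores / rowSums(scores)
  colnames(scores) <- score_columns()
  base$label <- labs[apply(scores, 1, which.max)]
  dplyr::bind_cols(base, tibble::as_tibble(scores))
}
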