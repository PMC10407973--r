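# Seeded synthetic corpus generator: templated relation-bearing sentences
# with exact character offsets, a label distribution mirroring the DrugProt
# training split, and a chemical-gene KB with controllable coverage of the
# planted relations. Every bundle passes formats_io validation, so the whole
# pipeline is testable without downloading any corpus.

#' Configuration for the synthetic fixture generator
#'
#' @param n_docs Number of documents to generate.
#' @param sentences_per_doc Integer range `c(min, max)` of sentences per
#'   abstract.
#' @param n_chems,n_genes Lexicon sizes (surface forms with normalized ids).
#' @param label_distribution Named probability vector over the 13 positive
#'   relation types; defaults to the DrugProt training-split distribution
#'   ([drugprot_label_distribution()]), including the three rare types.
#' @param p_negative_cooccurrence Probability that a sentence holds a
#'   co-occurring chemical-gene pair with no relation.
#' @param kb_coverage Probability that a distinct planted positive pair is
#'   inserted into the KB (each pair independently).
#' @param kb_noise Number of KB pairs never expressed in the text.
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   full configuration.
#' @param lexicon_seed Seed for lexicon generation; defaults to `seed`.
#'   Giving several bundles the same `lexicon_seed` (and lexicon sizes)
#'   makes them share surface forms and norm ids, the way real corpus
#'   splits share a vocabulary of chemicals and genes.
#' @param pmid_start First PMID; bundles meant to coexist (train / weak
#'   pool / dev) should use disjoint PMID ranges.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_docs = 100, sentences_per_doc = c(3, 6),
                           n_chems = 40, n_genes = 40,
                           label_distribution = drugprot_label_distribution("train"),
                           p_negative_cooccurrence = 0.3,
                           kb_coverage = 0.9, kb_noise = 50, seed = 1,
                           lexicon_seed = NULL, pmid_start = 9000001) {
  stopifnot(n_docs >= 0, length(sentences_per_doc) == 2,
            sentences_per_doc[1] >= 1,
            sentences_per_doc[2] >= sentences_per_doc[1],
            n_chems >= 1, n_genes >= 1,
            kb_coverage >= 0, kb_coverage <= 1, kb_noise >= 0,
            p_negative_cooccurrence >= 0, p_negative_cooccurrence <= 1)
  if (abs(sum(label_distribution) - 1) > 1e-8) {
    stop("label_distribution must sum to 1", call. = FALSE)
  }
  assert_labels(names(label_distribution), allow_none = FALSE)
  structure(
    list(n_docs = as.integer(n_docs),
         sentences_per_doc = as.integer(sentences_per_doc),
         n_chems = as.integer(n_chems), n_genes = as.integer(n_genes),
         label_distribution = label_distribution,
         p_negative_cooccurrence = p_negative_cooccurrence,
         kb_coverage = kb_coverage, kb_noise = as.integer(kb_noise),
         seed = as.integer(seed),
         lexicon_seed = as.integer(if (is.null(lexicon_seed)) seed else
           lexicon_seed),
         pmid_start = as.integer(pmid_start)),
    class = "fixture_config"
  )
}

# Per-type trigger templates. Each type has its own unambiguous trigger
# vocabulary so that a desk-scale classifier can learn the mapping; the only
# deliberate ambiguity in a bundle comes from negative co-occurrence
# sentences. {C} marks the chemical surface, {G} the gene surface.
relation_templates <- function() {
  list(
    "INHIBITOR" = c(
      "{C} was a slow-binding inhibitor of {G}.",
      "{C} potently inhibited {G} activity in vitro.",
      "Kinetic assays showed that {C} inhibits {G}."),
    "DIRECT-REGULATOR" = c(
      "{C} bound directly to {G} and regulated its function.",
      "{C} acted as a direct regulator of {G}.",
      "Binding studies confirmed that {C} directly regulates {G}."),
    "SUBSTRATE" = c(
      "{C} was an efficient substrate of {G}.",
      "{G} rapidly metabolized {C} in liver microsomes.",
      "{C} served as a substrate for {G}."),
    "ACTIVATOR" = c(
      "{C} strongly activated {G}.",
      "{C} was a potent activator of {G} signalling.",
      "Enzyme assays showed that {C} activates {G}."),
    "INDIRECT-UPREGULATOR" = c(
      "{C} treatment indirectly upregulated {G} expression.",
      "Exposure to {C} increased transcription of {G} via an indirect route.",
      "{C} raised {G} mRNA levels without direct binding."),
    "INDIRECT-DOWNREGULATOR" = c(
      "{C} treatment indirectly downregulated {G} expression.",
      "Exposure to {C} suppressed transcription of {G} via an indirect route.",
      "{C} lowered {G} mRNA levels without direct binding."),
    "ANTAGONIST" = c(
      "{C} was a selective antagonist of {G}.",
      "{C} antagonized {G} in receptor assays.",
      "Radioligand studies identified {C} as a {G} antagonist."),
    "PRODUCT-OF" = c(
      "{C} was generated as a product of {G}.",
      "{C} accumulated as the main product of {G} catalysis.",
      "Mass spectrometry identified {C} as a product of {G}."),
    "PART-OF" = c(
      "{C} was a structural part of the {G} complex.",
      "{C} is an integral component of {G}.",
      "Crystallography placed {C} as part of {G}."),
    "AGONIST" = c(
      "{C} was a full agonist of {G}.",
      "{C} behaved as an agonist at {G} receptors.",
      "Dose-response curves characterized {C} as a {G} agonist."),
    "AGONIST-ACTIVATOR" = c(
      "{C} acted as an agonist-activator of {G}.",
      "{C} engaged {G} as an agonistic activator."),
    "SUBSTRATE_PRODUCT-OF" = c(
      "{C} was both a substrate and a product of {G}.",
      "{C} cycled as substrate and product of {G}."),
    "AGONIST-INHIBITOR" = c(
      "{C} acted as an agonist-inhibitor of {G}.",
      "{C} engaged {G} as an agonistic inhibitor.")
  )
}

negative_templates <- function() {
  c("{C} and {G} were both detected in plasma samples.",
    "Levels of {C} did not correlate with {G} abundance.",
    "{C} was administered while {G} expression was monitored.",
    "The cohort study measured {C} alongside {G}.")
}

# Instantiate a template; returns sentence text and 0-based relative spans.
instantiate_template <- function(tpl, chem, gene) {
  pc <- as.integer(regexpr("{C}", tpl, fixed = TRUE))
  pg <- as.integer(regexpr("{G}", tpl, fixed = TRUE))
  stopifnot(pc > 0, pg > 0)
  text <- sub("{C}", chem, tpl, fixed = TRUE)
  text <- sub("{G}", gene, text, fixed = TRUE)
  if (pc < pg) {
    cs <- pc - 1L
    gs <- pg - 1L + nchar(chem) - 3L
  } else {
    gs <- pg - 1L
    cs <- pc - 1L + nchar(gene) - 3L
  }
  list(text = text,
       chem = c(start = cs, end = cs + nchar(chem)),
       gene = c(start = gs, end = gs + nchar(gene)))
}

# Deterministic lexicons (consume RNG state).
make_chem_lexicon <- function(n) {
  syl <- c("al", "ben", "cor", "dex", "eri", "flu", "gal", "hex", "ima",
           "jat", "kel", "lor", "mav", "nex", "oxa", "pra", "quin", "ril",
           "sor", "tal", "ume", "vor", "xan", "zol")
  suf <- c("ib", "ol", "ine", "ate", "mab", "one")
  surfaces <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- paste0(paste(sample(syl, 2), collapse = ""), sample(suf, 1))
      if (!(s %in% seen)) break
    }
    seen <- c(seen, s)
    surfaces[i] <- s
  }
  tibble::tibble(surface = surfaces, etype = "CHEMICAL",
                 norm_id = sprintf("MESH:C%05d", seq_len(n)))
}

make_gene_lexicon <- function(n) {
  surfaces <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- paste0(paste(sample(LETTERS, 3), collapse = ""),
                  sample(1:9, 1))
      if (!(s %in% seen)) break
    }
    seen <- c(seen, s)
    surfaces[i] <- s
  }
  tibble::tibble(surface = surfaces, etype = "GENE",
                 norm_id = sprintf("GENE:%05d", seq_len(n)))
}

#' Generate a synthetic fixture bundle
#'
#' Produces documents, entity annotations, gold relations, a KB table and a
#' ground-truth manifest, all mutually consistent and deterministic given
#' the configuration (identical config twice yields a byte-identical
#' bundle). Positive sentences are built from per-type trigger templates;
#' negative sentences use neutral co-occurrence phrasings and are planted
#' with probability `p_negative_cooccurrence`. Each distinct planted
#' positive (chemical id, gene id) pair enters the KB independently with
#' probability `kb_coverage`; `kb_noise` additional pairs never expressed
#' in the text are added with out-of-corpus supporting PMIDs.
#'
#' @param config A [fixture_config()].
#' @return Object of class `fixture_bundle` with elements `docs` (a
#'   [document_set()]), `kb` (KB records tibble in the [read_kb()] shape),
#'   `manifest` (planted pairs with labels and sentence indices), `lexicon`
#'   (chemical and gene surface forms with norm ids), and `config`.
#' @export
generate_fixtures <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  restore_lex <- local_seed(config$lexicon_seed)
  chems <- make_chem_lexicon(config$n_chems)
  genes <- make_gene_lexicon(config$n_genes)
  restore_lex()
  restore <- local_seed(config$seed)
  on.exit(restore())
  templates <- relation_templates()
  neg_tpl <- negative_templates()
  types <- names(config$label_distribution)

  docs <- vector("list", config$n_docs)
  ments <- vector("list", config$n_docs)
  rels <- vector("list", config$n_docs)
  manifest <- vector("list", config$n_docs)

  for (d in seq_len(config$n_docs)) {
    pmid <- as.character(config$pmid_start + d - 1L)
    title <- sprintf("Chemical and protein assay observations, record %d.", d)
    ns <- sample(seq(config$sentences_per_doc[1],
                     config$sentences_per_doc[2]), 1)
    sent_text <- character(ns)
    doc_m <- vector("list", ns)
    doc_r <- vector("list", ns)
    doc_man <- vector("list", ns)
    # sentence offsets into full_text = title \t abstract, sentences
    # joined by single spaces
    offset <- nchar(title) + 1L
    tcount <- 0L
    for (s in seq_len(ns)) {
      ci <- sample.int(nrow(chems), 1)
      gi <- sample.int(nrow(genes), 1)
      negative <- stats::runif(1) < config$p_negative_cooccurrence
      if (negative) {
        label <- "NONE"
        tpl <- neg_tpl[sample.int(length(neg_tpl), 1)]
      } else {
        label <- sample(types, 1, prob = config$label_distribution)
        tv <- templates[[label]]
        tpl <- tv[sample.int(length(tv), 1)]
      }
      inst <- instantiate_template(tpl, chems$surface[ci], genes$surface[gi])
      sent_text[s] <- inst$text
      id_c <- paste0("T", tcount + 1L)
      id_g <- paste0("T", tcount + 2L)
      tcount <- tcount + 2L
      doc_m[[s]] <- tibble::tibble(
        pmid = pmid,
        mention_id = c(id_c, id_g),
        etype = c("CHEMICAL", "GENE"),
        start = offset + c(inst$chem["start"], inst$gene["start"]),
        end = offset + c(inst$chem["end"], inst$gene["end"]),
        surface = c(chems$surface[ci], genes$surface[gi]),
        norm_id = c(chems$norm_id[ci], genes$norm_id[gi])
      )
      if (label != "NONE") {
        doc_r[[s]] <- tibble::tibble(pmid = pmid, rtype = label,
                                     arg1 = id_c, arg2 = id_g)
      }
      doc_man[[s]] <- tibble::tibble(
        pmid = pmid, sent_index = s, arg1 = id_c, arg2 = id_g,
        chem_id = chems$norm_id[ci], gene_id = genes$norm_id[gi],
        label = label
      )
      offset <- offset + nchar(inst$text) + 1L
    }
    docs[[d]] <- tibble::tibble(pmid = pmid, title = title,
                                abstract = paste(sent_text, collapse = " "))
    ments[[d]] <- dplyr::bind_rows(doc_m)
    rels[[d]] <- dplyr::bind_rows(doc_r)
    manifest[[d]] <- dplyr::bind_rows(doc_man)
  }

  documents <- if (config$n_docs > 0) dplyr::bind_rows(docs) else
    tibble::tibble(pmid = character(), title = character(),
                   abstract = character())
  manifest <- if (config$n_docs > 0) dplyr::bind_rows(manifest) else
    tibble::tibble(pmid = character(), sent_index = integer(),
                   arg1 = character(), arg2 = character(),
                   chem_id = character(), gene_id = character(),
                   label = character())

  ds <- document_set(documents,
                     if (config$n_docs > 0) dplyr::bind_rows(ments) else NULL,
                     if (config$n_docs > 0) dplyr::bind_rows(rels) else NULL)

  kb <- build_fixture_kb(manifest, chems, genes, config)

  structure(
    list(docs = ds, kb = kb, manifest = manifest,
         lexicon = dplyr::bind_rows(chems, genes), config = config),
    class = "fixture_bundle"
  )
}

build_fixture_kb <- function(manifest, chems, genes, config) {
  pos <- manifest[manifest$label != "NONE", ]
  planted <- unique(pos[, c("chem_id", "gene_id")])
  covered <- planted
  if (nrow(planted) > 0) {
    covered <- planted[stats::runif(nrow(planted)) < config$kb_coverage, ]
  }
  kb_rows <- list()
  if (nrow(covered) > 0) {
    key <- paste(pos$chem_id, pos$gene_id, sep = "\x1f")
    ckey <- paste(covered$chem_id, covered$gene_id, sep = "\x1f")
    support <- lapply(ckey, function(k) sort(unique(pos$pmid[key == k])))
    kb_rows[[1]] <- tibble::tibble(
      chem_id = covered$chem_id, gene_id = covered$gene_id,
      pmids = support,
      chem_name = chems$surface[match(covered$chem_id, chems$norm_id)],
      gene_name = genes$surface[match(covered$gene_id, genes$norm_id)],
      action = "interacts^curated"
    )
  }
  if (config$kb_noise > 0) {
    all_pairs <- expand.grid(ci = seq_len(nrow(chems)),
                             gi = seq_len(nrow(genes)))
    pkey <- paste(chems$norm_id[all_pairs$ci], genes$norm_id[all_pairs$gi],
                  sep = "\x1f")
    planted_key <- paste(planted$chem_id, planted$gene_id, sep = "\x1f")
    avail <- which(!(pkey %in% planted_key))
    if (length(avail) < config$kb_noise) {
      stop("lexicon too small for requested number of distinct KB noise ",
           "pairs (", config$kb_noise, " requested, ", length(avail),
           " available)", call. = FALSE)
    }
    pick <- sort(sample(avail, config$kb_noise))
    kb_rows[[length(kb_rows) + 1]] <- tibble::tibble(
      chem_id = chems$norm_id[all_pairs$ci[pick]],
      gene_id = genes$norm_id[all_pairs$gi[pick]],
      pmids = lapply(seq_along(pick), function(i)
        as.character(8800000L + i)),
      chem_name = chems$surface[all_pairs$ci[pick]],
      gene_name = genes$surface[all_pairs$gi[pick]],
      action = "interacts^noise"
    )
  }
  kb <- if (length(kb_rows) > 0) dplyr::bind_rows(kb_rows) else
    tibble::tibble(chem_id = character(), gene_id = character(),
                   pmids = list(), chem_name = character(),
                   gene_name = character(), action = character())
  class(kb) <- c("kb_records", class(kb))
  kb
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>", nrow(x$docs$documents), "documents,",
      nrow(x$manifest), "planted pairs (",
      sum(x$manifest$label != "NONE"), "positive ),",
      nrow(x$kb), "KB rows\n")
  invisible(x)
}

#' Ground-truth gold tuples of a generated bundle
#'
#' Returns the exact planted relation tuples, the oracle against which
#' pipeline evaluation is checked. Pairs planted as negative co-occurrence
#' are not included.
#'
#' @param bundle A [generate_fixtures()] bundle.
#' @return Tibble with columns `pmid`, `rtype`, `arg1`, `arg2`.
#' @export
planted_truth <- function(bundle) {
  if (!inherits(bundle, "fixture_bundle")) {
    stop("planted_truth() requires a bundle generated by this package",
         call. = FALSE)
  }
  pos <- bundle$manifest[bundle$manifest$label != "NONE", ]
  tibble::tibble(pmid = pos$pmid, rtype = pos$label,
                 arg1 = pos$arg1, arg2 = pos$arg2)
}

#' Write a fixture bundle to disk in the corpus dialects
#'
#' Writes `abstracts.tsv`, `entities.tsv`, `relations.tsv` (DrugProt
#' layout), `kb.tsv` (CTD-style header-driven table) and `manifest.tsv`
#' under `dir`.
#'
#' @param bundle A [generate_fixtures()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    abstracts = file.path(dir, "abstracts.tsv"),
    entities = file.path(dir, "entities.tsv"),
    relations = file.path(dir, "relations.tsv"),
    kb = file.path(dir, "kb.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_drugprot(bundle$docs, paths$abstracts, paths$entities,
                 paths$relations)
  cm <- kb_col_map()
  kb_out <- tibble::tibble(
    ChemicalName = bundle$kb$chem_name,
    ChemicalID = bundle$kb$chem_id,
    GeneSymbol = bundle$kb$gene_name,
    GeneID = bundle$kb$gene_id,
    InteractionActions = bundle$kb$action,
    PubMedIDs = vapply(bundle$kb$pmids, paste, character(1),
                       collapse = cm$pmid_sep)
  )
  readr::write_tsv(kb_out, paths$kb, escape = "none", quote = "none")
  readr::write_tsv(bundle$manifest, paths$manifest, escape = "none",
                   quote = "none")
  invisible(paths)
}
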