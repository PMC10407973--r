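mk_records <- function(chem, gene, pmids) {
  tibble::tibble(chem_id = chem, gene_id = gene, pmids = pmids)
}

test_that("the KB index merges duplicate pairs and unions their PMIDs", {
  rec <- mk_records(c("MESH:C1", "MESH:C1", "MESH:C2"),
                    c("GENE:1", "GENE:1", "GENE:2"),
                    list("1", "2", c("3", "4")))
  idx <- build_kb_index(rec)
  expect_equal(length(idx$pairs), 2)
  expect_setequal(idx$pair_pmids[[kbrelex:::pair_key(
    normalize_id("MESH:C1"), normalize_id("GENE:1"))]],
    c("1", "2"))
  expect_setequal(idx$doc_pmids, c("1", "2", "3", "4"))

  empty <- build_kb_index(mk_records(character(0), character(0), list()))
  expect_equal(length(empty$pairs), 0)
  expect_false(kb_has_pair(empty, "MESH:C1", "GENE:1"))
})

test_that("pair lookup is presence-only, case-normalized, and safe on unset ids", {
  idx <- build_kb_index(mk_records("MESH:C1", "GENE:1", list("1")))
  expect_true(kb_has_pair(idx, "MESH:C1", "GENE:1"))
  expect_true(kb_has_pair(idx, "mesh:c1", "gene:1"))
  expect_false(kb_has_pair(idx, "MESH:C1", "GENE:2"))
  res <- kb_has_pair(idx, c(NA, "", "MESH:C1"), c("GENE:1", "GENE:1", NA))
  expect_identical(as.logical(res), c(FALSE, FALSE, FALSE))
  expect_equal(attr(res, "n_unlinked"), 3)
})

test_that("the agreement rule keeps exactly the KB-consistent predictions", {
  idx <- build_kb_index(mk_records("MESH:C1", "GENE:1", list("1")))
  preds <- tibble::tibble(
    pmid = "1", arg1 = paste0("T", 1:4), arg2 = paste0("U", 1:4),
    label = c("INHIBITOR", "ACTIVATOR", "NONE", "NONE"),
    chem_id = c("MESH:C1", "MESH:C2", "MESH:C3", "MESH:C1"),
    gene_id = c("GENE:1", "GENE:1", "GENE:9", "GENE:1")
  )
  res <- refine(preds, idx)
  # positive in KB kept with the model's label; positive not in KB dropped;
  # NONE not in KB kept as negative; NONE in KB dropped
  expect_identical(res$augmented$arg1, c("T1", "T3"))
  expect_identical(res$augmented$label, c("INHIBITOR", "NONE"))
  expect_identical(res$augmented$model_label, res$augmented$label)
  expect_equal(res$report$n_input, 4)
  expect_equal(res$report$n_kept + res$report$n_dropped, 4)
  expect_equal(sum(res$report$breakdown), 4)
  expect_equal(res$report$breakdown["positive", "present"], 1)
  expect_equal(res$report$breakdown["negative", "absent"], 1)
})

test_that("surface forms fall back to KB name linking when norm ids are absent", {
  rec <- tibble::tibble(chem_id = "MESH:C1", gene_id = "GENE:1",
                        pmids = list("1"), chem_name = "Aspirin",
                        gene_name = "COX1")
  idx <- build_kb_index(rec)
  preds <- tibble::tibble(
    pmid = "1", arg1 = "T1", arg2 = "T2", label = "INHIBITOR",
    chem_id = NA_character_, gene_id = NA_character_,
    chem_surface = "aspirin", gene_surface = "COX1"
  )
  res <- refine(preds, idx)
  expect_equal(res$report$n_kept, 1)
})

test_that("refinement matches the brute-force keep rule on random instances", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    chems <- sprintf("MESH:C%d", 1:8)
    genes <- sprintf("GENE:%d", 1:8)
    kb_n <- sample(0:20, 1)
    kb <- unique(tibble::tibble(
      chem_id = sample(chems, kb_n, replace = TRUE),
      gene_id = sample(genes, kb_n, replace = TRUE)
    ))
    kb$pmids <- rep(list("1"), nrow(kb))
    idx <- build_kb_index(kb)
    preds <- tibble::tibble(
      pmid = as.character(sample.int(3, n, replace = TRUE)),
      arg1 = paste0("T", seq_len(n)), arg2 = paste0("U", seq_len(n)),
      label = sample(relation_labels(), n, replace = TRUE),
      chem_id = sample(chems, n, replace = TRUE),
      gene_id = sample(genes, n, replace = TRUE)
    )
    res <- refine(preds, idx)
    kb_pairs <- paste(tolower(kb$chem_id), tolower(kb$gene_id))
    keep <- oracle_refine_keep(preds, kb_pairs)
    expect_identical(res$augmented$arg1, preds$arg1[keep])
    expect_equal(res$report$n_kept + res$report$n_dropped, n)
  }
})

test_that("refinement is idempotent and monotone in the KB", {
  set.seed(17)
  chems <- sprintf("MESH:C%d", 1:6)
  genes <- sprintf("GENE:%d", 1:6)
  preds <- tibble::tibble(
    pmid = "1", arg1 = paste0("T", 1:80), arg2 = paste0("U", 1:80),
    label = sample(relation_labels(), 80, replace = TRUE),
    chem_id = sample(chems, 80, replace = TRUE),
    gene_id = sample(genes, 80, replace = TRUE)
  )
  small <- unique(tibble::tibble(
    chem_id = sample(chems, 8, replace = TRUE),
    gene_id = sample(genes, 8, replace = TRUE)))
  small$pmids <- rep(list("1"), nrow(small))
  big <- unique(dplyr::bind_rows(
    small, tibble::tibble(chem_id = sample(chems, 10, replace = TRUE),
                          gene_id = sample(genes, 10, replace = TRUE),
                          pmids = rep(list("2"), 10))))
  idx_small <- build_kb_index(small)
  idx_big <- build_kb_index(big)

  once <- refine(preds, idx_small)
  twice <- refine(once$augmented[, names(preds)], idx_small)
  expect_equal(twice$report$n_dropped, 0)

  r_small <- refine(preds, idx_small)
  r_big <- refine(preds, idx_big)
  pos_kept <- function(r) sum(r$augmented$label != "NONE")
  neg_kept <- function(r) sum(r$augmented$label == "NONE")
  expect_gte(pos_kept(r_big), pos_kept(r_small))
  expect_lte(neg_kept(r_big), neg_kept(r_small))
})

test_that("development-set overlap exclusion removes exactly the held-out PMIDs", {
  paths <- write_toy_corpus()
  ds <- read_drugprot(paths$abstracts, paths$entities, paths$relations)
  res <- exclude_dev_overlap(ds, "1001")
  expect_equal(res$n_excluded, 1)
  expect_identical(res$docs$documents$pmid, "1002")
  expect_equal(nrow(res$docs$relations), 0)

  ident <- exclude_dev_overlap(ds, character(0))
  expect_equal(ident$n_excluded, 0)
  expect_equal(ident$docs, ds)

  all_out <- exclude_dev_overlap(ds, c("1001", "1002"))
  expect_equal(all_out$n_excluded, 2)
  expect_equal(nrow(all_out$docs$documents), 0)
})

test_that("the weak-labelling pool can be restricted to KB-cited documents", {
  paths <- write_toy_corpus()
  ds <- read_drugprot(paths$abstracts, paths$entities, paths$relations)
  rec <- tibble::tibble(chem_id = "MESH:C1", gene_id = "GENE:1",
                        pmids = list("1002"))
  idx <- build_kb_index(rec)
  restricted <- restrict_to_kb_docs(ds, idx)
  expect_identical(restricted$documents$pmid, "1002")
  expect_equal(restrict_to_kb_docs(ds, idx, enabled = FALSE), ds)
})

test_that("refine reports serialize as text and JSON", {
  idx <- build_kb_index(mk_records("MESH:C1", "GENE:1", list("1")))
  preds <- tibble::tibble(pmid = "1", arg1 = "T1", arg2 = "U1",
                          label = "INHIBITOR", chem_id = "MESH:C1",
                          gene_id = "GENE:1")
  res <- refine(preds, idx)
  dir <- withr::local_tempdir()
  write_refine_report(res$report, file.path(dir, "r.txt"),
                      file.path(dir, "r.json"))
  txt <- readLines(file.path(dir, "r.txt"))
  expect_true(any(grepl("^n_kept\t1$", txt)))
  js <- jsonlite::read_json(file.path(dir, "r.json"))
  expect_equal(js$n_input, 1)
  expect_equal(js$breakdown$positive$present, 1)
})
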