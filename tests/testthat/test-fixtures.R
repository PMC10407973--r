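test_that("generation is deterministic given the configuration", {
  cfg <- fixture_config(n_docs = 15, seed = 77)
  a <- generate_fixtures(cfg)
  b <- generate_fixtures(cfg)
  expect_equal(a$docs, b$docs)
  expect_equal(a$manifest, b$manifest)
  expect_equal(a$kb, b$kb)
  # and the written files are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(a, d1)
  p2 <- write_fixtures(b, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("every generated bundle passes corpus validation on re-read", {
  bundle <- generate_fixtures(fixture_config(n_docs = 12, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(bundle, dir)
  ds <- read_drugprot(paths$abstracts, paths$entities, paths$relations)
  expect_equal(nrow(ds$documents), 12)
  expect_equal(nrow(ds$mentions), nrow(bundle$docs$mentions))
  expect_equal(nrow(ds$relations), sum(bundle$manifest$label != "NONE"))
  kb <- read_kb(paths$kb)
  expect_equal(nrow(kb), nrow(bundle$kb))
})

test_that("an empty corpus still yields valid, empty files", {
  bundle <- generate_fixtures(fixture_config(n_docs = 0, seed = 1))
  expect_equal(nrow(bundle$docs$documents), 0)
  expect_equal(nrow(bundle$manifest), 0)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(bundle, dir)
  ds <- read_drugprot(paths$abstracts, paths$entities, paths$relations)
  expect_equal(nrow(ds$documents), 0)
  expect_equal(nrow(ds$mentions), 0)
})

test_that("planted truth matches the gold relation files exactly", {
  bundle <- generate_fixtures(fixture_config(n_docs = 20, seed = 41))
  truth <- planted_truth(bundle)
  expect_equal(nrow(truth), sum(bundle$manifest$label != "NONE"))
  rel <- bundle$docs$relations
  expect_setequal(paste(truth$pmid, truth$rtype, truth$arg1, truth$arg2),
                  paste(rel$pmid, rel$rtype, rel$arg1, rel$arg2))
  expect_error(planted_truth(list(manifest = bundle$manifest)),
               "generated by this package")
})

test_that("full KB coverage without noise keeps every correct positive", {
  bundle <- generate_fixtures(fixture_config(n_docs = 25, kb_coverage = 1,
                                             kb_noise = 0, seed = 19))
  idx <- build_kb_index(bundle$kb)
  man <- bundle$manifest
  # a perfect classifier's predictions are the planted truth itself
  perfect <- tibble::tibble(pmid = man$pmid, arg1 = man$arg1,
                            arg2 = man$arg2, label = man$label,
                            chem_id = man$chem_id, gene_id = man$gene_id)
  res <- refine(perfect, idx)
  n_pos <- sum(man$label != "NONE")
  expect_equal(sum(res$augmented$label != "NONE"), n_pos)
  # brute-force check over the manifest
  kb_pairs <- paste(tolower(bundle$kb$chem_id), tolower(bundle$kb$gene_id))
  keep <- oracle_refine_keep(perfect, kb_pairs)
  expect_equal(res$report$n_kept, sum(keep))
})

test_that("planted labels follow the configured distribution", {
  dist <- drugprot_label_distribution("train")
  # enough documents for roughly 2000 positive relations
  n_docs <- ceiling(2000 / (4.5 * 0.7))
  bundle <- generate_fixtures(fixture_config(n_docs = n_docs, seed = 12))
  labels <- bundle$manifest$label[bundle$manifest$label != "NONE"]
  expect_gt(length(labels), 1500)
  obs <- table(factor(labels, levels = names(dist)))
  set.seed(1)
  test <- suppressWarnings(
    stats::chisq.test(obs, p = dist, simulate.p.value = TRUE, B = 2000))
  expect_gt(test$p.value, 0.01)
})

test_that("KB noise pairs are never expressed as planted positives", {
  bundle <- generate_fixtures(fixture_config(n_docs = 20, kb_noise = 30,
                                             seed = 8))
  man <- bundle$manifest[bundle$manifest$label != "NONE", ]
  planted <- unique(paste(man$chem_id, man$gene_id))
  noise <- bundle$kb[bundle$kb$action == "interacts^noise", ]
  expect_equal(nrow(noise), 30)
  expect_length(intersect(paste(noise$chem_id, noise$gene_id), planted), 0)
  # supporting PMIDs of noise pairs lie outside the corpus
  expect_length(intersect(unlist(noise$pmids),
                          bundle$docs$documents$pmid), 0)
})

test_that("an impossible KB noise request is rejected", {
  expect_error(
    generate_fixtures(fixture_config(n_docs = 5, n_chems = 2, n_genes = 2,
                                     kb_noise = 100, seed = 2)),
    "lexicon too small")
})

test_that("shared lexicon seeds give splits a common vocabulary", {
  a <- generate_fixtures(fixture_config(n_docs = 5, seed = 1,
                                        lexicon_seed = 99,
                                        pmid_start = 101))
  b <- generate_fixtures(fixture_config(n_docs = 5, seed = 2,
                                        lexicon_seed = 99,
                                        pmid_start = 201))
  expect_equal(a$lexicon, b$lexicon)
  expect_length(intersect(a$docs$documents$pmid, b$docs$documents$pmid), 0)
})
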