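test_that("rule-based splitting yields offset-exact, tiling windows", {
  doc <- tibble::tibble(pmid = "1", title = "T.",
                        abstract = "A binds B. C inhibits D.")
  doc$full_text <- paste(doc$title, doc$abstract, sep = "\t")
  win <- split_sentences(doc)
  expect_equal(nrow(win), 3)  # title plus two sentences
  expect_identical(win$text,
                   c("T.", "A binds B.", "C inhibits D."))
  # offset preservation: text == full_text[start:end)
  expect_identical(substr(rep(doc$full_text, 3), win$start + 1, win$end),
                   win$text)
  # windows ordered and non-overlapping
  expect_true(all(win$start[-1] >= win$end[-nrow(win)]))

  single <- tibble::tibble(pmid = "2", title = "X",
                           abstract = "One sentence only")
  single$full_text <- paste(single$title, single$abstract, sep = "\t")
  w2 <- split_sentences(single)
  expect_equal(nrow(w2), 2)
  expect_identical(w2$text[2], "One sentence only")
})

test_that("a splitter violating the window contract is rejected", {
  doc <- tibble::tibble(pmid = "1", title = "T.", abstract = "A binds B.")
  doc$full_text <- paste(doc$title, doc$abstract, sep = "\t")
  overlapping <- function(text) cbind(start = c(0L, 2L), end = c(5L, 8L))
  expect_error(split_sentences(doc, overlapping), "overlap")
  out_of_range <- function(text) cbind(start = 0L,
                                       end = nchar(text) + 5L)
  expect_error(split_sentences(doc, out_of_range), "range")
})

test_that("entity projection attaches contained mentions and drops straddlers", {
  paths <- write_toy_corpus()
  ds <- read_drugprot(paths$abstracts, paths$entities, paths$relations)
  doc <- ds$documents[ds$documents$pmid == "1001", ]
  win <- split_sentences(doc)
  # add a mention straddling the boundary between the two abstract sentences
  straddler <- tibble::tibble(pmid = "1001", mention_id = "TX",
                              etype = "GENE", start = 33L, end = 42L,
                              surface = substr(doc$full_text, 34, 42),
                              norm_id = NA_character_)
  m <- dplyr::bind_rows(ds$mentions, straddler)
  win <- project_entities(doc, win, m)
  expect_equal(attr(win, "n_dropped"), 1)
  attached <- dplyr::bind_rows(win$mentions)
  expect_false("TX" %in% attached$mention_id)
  expect_setequal(attached$mention_id, c("T1", "T2", "T3", "T4"))
})

test_that("identical spans with different types are both attached", {
  docs <- tibble::tibble(pmid = "7", title = "N.", abstract = "ABC1 works.")
  mentions <- tibble::tibble(
    pmid = "7", mention_id = c("T1", "T2"),
    etype = c("CHEMICAL", "GENE"), start = c(3L, 3L), end = c(7L, 7L),
    surface = c("ABC1", "ABC1"), norm_id = NA_character_
  )
  ds <- document_set(docs, mentions)
  doc <- ds$documents[1, ]
  win <- project_entities(doc, split_sentences(doc), ds$mentions)
  attached <- dplyr::bind_rows(win$mentions)
  expect_setequal(attached$mention_id, c("T1", "T2"))
})

test_that("pair enumeration is the ordered cartesian product within a sentence", {
  mk <- function(id, etype, start, surface) {
    tibble::tibble(pmid = "1", mention_id = id, etype = etype,
                   start = start, end = start + nchar(surface),
                   surface = surface, norm_id = NA_character_)
  }
  window <- tibble::tibble(
    pmid = "1", sent_index = 0L, start = 0L, end = 60L,
    text = strrep("x", 60),
    mentions = list(dplyr::bind_rows(
      mk("C1", "CHEMICAL", 0L, "aaa"), mk("C2", "CHEMICAL", 10L, "bbb"),
      mk("G1", "GENE", 20L, "ccc"), mk("G2", "GENE", 30L, "ddd"),
      mk("G3", "GENE", 40L, "eee")
    ))
  )
  pairs <- enumerate_pairs(window)
  expect_equal(nrow(pairs), 6)  # 2 chemicals x 3 genes
  # deterministic (chem offset, gene offset) order
  expect_identical(pairs$arg1, c("C1", "C1", "C1", "C2", "C2", "C2"))
  expect_identical(pairs$arg2, rep(c("G1", "G2", "G3"), 2))

  chem_only <- window
  chem_only$mentions <- list(dplyr::bind_rows(
    mk("C1", "CHEMICAL", 0L, "aaa"), mk("C2", "CHEMICAL", 10L, "bbb")))
  expect_equal(nrow(enumerate_pairs(chem_only)), 0)
})

test_that("no pair is produced across sentence boundaries", {
  docs <- tibble::tibble(pmid = "9", title = "T.",
                         abstract = "Aspirin works. COX1 reacts.")
  mentions <- tibble::tibble(
    pmid = "9", mention_id = c("T1", "T2"),
    etype = c("CHEMICAL", "GENE"),
    start = c(3L, 18L), end = c(10L, 22L),
    surface = c("Aspirin", "COX1"), norm_id = NA_character_
  )
  ds <- document_set(docs, mentions)
  pairs <- preprocess_corpus(ds)
  expect_equal(nrow(pairs), 0)
})

test_that("the four marking methods reproduce the worked example", {
  ds <- marking_example_doc()
  pairs <- preprocess_corpus(ds, method = "NONE")
  expect_equal(nrow(pairs), 1)
  pair <- pairs[1, ]
  expect_identical(
    mark_entities(pair, "NONE")$text,
    "Alendronate was a slow-binding inhibitor of PTPmeg1.")
  expect_identical(
    mark_entities(pair, "MASK")$text,
    "CHEM was a slow-binding inhibitor of GENE.")
  expect_identical(
    mark_entities(pair, "WRAP_TYPE")$text,
    "CHEM Alendronate CHEM was a slow-binding inhibitor of GENE PTPmeg1 GENE.")
  expect_identical(
    mark_entities(pair, "WRAP_TYPE_SE")$text,
    "CHEM-S Alendronate CHEM-E was a slow-binding inhibitor of GENE-S PTPmeg1 GENE-E.")
})

test_that("start/end wrapping is invertible and only touches the pair", {
  bundle <- generate_fixtures(fixture_config(n_docs = 15, seed = 23))
  pairs <- preprocess_corpus(bundle$docs, method = "WRAP_TYPE_SE")
  raw <- preprocess_corpus(bundle$docs, method = "NONE")
  tok <- marker_tokens()
  stripped <- pairs$marked
  for (mk in c(tok$chem_start, tok$gene_start)) {
    stripped <- gsub(paste0(mk, " "), "", stripped, fixed = TRUE)
  }
  for (mk in c(tok$chem_end, tok$gene_end)) {
    stripped <- gsub(paste0(" ", mk), "", stripped, fixed = TRUE)
  }
  expect_identical(stripped, raw$marked)
})

test_that("co-occurring mentions outside the selected pair stay raw", {
  docs <- tibble::tibble(pmid = "5", title = "T.",
                         abstract = "Aspirin and naproxen inhibit COX1.")
  mentions <- tibble::tibble(
    pmid = "5", mention_id = c("T1", "T2", "T3"),
    etype = c("CHEMICAL", "CHEMICAL", "GENE"),
    start = c(3L, 15L, 32L), end = c(10L, 23L, 36L),
    surface = c("Aspirin", "naproxen", "COX1"), norm_id = NA_character_
  )
  ds <- document_set(docs, mentions)
  pairs <- preprocess_corpus(ds, method = "WRAP_TYPE_SE")
  expect_equal(nrow(pairs), 2)
  m1 <- pairs$marked[pairs$arg1 == "T1"]
  # naproxen is untouched in the sequence for the (Aspirin, COX1) pair
  expect_true(grepl("and naproxen inhibit", m1, fixed = TRUE))
  expect_identical(
    m1,
    "CHEM-S Aspirin CHEM-E and naproxen inhibit GENE-S COX1 GENE-E.")
})

test_that("identical chem/gene spans nest with chemical markers outside", {
  pair <- tibble::tibble(
    pmid = "1", sent_index = 0L, arg1 = "T1", arg2 = "T2",
    chem_start = 0L, chem_end = 4L, chem_surface = "ABC1",
    chem_id = NA_character_,
    gene_start = 0L, gene_end = 4L, gene_surface = "ABC1",
    gene_id = NA_character_,
    text = "ABC1 signals."
  )
  out <- mark_entities(pair, "WRAP_TYPE_SE")
  expect_identical(out$text,
                   "CHEM-S GENE-S ABC1 GENE-E CHEM-E signals.")
})

test_that("over-long sentences are truncated symmetrically around the pair", {
  pad <- strrep("filler words here ", 20)
  text <- paste0(pad, "aspirin inhibits COX1", " ", pad)
  cs <- nchar(pad)
  pair <- tibble::tibble(
    pmid = "1", sent_index = 0L, arg1 = "T1", arg2 = "T2",
    chem_start = cs, chem_end = cs + 7L, chem_surface = "aspirin",
    chem_id = NA_character_,
    gene_start = cs + 17L, gene_end = cs + 21L, gene_surface = "COX1",
    gene_id = NA_character_,
    text = text
  )
  out <- mark_entities(pair, "WRAP_TYPE_SE", max_chars = 80)
  expect_true(out$truncated)
  expect_true(grepl("CHEM-S aspirin CHEM-E inhibits GENE-S COX1 GENE-E",
                    out$text, fixed = TRUE))
  # 80 cap plus four markers and padding
  expect_lte(nchar(out$text), 80 + 4 * 7)
})

test_that("dictionary tagging finds exact word-boundary matches with norm ids", {
  docs <- tibble::tibble(pmid = "3", title = "T.",
                         abstract = "Aspirin inhibits COX1 but not COX15.")
  ds <- document_set(docs)
  lex <- tibble::tibble(surface = c("Aspirin", "COX1"),
                        etype = c("CHEMICAL", "GENE"),
                        norm_id = c("MESH:C1", "GENE:1"))
  tagged <- tag_entities_dictionary(ds, lex)
  expect_equal(nrow(tagged$mentions), 2)  # COX15 must not match COX1
  expect_setequal(tagged$mentions$norm_id, c("MESH:C1", "GENE:1"))
})
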