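gold2 <- tibble::tibble(
  pmid = "d1", rtype = c("INHIBITOR", "SUBSTRATE"),
  arg1 = "c1", arg2 = c("g1", "g2")
)
pred2 <- tibble::tibble(
  pmid = "d1", arg1 = "c1", arg2 = c("g1", "g3"),
  label = c("INHIBITOR", "AGONIST")
)

test_that("tuple-match scoring reproduces the hand-enumerated example", {
  rep <- evaluate_relations(gold2, pred2)
  expect_equal(rep$micro$precision, 0.5)
  expect_equal(rep$micro$recall, 0.5)
  expect_equal(rep$micro$f1, 0.5)
  expect_equal(rep$per_type$tp[rep$per_type$type == "INHIBITOR"], 1)
  expect_equal(rep$per_type$fp[rep$per_type$type == "AGONIST"], 1)
  expect_equal(rep$per_type$fn[rep$per_type$type == "SUBSTRATE"], 1)
})

test_that("perfect and empty predictions hit the degenerate conventions", {
  perfect <- tibble::tibble(pmid = gold2$pmid, arg1 = gold2$arg1,
                            arg2 = gold2$arg2, label = gold2$rtype)
  rep <- evaluate_relations(gold2, perfect)
  expect_equal(rep$micro$precision, 1)
  expect_equal(rep$micro$recall, 1)
  expect_equal(rep$micro$f1, 1)

  none <- tibble::tibble(pmid = character(0), arg1 = character(0),
                         arg2 = character(0), label = character(0))
  rep0 <- evaluate_relations(gold2, none)
  expect_equal(rep0$micro$precision, 0)
  expect_equal(rep0$micro$recall, 0)
  expect_equal(rep0$micro$f1, 0)

  # NONE predictions generate no false positives
  just_none <- tibble::tibble(pmid = "d1", arg1 = "c9", arg2 = "g9",
                              label = "NONE")
  repn <- evaluate_relations(gold2, just_none)
  expect_equal(repn$micro$fp, 0)
})

test_that("micro F1 ignores prediction order and duplicate tuples", {
  preds <- random_predictions(40, seed = 8)
  gold <- tibble::tibble(pmid = preds$pmid[1:15], rtype = preds$label[1:15],
                         arg1 = preds$arg1[1:15], arg2 = preds$arg2[1:15])
  gold <- gold[gold$rtype != "NONE", ]
  a <- evaluate_relations(gold, preds)
  b <- evaluate_relations(gold, preds[rev(seq_len(nrow(preds))), ])
  expect_equal(a$micro, b$micro)
  expect_warning(c_ <- evaluate_relations(gold, dplyr::bind_rows(preds, preds)),
                 "duplicate")
  expect_equal(a$micro, c_$micro)
})

test_that("scoring matches the brute-force set-intersection oracle", {
  set.seed(55)
  for (i in 1:25) {
    preds <- random_predictions(sample(10:80, 1), seed = 1000 + i)
    ng <- sample(5:40, 1)
    gold <- tibble::tibble(
      pmid = as.character(sample.int(3, ng, replace = TRUE)),
      rtype = sample(positive_labels(), ng, replace = TRUE),
      arg1 = paste0("C", sample.int(4, ng, replace = TRUE)),
      arg2 = paste0("G", sample.int(4, ng, replace = TRUE))
    )
    gold <- gold[!duplicated(gold), ]
    rep <- evaluate_relations(gold, preds)
    orc <- oracle_micro(gold, preds)
    expect_equal(rep$micro$precision, orc$precision)
    expect_equal(rep$micro$recall, orc$recall)
    expect_equal(rep$micro$f1, orc$f1)
    # count-sum law: per-type TP+FN covers every gold tuple exactly once
    expect_equal(sum(rep$per_type$tp + rep$per_type$fn), nrow(gold))
  }
})

test_that("confusion counts route wrong types, misses, and spurious pairs", {
  gold <- tibble::tibble(pmid = "d1", rtype = c("INHIBITOR", "AGONIST"),
                         arg1 = c("c1", "c2"), arg2 = c("g1", "g2"))
  preds <- tibble::tibble(
    pmid = "d1", arg1 = c("c1", "c3"), arg2 = c("g1", "g3"),
    label = c("ACTIVATOR", "SUBSTRATE")
  )
  cm <- confusion_relations(gold, preds)
  expect_equal(cm["INHIBITOR", "ACTIVATOR"], 1)  # wrong type
  expect_equal(cm["AGONIST", "NONE"], 1)         # missed gold pair
  expect_equal(cm["NONE", "SUBSTRATE"], 1)       # spurious pair
  # matrix total equals the number of distinct scored pair keys
  expect_equal(sum(cm), 3)
  # rendering option drops the NONE prediction column
  cm2 <- confusion_relations(gold, preds, omit_none_pred = TRUE)
  expect_false("NONE" %in% colnames(cm2))
})

test_that("report diffs are antisymmetric and recover the published gap", {
  pair <- dev_report_pair()
  d <- diff_reports(pair$baseline, pair$transfer)
  expect_equal(unname(d$micro["f1"]), 0.18, tolerance = 1e-8)
  expect_equal(unname(d$micro["precision"]), 0.96, tolerance = 1e-8)
  expect_equal(unname(d$micro["recall"]), -0.56, tolerance = 1e-8)
  back <- diff_reports(pair$transfer, pair$baseline)
  expect_equal(d$micro, -back$micro)
  expect_equal(d$per_type$f1, -back$per_type$f1)
  same <- diff_reports(pair$baseline, pair$baseline)
  expect_true(all(same$micro == 0))
  expect_true(all(same$per_type$f1 == 0))
  # label-set mismatch is an error
  trimmed <- pair$transfer
  trimmed$per_type <- trimmed$per_type[-1, ]
  expect_error(diff_reports(pair$baseline, trimmed), "label set")
})

test_that("reports render as aligned text and machine-readable JSON", {
  rep <- evaluate_relations(gold2, pred2)
  lines <- render_eval_report(rep)
  expect_true(any(grepl("Micro-average", lines)))
  expect_true(any(grepl("50.00", lines)))
  dir <- withr::local_tempdir()
  write_eval_report(rep, file.path(dir, "rep.json"))
  js <- jsonlite::read_json(file.path(dir, "rep.json"))
  expect_equal(js$micro$f1, 0.5)
})
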