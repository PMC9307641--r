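test_that("normalization folds case and whitespace and is idempotent", {
  expect_identical(normalize_text("Adeno-Carcinoma  of   colon")$text,
                   "adeno-carcinoma of colon")
  expect_identical(normalize_text("NO  high-grade dysplasia")$text,
                   "no high-grade dysplasia")
  t1 <- normalize_text("Severe   Dysplasia\n of the  COLON")$text
  expect_identical(normalize_text(t1)$text, t1)
  expect_error(normalize_text("   "), class = "pathmil_validation_error")
  # the offset map projects normalized spans back onto the original text
  norm <- normalize_text("Tubular   Adenoma")
  expect_identical(substr("Tubular   Adenoma", norm$map[9], norm$map[9] + 6),
                   "Adenoma")
})

test_that("mention recognition prefers the longest match and never overlaps", {
  gaz <- toy_gazetteer()
  m <- recognize_mentions("tubular adenoma with low-grade dysplasia", gaz)
  expect_identical(m$surface, c("tubular adenoma", "low-grade dysplasia"))
  m2 <- recognize_mentions("moderately differentiated adenocarcinoma", gaz)
  expect_identical(m2$surface, "adenocarcinoma")
  expect_identical(nrow(recognize_mentions("nothing relevant here", gaz)), 0L)
  # surfaces equal the normalized-text slice at the span
  txt <- normalize_text("fragments with severe dysplasia and hyperplasia")$text
  m3 <- recognize_mentions(txt, gaz)
  for (i in seq_len(nrow(m3))) {
    expect_identical(substring(txt, m3$start[i], m3$end[i]), m3$surface[i])
  }
  # spans never overlap
  if (nrow(m3) > 1) expect_true(all(diff(m3$start) > 0) &&
                                  all(m3$start[-1] > m3$end[-nrow(m3)]))
})

test_that("recognition agrees with a brute-force longest-match oracle", {
  gaz <- toy_gazetteer()
  texts <- c("tubular adenoma with low-grade dysplasia",
             "hyperplasia at the margin of resection",
             "severe dysplasia and adenocarcinoma of the colon",
             "normal colonic mucosa without dysplasia",
             "dysplasia dysplasia high-grade dysplasia")
  term_tokens <- lapply(pathmil:::gazetteer_terms(gaz)$key,
                        function(k) strsplit(k, " ")[[1]])
  for (txt in texts) {
    norm <- normalize_text(txt)$text
    toks <- pathmil:::tokenize_norm(norm)
    hits <- oracle_greedy_match(toks$token, term_tokens)
    m <- recognize_mentions(norm, gaz)
    expect_identical(nrow(m), length(hits))
    for (i in seq_along(hits)) {
      expect_identical(m$start[i], toks$start[hits[[i]][1]])
      expect_identical(m$end[i], toks$end[hits[[i]][2]])
    }
  }
})

test_that("linking falls through exact, ad-hoc and similarity stages", {
  gaz <- toy_gazetteer()
  exact <- link_mention("adenocarcinoma", gaz)
  expect_identical(exact$method, "exact")
  expect_identical(exact$score, 1.0)
  # deletion typo resolves by similarity with the DP edit-distance ratio
  typo <- link_mention("adenocarcnoma", gaz)
  expect_identical(typo$method, "similarity")
  expect_identical(typo$concept_id, "c:adeno")
  d <- oracle_edit_distance("adenocarcnoma", "adenocarcinoma")
  expect_equal(typo$score, 1 - d / max(nchar("adenocarcnoma"), nchar("adenocarcinoma")))
  expect_gte(typo$score, 0.85)
  expect_null(link_mention("qwertyuiop", gaz))
  # plural rewrites through the ad-hoc stage
  adhoc <- link_mention("adeno carcinoma", gaz)
  expect_identical(adhoc$method, "adhoc_rule")
})

test_that("negation detection honors cues, windows and sentence boundaries", {
  gaz <- toy_gazetteer()
  cfg <- labeler_config()
  nt <- normalize_text("no high-grade dysplasia")$text
  m <- recognize_mentions(nt, gaz)
  expect_true(detect_negation(nt, m[1, ], cfg))
  nt2 <- normalize_text("high-grade dysplasia is present")$text
  m2 <- recognize_mentions(nt2, gaz)
  expect_false(detect_negation(nt2, m2[1, ], cfg))
  # cue beyond the 5-token window does not negate
  nt3 <- normalize_text(
    "no evidence, in any of the many fragments examined, of dysplasia")$text
  m3 <- recognize_mentions(nt3, gaz)
  expect_false(detect_negation(nt3, m3[nrow(m3), ], cfg))
  # sentence boundary blocks the cue
  nt4 <- normalize_text("no ulceration. high-grade dysplasia")$text
  m4 <- recognize_mentions(nt4, gaz)
  expect_false(detect_negation(nt4, m4[nrow(m4), ], cfg))
  # multiword cue
  nt5 <- normalize_text("absence of dysplasia")$text
  m5 <- recognize_mentions(nt5, gaz)
  expect_true(detect_negation(nt5, m5[1, ], cfg))
})

test_that("report labeling maps concepts, resolves grades and falls back to normal", {
  gaz <- toy_gazetteer()
  # nothing recognized -> normal fallback
  r <- label_report("three unremarkable tissue fragments", gaz)
  expect_identical(unname(r$label), c(0L, 0L, 0L, 0L, 1L))
  # severe grade adjective promotes dysplasia to high grade; multilabel with cancer
  r2 <- label_report(
    "tubulovillous adenoma with severe dysplasia; infiltrating adenocarcinoma",
    gaz)
  expect_identical(unname(r2$label), c(1L, 1L, 0L, 0L, 0L))
  # bare dysplasia defaults to the configured (low) grade
  r3 <- label_report("fragments with dysplasia", gaz)
  expect_identical(label_classes(r3$label), "low_grade_dysplasia")
  r3b <- label_report("fragments with dysplasia", gaz,
                      labeler_config(unspecified_grade_class = "high_grade_dysplasia"))
  expect_identical(label_classes(r3b$label), "high_grade_dysplasia")
  # negated mention is discarded when negation is on, kept when off
  txt <- "tubular adenoma with mild dysplasia. no high-grade dysplasia."
  on <- label_report(txt, gaz)
  off <- label_report(txt, gaz, labeler_config(negation_enabled = FALSE))
  expect_identical(label_classes(on$label), "low_grade_dysplasia")
  expect_setequal(label_classes(off$label),
                  c("low_grade_dysplasia", "high_grade_dysplasia"))
  # disabling negation only ever adds classes (monotone superset)
  expect_true(all(on$label <= off$label))
})

test_that("the hyperplasia-margin trap is suppressed by context rules only", {
  gaz <- toy_gazetteer()
  txt <- "margin of resection on hyperplasia-adenomatous mucosa"
  with_rules <- label_report(txt, gaz)
  expect_identical(label_classes(with_rules$label), "normal")
  no_rules <- label_report(txt, gaz,
                           labeler_config(context_rules_enabled = FALSE,
                                          negation_enabled = FALSE))
  expect_identical(label_classes(no_rules$label), "hyperplastic_polyp")
})

test_that("label_report never returns the all-zero vector", {
  gaz <- toy_gazetteer()
  texts <- c("a", "no adenocarcinoma", "without dysplasia. free of hyperplasia.",
             "margin of resection on hyperplasia",
             "colon biopsy fragments")
  for (txt in texts) {
    expect_gte(sum(label_report(txt, gaz)$label), 1L)
  }
})

test_that("corpus labeling scores against ground truth with a cell-count oracle", {
  gaz <- toy_gazetteer()
  reports <- tibble::tibble(
    report_id = paste0("r", 1:4),
    text = c("infiltrating adenocarcinoma",
             "tubular adenoma with mild dysplasia",
             "hyperplastic polyp",
             "normal colonic mucosa"))
  gt <- pathmil:::labels_to_tibble(reports$report_id, rbind(
    make_label("cancer"), make_label("low_grade_dysplasia"),
    make_label("hyperplastic_polyp"), make_label("normal")))
  perfect <- label_corpus(reports, gaz, gt = gt)
  expect_equal(perfect$metrics$micro_accuracy, 1.0)
  # flip one ground-truth cell: 19 of 20 indicator cells now agree
  gt_bad <- gt
  gt_bad$cancer[2] <- 1L
  one_off <- label_corpus(reports, gaz, gt = gt_bad)
  expect_equal(one_off$metrics$micro_accuracy, 19 / 20)
  dup <- reports
  dup$report_id[2] <- "r1"
  expect_error(label_corpus(dup, gaz), class = "pathmil_validation_error")
})

test_that("reports round-trip through JSONL", {
  reports <- tibble::tibble(report_id = c("a", "b"),
                            text = c("normal colonic mucosa", "dysplasia"),
                            case_ids = list("s1", c("s2", "s3")))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(reports, path)
  back <- read_reports_jsonl(path)
  expect_equal(back, reports)
})
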