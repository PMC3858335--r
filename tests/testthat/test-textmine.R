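# text mining: query construction, tokenization, entity detection,
# distance-rule scoring, relation extraction, dedup

test_that("build_query reproduces the four-clause template", {
  expect_identical(
    build_query("2C19", "population", "effect"),
    paste0("(Abstract: CYP2C19* OR Title: CYP2C19*) AND ",
           "(Abstract: population OR Title: population) AND ",
           "(Abstract: effect OR Title: effect) AND ",
           "(Abstract: frequenc* OR Title: frequenc*)"))
  # OR-expansion of synonym lists (string-construction oracle)
  q <- build_query("2D6", c("population", "cohort"), "effect")
  expect_true(grepl(
    "(Abstract: population OR Title: population OR Abstract: cohort OR Title: cohort)",
    q, fixed = TRUE))
  expect_error(build_query("2C19", character(0), character(0)),
               "empty synonym list")
  expect_error(build_query("not-a-cyp", "population", "effect"),
               "malformed CYP id.*not-a-cyp")
})

test_that("tokenize keeps domain units intact and segments sentences", {
  t1 <- tokenize("CYP2D6*4 is frequent.")
  expect_identical(t1$token, c("CYP2D6*4", "is", "frequent", "."))
  expect_identical(t1$sentence, rep(0L, 4))
  expect_identical(t1$position, 0:3)

  expect_identical(nrow(tokenize("")), 0L)

  t2 <- tokenize("A. B.")
  expect_identical(unique(t2$sentence), c(0L, 1L))

  # rsIDs and percentages survive as single tokens
  t3 <- tokenize("rs1065852 occurred at 81.3% here")
  expect_true(all(c("rs1065852", "81.3%") %in% t3$token))

  # no lexicon single-token surface form is ever split
  lex <- default_lexicon()
  single <- lex$surface_form[!grepl("\\s", lex$surface_form)]
  for (s in single) expect_identical(tokenize(s)$token, s)
})

test_that("detect_mentions finds dictionary and pattern entities", {
  m <- detect_mentions(tokenize("In Caucasians CYP2C19*2 occurred at 16.0%."))
  expect_identical(m$entity_class, c("ETHNICITY", "CYP", "FREQUENCY"))
  expect_identical(m$canonical_id[1:2], c("Caucasian", "2C19"))
  expect_identical(m$token_start, c(1L, 2L, 5L))
  expect_equal(m$value[3], 16.0)

  expect_identical(nrow(detect_mentions(tokenize(""))), 0L)

  # out-of-range frequency guard
  expect_warning(m2 <- detect_mentions(tokenize("150% of samples")),
                 "out-of-range")
  expect_false(any(m2$entity_class == "FREQUENCY"))

  # spaced CYP form and "percent" word form
  m3 <- detect_mentions(tokenize("CYP 2D6 in 12 percent of Europeans"))
  expect_true(any(m3$entity_class == "CYP" & m3$canonical_id == "2D6"))
  expect_true(any(m3$entity_class == "FREQUENCY" & m3$value == 12))
})

test_that("score_relation follows the distance rule", {
  expect_identical(score_relation(7, 6), 100)   # at the thresholds
  expect_identical(score_relation(0, 0), 100)
  # linear decay beyond thresholds, 10 points per excess token
  expect_identical(score_relation(9, 6), 100 - 10 * (9 - 7))
  expect_identical(score_relation(7, 10), 100 - 10 * (10 - 6))
  expect_identical(score_relation(30, 30), 0)   # floored at 0
  # negation halves
  expect_identical(score_relation(7, 6, negated = TRUE), 50)
  expect_error(score_relation(-1, 0), "non-negative")
})

test_that("score_relation is monotone non-increasing and clamped (property)", {
  for (negated in c(FALSE, TRUE)) {
    s <- outer(0:30, 0:30, function(a, b)
      score_relation(a, b, negated = negated))
    expect_true(all(s >= 0 & s <= 100))
    expect_true(all(diff(s[, 1]) <= 0))          # in d_ce
    expect_true(all(apply(s, 1, diff) <= 0))     # in d_fc
  }
})

test_that("extract_relations enumerates in-window triples", {
  doc <- one_doc(paste("Background sentence here.",
                       "In Caucasians CYP2C19*2 occurred at 16.0%",
                       "with decreased activity."))
  r <- extract_relations(doc)
  expect_identical(nrow(r), 1L)
  expect_identical(r$cyp, "2C19")
  expect_identical(r$ethnicity, "Caucasian")
  expect_equal(r$frequency, 16.0)
  expect_identical(r$effect, "decrease")
  expect_identical(r$score, 100)

  # CYP alone yields nothing
  expect_identical(nrow(extract_relations(one_doc("Only CYP2D6 appears."))), 0L)

  # two identical triples -> 2 candidates before dedup, 1 after
  twice <- one_doc(paste("Caucasians carry CYP2D6*4 at 20.7%.",
                         "Caucasians carry CYP2D6*4 at 20.7%."))
  r2 <- extract_relations(twice)
  expect_identical(nrow(r2), 2L)
  expect_identical(nrow(deduplicate(r2)), 1L)
})

test_that("negation and cross-sentence windows are handled", {
  # the negation cue sits between the closest pair (frequency-CYP here)
  neg <- extract_relations(one_doc(
    "CYP2D6*4 was not seen at 20.7% in Caucasians."))
  expect_true(neg$negated)
  expect_identical(neg$score, 50)

  split_doc <- one_doc("Caucasians were genotyped. CYP2D6*4 reached 20.7%.")
  expect_identical(nrow(extract_relations(split_doc)), 0L)
  xs <- extract_relations(split_doc,
                          params = scoring_params(cross_sentence = TRUE))
  expect_identical(nrow(xs), 1L)
  expect_lte(xs$score, 90)  # cross-sentence cap
})

test_that("deduplicate keeps the top-scoring candidate per key and is idempotent", {
  r <- extract_relations(one_doc(paste(
    "Caucasians carry CYP2D6*4 at 20.7%.",
    "Caucasians very clearly also were seen to carry with some further",
    "words between CYP2D6*4 at 20.7% today.")))
  expect_identical(nrow(r), 2L)
  expect_true(any(r$score < 100))
  d <- deduplicate(r)
  expect_identical(nrow(d), 1L)
  expect_identical(d$score, 100)
  expect_identical(deduplicate(d), d)
  expect_identical(nrow(deduplicate(r[0, ])), 0L)
})

test_that("validation records follow the review state machine and round-trip", {
  r <- extract_relations(one_doc(
    "In Caucasians CYP2C19*2 occurred at 16.0% with decreased activity."))
  v <- as_validation_records(r)
  expect_identical(v$state, "UNREVIEWED")
  expect_error(export_records(v, tempfile()), "unresolved")

  v <- set_validation_state(v, 1, "NOT_SURE", reviewer = "scientist1")
  expect_error(export_records(v, tempfile(), allow_unresolved = FALSE),
               "NOT_SURE")
  v <- set_validation_state(v, 1, "TRUE", reviewer = "scientist2",
                            comment = "checked full text")
  expect_error(set_validation_state(v, 1, "FALSE"), "invalid.*transition")

  path <- withr::local_tempfile(fileext = ".tsv")
  export_records(v, path)
  back <- read_validation_records(path)
  expect_identical(nrow(back), 1L)
  cols <- c("doc_id", "cyp", "ethnicity", "frequency", "effect",
            "score", "state", "comment")
  rt <- as.data.frame(v)[, cols]
  rownames(rt) <- NULL
  expect_equal(back, rt)
})

test_that("read_corpus accepts TSV and directories of txt files", {
  dir <- withr::local_tempdir()
  writeLines("Caucasians carry CYP2D6*4 at 20.7%.",
             file.path(dir, "PMID001.txt"))
  cd <- read_corpus(dir)
  expect_identical(cd$doc_id, "PMID001")
  hits <- mine_corpus(cd, params = scoring_params(min_score = 100))
  expect_identical(nrow(hits), 1L)
})
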