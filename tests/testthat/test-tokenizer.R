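test_that("character-run splitting keeps letter and digit runs intact", {
  expect_identical(split_char_runs("Dr.Smith")$text, c("Dr", ".", "Smith"))
  expect_identical(split_char_runs("48-year-old")$text,
                   c("48", "-", "year", "-", "old"))
  expect_identical(nrow(split_char_runs("")), 0L)
  expect_identical(nrow(split_char_runs("   ")), 0L)
  t <- split_char_runs("a_b 12.5")
  expect_identical(t$text, c("a", "_", "b", "12", ".", "5"))
  expect_identical(t$start, c(0L, 1L, 2L, 4L, 6L, 7L))
})

test_that("uppercase splitting cuts before internal capitals only", {
  hc <- split_uppercase(split_char_runs("HealthCare"))
  expect_identical(hc$text, c("Health", "Care"))
  expect_identical(split_uppercase(split_char_runs("Edwin"))$text, "Edwin")
  expect_identical(split_uppercase(split_char_runs("ABC"))$text,
                   c("A", "B", "C"))
  # offsets stay anchored to the source
  expect_identical(hc$start, c(0L, 6L))
  expect_identical(hc$end, c(6L, 10L))
})

test_that("the full worked tokenization example comes out exactly", {
  toks <- tokenize("48-year-old in Edwin HealthCare")
  expect_identical(toks$text,
                   c("48", "-", "year", "-", "old", "in", "Edwin",
                     "Health", "Care"))
})

test_that("BPE learns the most frequent pair first and is order-invariant", {
  mk <- function(s) split_uppercase(split_char_runs(s))
  corpus <- c(replicate(9, mk("year-old"), simplify = FALSE),
              list(mk("foo-bar")))
  # (year,-) and (-,old) are tied at 9; the lexicographic tie-break picks
  # the pair sorting first
  m <- learn_bpe(corpus, num_merges = 1)
  expect_identical(unname(m$merges[1, ]), c("-", "old"))
  # an untied corpus picks the strictly most frequent pair
  corpus2 <- c(replicate(9, mk("year-old"), simplify = FALSE),
               replicate(3, mk("year-book"), simplify = FALSE),
               list(mk("foo-bar")))
  m2 <- learn_bpe(corpus2, num_merges = 1)
  expect_identical(unname(m2$merges[1, ]), c("year", "-"))
  m0 <- learn_bpe(corpus, num_merges = 0)
  expect_identical(nrow(m0$merges), 0L)
  expect_identical(apply_bpe(corpus[[1]], m0), corpus[[1]])
  shuffled <- corpus[c(10, 3, 1, 7, 5, 2, 9, 4, 8, 6)]
  expect_identical(learn_bpe(corpus, 5)$merges,
                   learn_bpe(shuffled, 5)$merges)
  expect_error(learn_bpe(corpus, -1))
})

test_that("BPE merges take union spans and never cross whitespace", {
  toks <- split_uppercase(split_char_runs("HealthCare x HealthCare"))
  model <- structure(list(merges = rbind(c("Health", "Care"))),
                     class = "bpe_model")
  out <- apply_bpe(toks, model)
  expect_identical(out$text, c("HealthCare", "x", "HealthCare"))
  expect_identical(out$start[1], 0L)
  expect_identical(out$end[1], 10L)
  # "Health Care" with a space stays split even with the same merge
  spaced <- split_uppercase(split_char_runs("Health Care"))
  expect_identical(apply_bpe(spaced, model)$text, c("Health", "Care"))
})

test_that("BPE model round-trips through its merge file", {
  mk <- function(s) split_uppercase(split_char_runs(s))
  corpus <- replicate(5, mk("48-year-old HealthCare"), simplify = FALSE)
  m <- learn_bpe(corpus, 10)
  expect_gt(nrow(m$merges), 0)
  p <- tempfile()
  write_bpe(m, p)
  expect_identical(read_bpe(p)$merges, m$merges)
})

test_that("tokens reconstruct the source text over random strings", {
  set.seed(5)
  alphabet <- c(letters, LETTERS, 0:9, ".", ",", "-", "(", ")", " ", " ",
                "\n", "@", "/")
  for (r in 1:100) {
    txt <- paste(sample(alphabet, sample(1:60, 1), replace = TRUE),
                 collapse = "")
    toks <- tokenize(txt)
    if (nrow(toks) == 0) next
    # every token matches its span; offsets strictly increase
    expect_identical(toks$text,
                     substring(txt, toks$start + 1L, toks$end))
    expect_true(all(diff(toks$start) > 0))
    expect_true(all(toks$end > toks$start))
    expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
    # whitespace gaps only
    gaps <- mapply(function(a, b) substring(txt, a + 1L, b),
                   toks$end[-nrow(toks)], toks$start[-1])
    expect_true(all(grepl("^\\s*$", gaps)))
  }
})

test_that("sentence boundaries split on newline and terminal punctuation", {
  toks <- tokenize("He is well. She is fine.\nNext line")
  sent <- split(toks$text, toks$sentence)
  expect_identical(length(sent), 3L)
  expect_identical(unname(sent[[1]]), c("He", "is", "well", "."))
  expect_identical(unname(sent[[3]]), c("Next", "line"))
})

test_that("PHI alignment error rate counts boundary-in-token entities", {
  txt <- "Dr.Smith saw us"
  doc_bad <- annotated_document("a", txt, phi_entities(3L, 8L, "DOCTOR",
                                                       source_text = txt))
  expect_equal(phi_alignment_error_rate(list(doc_bad)), 0)  # subword aligns
  # a BPE merge that glues ".Smith" back misaligns the entity
  model <- structure(list(merges = rbind(c("Dr", "."), c("Dr.", "Smith"))),
                     class = "bpe_model")
  expect_equal(phi_alignment_error_rate(list(doc_bad), model), 1)
  # counted fixture: 1 misaligned of 200
  docs <- c(replicate(199, tiny_doc(), simplify = FALSE), list(doc_bad))
  # tiny_doc has 2 entities each -> 199*2 + 1 = 399 total, 0 misaligned
  expect_equal(phi_alignment_error_rate(docs), 0)
  docs_mis <- c(replicate(199, doc_bad, simplify = FALSE), list(doc_bad))
  expect_equal(phi_alignment_error_rate(docs_mis, model), 1)
})

test_that("a 1-in-200 misalignment yields rate 0.005", {
  txt <- "Dr.Smith saw us"
  aligned <- annotated_document("a", txt, phi_entities(0L, 8L, "DOCTOR",
                                                       source_text = txt))
  model <- structure(list(merges = rbind(c("Dr", "."), c("Dr.", "Smith"))),
                     class = "bpe_model")
  # under the merge model the full-chunk entity [0,8) still aligns, the
  # inner entity [3,8) does not
  inner <- annotated_document("b", txt, phi_entities(3L, 8L, "DOCTOR",
                                                     source_text = txt))
  docs <- c(replicate(199, aligned, simplify = FALSE), list(inner))
  expect_equal(phi_alignment_error_rate(docs, model), 1 / 200)
})
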