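mk_ent <- function(start, end, category,
                   text = rep(NA_character_, length(start))) {
  data.frame(start = as.integer(start), end = as.integer(end),
             category = category, text = text, stringsAsFactors = FALSE)
}

test_that("candidate pooling merges exact duplicates and keeps overlaps", {
  e <- mk_ent(0, 5, "DATE", "2071m")
  preds <- list(rule = e, crf = e, lexicon = e)
  cands <- collect_candidates(preds)
  expect_equal(nrow(cands), 1)
  expect_identical(cands$sources, "crf,lexicon,rule")
  # disjoint entities from two taggers stay separate
  preds2 <- list(rule = mk_ent(0, 5, "DATE"), crf = mk_ent(10, 14, "AGE"))
  expect_equal(nrow(collect_candidates(preds2)), 2)
  # overlapping non-identical spans are both retained
  preds3 <- list(rule = mk_ent(0, 8, "STATE"), crf = mk_ent(4, 12, "HOSPITAL"))
  cands3 <- collect_candidates(preds3)
  expect_equal(nrow(cands3), 2)
  expect_error(collect_candidates(preds3, registry = "rule"),
               "unregistered")
})

test_that("candidate features encode provenance, overlap and category", {
  reg <- c("rule", "crf", "lexicon")
  cands <- collect_candidates(list(
    rule = mk_ent(c(0, 20), c(10, 24), c("DATE", "AGE")),
    crf = mk_ent(0, 10, "DATE")
  ), reg)
  toks <- space_tokens(c("aaa", "bbbbbb", "cc", "ddd", "eeee"))
  X <- featurize_candidates(cands, reg, toks)
  r1 <- which(cands$start == 0)
  expect_equal(unname(X[r1, c("src_rule", "src_crf", "src_lexicon")]),
               c(1, 1, 0))
  expect_equal(unname(X[r1, "n_overlap"]), 0)
  expect_equal(unname(X[r1, "cat_DATE"]), 1)
  # two candidates sharing 5 of a 10-character span -> fraction 0.5
  ov <- collect_candidates(list(rule = mk_ent(0, 10, "DATE"),
                                crf = mk_ent(5, 15, "DATE")))
  Xo <- featurize_candidates(ov, c("rule", "crf"))
  expect_equal(unname(Xo[, "max_overlap_frac"]), c(0.5, 0.5))
  expect_equal(unname(Xo[, "n_overlap"]), c(1, 1))
})

test_that("selection keeps high scores and resolves overlaps greedily", {
  cands <- collect_candidates(list(
    rule = mk_ent(c(0, 20), c(10, 25), c("DATE", "AGE")),
    crf = mk_ent(5, 15, "DATE")
  ))
  # scores aligned with sorted candidate order: [0,10), [5,15), [20,25)
  sel <- select_phi(cands, c(0.9, 0.4, 0.8), threshold = 0)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$start, c(0L, 20L))
  # everything below threshold -> empty
  expect_equal(nrow(select_phi(cands, c(-1, -2, -0.5), 0)), 0)
  none <- collect_candidates(list(rule = mk_ent(integer(0), integer(0),
                                                character(0))))
  expect_equal(nrow(select_phi(none, numeric(0))), 0)
  # output is always a subset of the candidates
  sel2 <- select_phi(cands, c(0.1, 0.2, 0.3), threshold = 0)
  key <- paste(sel2$start, sel2$end, sel2$category)
  expect_true(all(key %in% paste(cands$start, cands$end, cands$category)))
})

test_that("perfect submodels give an all-positive stacker reproducing gold", {
  docs <- generate_corpus(generator_config(n_docs = 8, seed = 15))
  preps <- prepare_docs(docs, NULL, NULL)
  oracle <- structure(list(
    name = "oracle",
    fit = function(preps) NULL,
    predict = function(fitted, prep) prep$doc$entities
  ), class = "tagger_spec")
  ens <- train_stacker(preps, list(oracle),
                       stacker_config(folds = 2, seed = 1))
  expect_identical(ens$svm$kind, "constant")
  expect_equal(ens$svm$score, 1)
  pred <- lapply(preps, function(p)
    annotated_document(p$doc$doc_id, p$doc$text, predict_ensemble(ens, p)))
  ev <- evaluate_deid(pred, docs)
  expect_equal(ev$f1, 100)
})

test_that("stacking is deterministic given the seed", {
  docs <- generate_corpus(generator_config(n_docs = 12, seed = 33))
  preps <- prepare_docs(docs, NULL, NULL)
  flaky <- structure(list(
    name = "flaky",
    fit = function(preps) NULL,
    predict = function(fitted, prep) {
      e <- prep$doc$entities
      keep <- (prep$doc$doc_id == "synth-0003") |
        seq_len(nrow(e)) %% 2 == 1
      e[keep, , drop = FALSE]
    }
  ), class = "tagger_spec")
  exact <- structure(list(
    name = "exact",
    fit = function(preps) NULL,
    predict = function(fitted, prep) {
      e <- prep$doc$entities
      e[e$category %in% c("DATE", "AGE"), , drop = FALSE]
    }
  ), class = "tagger_spec")
  cfg <- stacker_config(folds = 3, seed = 9)
  e1 <- train_stacker(preps, list(flaky, exact), cfg)
  e2 <- train_stacker(preps, list(flaky, exact), cfg)
  p1 <- lapply(preps, function(p) predict_ensemble(e1, p))
  p2 <- lapply(preps, function(p) predict_ensemble(e2, p))
  expect_identical(p1, p2)
})

test_that("the ensemble never invents spans and outputs are disjoint", {
  docs <- generate_corpus(generator_config(n_docs = 10, seed = 27,
                                           hard = TRUE))
  preps <- prepare_docs(docs, NULL, NULL)
  noisy <- structure(list(
    name = "noisy",
    fit = function(preps) NULL,
    predict = function(fitted, prep) {
      e <- prep$doc$entities
      extra <- mk_ent(e$start[1], e$end[1] + 2L, "DATE")
      rbind(e[, c("start", "end", "category", "text")],
            cbind(extra[, 1:3], text = NA_character_))
    }
  ), class = "tagger_spec")
  exact <- structure(list(
    name = "exact",
    fit = function(preps) NULL,
    predict = function(fitted, prep) prep$doc$entities
  ), class = "tagger_spec")
  ens <- train_stacker(preps, list(noisy, exact),
                       stacker_config(folds = 2, seed = 4))
  for (p in preps) {
    predictions <- lapply(ens$registry, function(nm)
      ens$taggers[[nm]]$predict(ens$fitted[[nm]], p))
    names(predictions) <- ens$registry
    cands <- collect_candidates(predictions, ens$registry)
    out <- predict_ensemble(ens, p)
    if (nrow(out) > 1) {
      expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
    }
    expect_true(all(paste(out$start, out$end, out$category) %in%
                      paste(cands$start, cands$end, cands$category)))
  }
})
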