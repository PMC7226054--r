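# small hand-built state: tokens/features/init/gold fully under control
mini_state <- function(words, init, gold) {
  txt <- paste(words, collapse = " ")
  toks <- space_tokens(words)
  ftab <- feature_table(txt, toks, heuristic_pos_ner)
  tbed_state(list(ftab), list(init), list(gold))
}

test_that("candidate generation binds conditions at error positions", {
  templates <- default_templates()
  st <- mini_state(c("go", "to", "Mercy", "Hospital", "now"),
                   init = c("O", "O", "O", "O", "O"),
                   gold = c("O", "O", "B(HOSPITAL)", "I(HOSPITAL)", "O"))
  cands <- generate_candidates(st, templates)
  expect_gt(length(cands), 0)
  strs <- vapply(cands, rule_string, character(1))
  expect_true("IF token@0='Hospital' THEN O->I(HOSPITAL)" %in% strs)
  expect_false(any(duplicated(strs)))
  # zero errors -> no candidates
  st0 <- mini_state(c("a", "b"), c("O", "O"), c("O", "O"))
  expect_length(generate_candidates(st0, templates), 0)
  # one error, k templates -> at most k distinct rules
  st1 <- mini_state(c("a", "b"), c("O", "O"), c("B(AGE)", "O"))
  expect_lte(length(generate_candidates(st1, templates)), length(templates))
})

test_that("duplicate error contexts collapse to one candidate", {
  st <- mini_state(c("Hospital", "x", "Hospital", "y", "Hospital", "z"),
                   init = rep("O", 6),
                   gold = c("I(HOSPITAL)", "O", "I(HOSPITAL)", "O",
                            "I(HOSPITAL)", "O"))
  tmpl <- read_templates(textConnection("token@0"))
  cands <- generate_candidates(st, tmpl)
  expect_length(cands, 1)
})

test_that("rule scoring counts fixed and broken sites exactly", {
  # rule token@0='x': fixes 3 errors, breaks 1 correct tag
  st <- mini_state(c("x", "x", "x", "x", "q"),
                   init = c("O", "O", "O", "B(AGE)", "O"),
                   gold = c("B(AGE)", "B(AGE)", "B(AGE)", "B(AGE)", "O"))
  tmpl <- read_templates(textConnection("token@0"))[[1]]
  rule <- deidr:::new_rule(tmpl, "x", "O", "B(AGE)")
  sc <- score_rule(rule, st)
  expect_identical(sc$fixed, 3L)
  expect_identical(sc$broken, 0L)
  expect_identical(sc$score, 3L)
  # now a rule that also breaks: gold O at a firing site
  st2 <- mini_state(c("x", "x", "x", "x"),
                    init = c("O", "O", "O", "O"),
                    gold = c("B(AGE)", "B(AGE)", "B(AGE)", "O"))
  sc2 <- score_rule(rule, st2)
  expect_identical(sc2$fixed, 3L)
  expect_identical(sc2$broken, 1L)
  expect_identical(sc2$score, 2L)
  # a rule matching nowhere scores zero
  inert <- deidr:::new_rule(tmpl, "zzz", "O", "B(AGE)")
  expect_identical(score_rule(inert, st2)$score, 0L)
  # a rule wrong everywhere it fires scores negative
  wrong <- deidr:::new_rule(tmpl, "x", "O", "B(ZIP)")
  expect_lt(score_rule(wrong, st2)$score, 0)
})

test_that("rule application is simultaneous and reduces error by the score", {
  st <- mini_state(c("x", "x", "x", "x"),
                   init = c("O", "O", "O", "O"),
                   gold = c("B(AGE)", "B(AGE)", "B(AGE)", "O"))
  tmpl <- read_templates(textConnection("token@0"))[[1]]
  rule <- deidr:::new_rule(tmpl, "x", "O", "B(AGE)")
  before <- sum(st$current != st$gold)
  sc <- score_rule(rule, st)
  st2 <- apply_rule(rule, st)
  expect_identical(sum(st2$current != st2$gold), before - sc$score)
  # reapplying is a no-op: the from-tag is gone at all firing sites
  st3 <- apply_rule(rule, st2)
  expect_identical(st3$current, st2$current)
  # a rule matching nowhere leaves the state unchanged
  inert <- deidr:::new_rule(tmpl, "zzz", "O", "B(AGE)")
  expect_identical(apply_rule(inert, st)$current, st$current)
})

test_that("tag-conditioned rules see pre-application tags", {
  # rule: tag@-1='O': O->B(AGE) on tags (O,O,O). Under simultaneous
  # application positions 2 and 3 both qualify against the original tags;
  # left-to-right cascading would block position 3 after rewriting 2.
  tmpl <- read_templates(textConnection("tag@-1"))[[1]]
  st <- mini_state(c("x", "x", "x"), c("O", "O", "O"),
                   c("O", "B(AGE)", "B(AGE)"))
  rule <- deidr:::new_rule(tmpl, "O", "O", "B(AGE)")
  st2 <- apply_rule(rule, st)
  expect_identical(st2$current, c("O", "B(AGE)", "B(AGE)"))
})

test_that("training recovers a planted corruption and is monotone", {
  docs <- generate_corpus(generator_config(n_docs = 10, seed = 7))
  pc <- plant_rule_corpus(docs, list(
    list(feature = "token", offset = 0L, value = "Hospital",
         from = "I(HOSPITAL)", to = "O")
  ))
  expect_gt(pc$site_counts[1], 0)
  st <- tbed_state(pc$features, pc$init_tags, pc$gold_tags)
  fit <- train_tbed(st)
  expect_identical(utils::tail(fit$trace$errors, 1), 0L)
  expect_lte(nrow(fit$trace), 1L)
  expect_identical(fit$trace$score[1], pc$site_counts[1])
  expect_identical(fit$rules[[1]]$to, "I(HOSPITAL)")
  # already-perfect init -> empty rule list
  st0 <- tbed_state(pc$features, pc$gold_tags, pc$gold_tags)
  expect_length(train_tbed(st0)$rules, 0)
})

test_that("per-iteration error drops by exactly the selected score", {
  docs <- generate_corpus(generator_config(n_docs = 12, seed = 13))
  pats <- load_patterns()
  tokens <- lapply(docs, function(d) tokenize(d$text))
  feats <- mapply(function(d, tt) feature_table(d$text, tt,
                                                heuristic_pos_ner),
                  docs, tokens, SIMPLIFY = FALSE)
  init <- mapply(function(d, tt) annotate_initial(d$text, tt, pats),
                 docs, tokens, SIMPLIFY = FALSE)
  gold <- mapply(function(d, tt) encode_iob(tt, d$entities),
                 docs, tokens, SIMPLIFY = FALSE)
  st <- tbed_state(feats, init, gold)
  err0 <- sum(st$current != st$gold)
  fit <- train_tbed(st, max_iters = 25)
  tr <- fit$trace
  expect_true(all(diff(c(err0, tr$errors)) == -tr$score))
  expect_true(all(diff(tr$errors) < 0))
  expect_true(all(tr$score >= 1))
  # re-tagging the training corpus reproduces the final error count
  retagged <- mapply(function(d, tt, ft)
    tag_tbed(d$text, tt, ft, pats, fit), docs, tokens, feats,
    SIMPLIFY = FALSE)
  err_final <- sum(unlist(retagged) != unlist(gold))
  expect_identical(err_final, utils::tail(tr$errors, 1))
})

test_that("selected rules match the exhaustive oracle on random corpora", {
  set.seed(17)
  templates <- default_templates()[c(1, 2, 8, 9)]
  cats <- c("O", "B(AGE)", "I(AGE)", "B(DATE)")
  for (rep in 1:12) {
    n <- sample(8:20, 1)
    words <- sample(c("on", "age", "43", "2071", "x", "y"), n, replace = TRUE)
    gold <- sample(cats, n, replace = TRUE)
    init <- gold
    flip <- sample(n, sample(2:4, 1))
    init[flip] <- sample(cats, length(flip), replace = TRUE)
    st <- mini_state(words, init, gold)
    if (all(st$current == st$gold)) next
    oracle_best <- tbed_oracle_best(st, templates)
    fit <- train_tbed(st, templates, max_iters = 1)
    if (is.null(oracle_best) || oracle_best < 1) {
      expect_length(fit$rules, 0)
    } else {
      expect_identical(fit$trace$score[1], as.integer(oracle_best))
    }
  }
})

test_that("rule files round-trip through their text serialization", {
  docs <- generate_corpus(generator_config(n_docs = 10, seed = 7))
  pc <- plant_rule_corpus(docs, list(
    list(feature = "token", offset = 0L, value = "Hospital",
         from = "I(HOSPITAL)", to = "O"),
    list(feature = "token", offset = 0L, value = "Street",
         from = "I(STREET)", to = "O")
  ))
  st <- tbed_state(pc$features, pc$init_tags, pc$gold_tags)
  fit <- train_tbed(st)
  p <- tempfile()
  write_rules(fit, p)
  back <- read_rules(p)
  expect_identical(length(back$rules), length(fit$rules))
  for (i in seq_along(fit$rules)) {
    expect_identical(rule_string(back$rules[[i]]),
                     rule_string(fit$rules[[i]]))
    expect_identical(back$rules[[i]]$score, fit$rules[[i]]$score)
  }
  # quoted values survive
  tmpl <- read_templates(textConnection("token@0"))[[1]]
  q <- deidr:::new_rule(tmpl, "O'Neil", "O", "B(PATIENT)")
  p2 <- tempfile()
  write_rules(list(q), p2)
  expect_identical(read_rules(p2)$rules[[1]]$values, "O'Neil")
})
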