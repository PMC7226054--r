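#' End-to-end pipeline configuration
#'
#' One configuration object drives training, tagging, evaluation and
#' ablation; every random draw (fold assignment, synthetic data) flows from
#' the single `seed`, so re-running with the same seed reproduces every
#' artifact and number exactly. The learning-rate/regularization and SVM
#' defaults follow the published hyper-parameter table.
#'
#' @param patterns_file initial-annotator pattern file.
#' @param templates_file transformation-rule template file.
#' @param crosses_file feature-cross specification file.
#' @param num_merges BPE merges learned from the training corpus.
#' @param tbed_max_iters,tbed_min_score transformation-learner controls.
#' @param crf_lr,crf_l2,crf_epochs CRF training controls.
#' @param c_pos,c_neg,gamma,folds,threshold stacking-classifier controls.
#' @param taggers which submodels to register: subset of
#'   `c("rule", "crf", "lexicon")`.
#' @param seed root random seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(patterns_file = default_patterns_file(),
                            templates_file = system.file(
                              "extdata", "templates_default.txt",
                              package = "deidr", mustWork = TRUE),
                            crosses_file = system.file(
                              "extdata", "crosses_default.txt",
                              package = "deidr", mustWork = TRUE),
                            num_merges = 1000L,
                            tbed_max_iters = 200L, tbed_min_score = 1L,
                            crf_lr = 0.0005, crf_l2 = 0.0003,
                            crf_epochs = 100L,
                            c_pos = 5.2, c_neg = 12.48, gamma = 0.009,
                            folds = 5L, threshold = 0,
                            taggers = c("rule", "crf", "lexicon"),
                            seed = 1L) {
  for (f in c(patterns_file, templates_file, crosses_file)) {
    if (!file.exists(f)) stop("config file does not exist: ", f,
                              call. = FALSE)
  }
  taggers <- match.arg(taggers, c("rule", "crf", "lexicon"),
                       several.ok = TRUE)
  structure(list(
    patterns_file = patterns_file, templates_file = templates_file,
    crosses_file = crosses_file, num_merges = as.integer(num_merges),
    tbed_max_iters = as.integer(tbed_max_iters),
    tbed_min_score = as.integer(tbed_min_score),
    crf_lr = crf_lr, crf_l2 = crf_l2, crf_epochs = as.integer(crf_epochs),
    c_pos = c_pos, c_neg = c_neg, gamma = gamma, folds = as.integer(folds),
    threshold = threshold, taggers = taggers, seed = as.integer(seed)
  ), class = "pipeline_config")
}

build_taggers <- function(config, patterns, templates) {
  specs <- list(
    rule = function() rule_tagger_spec(patterns, templates,
                                       config$tbed_max_iters,
                                       config$tbed_min_score),
    crf = function() crf_tagger_spec(config$crf_lr, config$crf_l2,
                                     config$crf_epochs),
    lexicon = function() lexicon_tagger_spec()
  )
  lapply(config$taggers, function(nm) specs[[nm]]())
}

#' Train the full hybrid de-identification model
#'
#' Learns the BPE tokenizer on the training notes, prepares feature
#' tables, trains the registered submodels (rule learner, CRF, optional
#' gazetteer) and the stacked-generalization ensemble with out-of-fold
#' labels.
#'
#' @param docs training [annotated_document()]s.
#' @param config a [pipeline_config()].
#' @return a `deid_model`: BPE model, cross spec, ensemble, configuration.
#' @export
deid_train <- function(docs, config = pipeline_config()) {
  set.seed(config$seed)
  toks12 <- lapply(docs, function(d)
    split_uppercase(split_char_runs(d$text)))
  bpe <- learn_bpe(toks12, config$num_merges)
  cross_spec <- read_cross_spec(config$crosses_file)
  patterns <- load_patterns(config$patterns_file)
  templates <- read_templates(config$templates_file)
  preps <- prepare_docs(docs, bpe, cross_spec, heuristic_pos_ner)
  taggers <- build_taggers(config, patterns, templates)
  ensemble <- train_stacker(preps, taggers, stacker_config(
    c_pos = config$c_pos, c_neg = config$c_neg, gamma = config$gamma,
    threshold = config$threshold, folds = config$folds, seed = config$seed
  ))
  structure(list(bpe = bpe, cross_spec = cross_spec,
                 ensemble = ensemble, config = config),
            class = "deid_model")
}

#' @export
print.deid_model <- function(x, ...) {
  cat(sprintf("<deid_model: %d BPE merges, submodels [%s]>\n",
              nrow(x$bpe$merges),
              paste(x$ensemble$registry, collapse = ", ")))
  invisible(x)
}

#' Tag documents with a trained model
#'
#' @param model a `deid_model` from [deid_train()].
#' @param docs documents to tag (gold entities, if present, are ignored).
#' @param submodel `NULL` for the full ensemble, or one registered tagger
#'   name to obtain that submodel's predictions alone.
#' @return a list of [annotated_document()]s carrying predicted entities.
#' @export
deid_tag <- function(model, docs, submodel = NULL) {
  stripped <- lapply(docs, function(d)
    annotated_document(d$doc_id, d$text, validate = FALSE))
  preps <- prepare_docs(stripped, model$bpe, model$cross_spec,
                        heuristic_pos_ner)
  ens <- model$ensemble
  lapply(preps, function(p) {
    ent <- if (is.null(submodel)) {
      predict_ensemble(ens, p)
    } else {
      if (!submodel %in% ens$registry) {
        stop("no such submodel: ", submodel, call. = FALSE)
      }
      ens$taggers[[submodel]]$predict(ens$fitted[[submodel]], p)
    }
    annotated_document(p$doc$doc_id, p$doc$text, ent)
  })
}

#' Ablation: retrain the ensemble without one submodel
#'
#' Rebuilds the stacking ensemble with the named submodel removed
#' (submodels and stacker retrained under the same seed) and reports the
#' strict-F1 delta on the test documents relative to the full model.
#'
#' @param model the full trained `deid_model`.
#' @param train_docs,test_docs annotated training and test documents.
#' @param without the registered tagger name to remove.
#' @return a list with `f1_full`, `f1_without` and `delta` (percentage
#'   points, negative when removal hurts).
#' @export
deid_ablate <- function(model, train_docs, test_docs, without) {
  config <- model$config
  if (!without %in% config$taggers) {
    stop("submodel '", without, "' is not registered", call. = FALSE)
  }
  reduced_cfg <- config
  reduced_cfg$taggers <- setdiff(config$taggers, without)
  if (!length(reduced_cfg$taggers)) {
    stop("cannot remove the only submodel", call. = FALSE)
  }
  reduced <- deid_train(train_docs, reduced_cfg)
  full_eval <- evaluate_deid(deid_tag(model, test_docs), test_docs)
  red_eval <- evaluate_deid(deid_tag(reduced, test_docs), test_docs)
  list(f1_full = full_eval$f1, f1_without = red_eval$f1,
       delta = red_eval$f1 - full_eval$f1)
}

#' Persist and restore trained pipeline artifacts
#'
#' Text artifacts (learned rule list, CRF container, BPE merges) are
#' written in their human-readable formats; the stacking classifier and
#' registry go into an RDS container. Re-running training with the same
#' seed reproduces these files byte-identically.
#'
#' @param model a `deid_model`.
#' @param dir output directory (created if needed).
#' @export
deid_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fitted <- model$ensemble$fitted
  if ("rule" %in% model$ensemble$registry) {
    write_rules(fitted[["rule"]]$rules, file.path(dir, "rules.txt"))
  }
  if ("crf" %in% model$ensemble$registry) {
    write_crf(fitted[["crf"]], file.path(dir, "crf.json"))
  }
  write_bpe(model$bpe, file.path(dir, "bpe_merges.txt"))
  saveRDS(model, file.path(dir, "deid_model.rds"))
  invisible(dir)
}

#' @rdname deid_save
#' @export
deid_load <- function(dir) {
  path <- file.path(dir, "deid_model.rds")
  if (!file.exists(path)) {
    stop("no trained model artifacts in ", dir,
         "; run deid_train()/deid_save() first", call. = FALSE)
  }
  readRDS(path)
}

#' The hard-mode synthetic benchmark
#'
#' A fixed-construction benchmark with complementary submodel strengths:
#' hard-mode synthetic notes (number/date confusions, multi-token states)
#' split into training and test sets. Used by the package's own evaluation
#' and by the ablation demonstration.
#'
#' @param n_train,n_test document counts.
#' @param seed generator seed.
#' @return a list with `train` and `test` document lists.
#' @export
benchmark_corpus <- function(n_train = 100L, n_test = 50L, seed = 20L) {
  docs <- generate_corpus(generator_config(
    n_docs = n_train + n_test, hard = TRUE, seed = seed
  ))
  list(train = docs[seq_len(n_train)],
       test = docs[n_train + seq_len(n_test)])
}
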