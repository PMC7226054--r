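# Stacked-generalization ensemble. Submodel predictions are pooled into
# PHI candidates (exact duplicates merge, overlapping spans are all kept),
# each candidate is featurized by its provenance (which taggers proposed
# it), its overlap with other candidates, its category and its length, and
# a binary RBF-kernel SVM scores the candidates; the final PHI set is the
# high-scoring, non-overlapping subset. Stacking labels are built
# out-of-fold so the meta-classifier never sees optimistic in-sample
# submodel output.

#' Prepare documents for training and tagging
#'
#' Tokenizes each document, computes its feature table and CRF observation
#' features once, and caches gold IOB tags (misaligned gold entities are
#' skipped with a warning — they cannot be represented at token level).
#'
#' @param docs a list of [annotated_document()]s.
#' @param bpe optional `bpe_model` used in tokenization.
#' @param cross_spec feature-cross specification for the CRF.
#' @param tagger external POS/NER tagger plug-in.
#' @return a list of prepared bundles (`doc`, `tokens`, `ftab`, `obs`,
#'   `gold_tags`).
#' @export
prepare_docs <- function(docs, bpe = NULL, cross_spec = default_cross_spec(),
                         tagger = heuristic_pos_ner) {
  lapply(docs, function(d) {
    toks <- tokenize(d$text, bpe)
    ftab <- feature_table(d$text, toks, tagger)
    gold <- suppressWarnings(encode_iob(toks, d$entities,
                                        on_misaligned = "skip"))
    list(doc = d, tokens = toks, ftab = ftab,
         obs = crf_observations(ftab, cross_spec),
         gold_tags = gold)
  })
}

#' Submodel tagger specifications
#'
#' A tagger spec is the unit the ensemble registers: a `name`, a
#' `fit(preps)` function returning a fitted object, and a
#' `predict(fitted, prep)` function returning a [phi_entities()] table.
#' Any object honoring this contract can be registered as a third
#' submodel.
#'
#' `rule_tagger_spec()` wraps the regex initial annotator plus the
#' transformation-rule learner; `crf_tagger_spec()` wraps the linear-chain
#' CRF; `lexicon_tagger_spec()` is a simple memorizing gazetteer (exact
#' surface matches of training PHI, highest-precision and lowest-recall of
#' the three) useful as a demonstration third submodel.
#'
#' @param patterns initial-annotator patterns ([load_patterns()]).
#' @param templates rule templates ([default_templates()]).
#' @param max_iters,min_score transformation-learner stopping controls.
#' @return a `tagger_spec` list.
#' @export
rule_tagger_spec <- function(patterns = load_patterns(),
                             templates = default_templates(),
                             max_iters = 200L, min_score = 1L) {
  structure(list(
    name = "rule",
    fit = function(preps) {
      init <- lapply(preps, function(p)
        annotate_initial(p$doc$text, p$tokens, patterns))
      st <- tbed_state(lapply(preps, `[[`, "ftab"), init,
                       lapply(preps, `[[`, "gold_tags"))
      fit <- train_tbed(st, templates, max_iters = max_iters,
                        min_score = min_score)
      list(patterns = patterns, rules = fit)
    },
    predict = function(fitted, prep) {
      tags <- tag_tbed(prep$doc$text, prep$tokens, prep$ftab,
                       fitted$patterns, fitted$rules)
      decode_iob(prep$tokens, tags, prep$doc$text)
    }
  ), class = "tagger_spec")
}

#' @rdname rule_tagger_spec
#' @param lr,l2,epochs CRF training controls (see [train_crf()]).
#' @export
crf_tagger_spec <- function(lr = 0.0005, l2 = 0.0003, epochs = 100L) {
  structure(list(
    name = "crf",
    fit = function(preps) {
      data <- lapply(preps, function(p) list(obs = p$obs, tags = p$gold_tags))
      train_crf(data, lr = lr, l2 = l2, epochs = epochs)
    },
    predict = function(fitted, prep) {
      tags <- crf_decode(fitted, prep$obs)
      decode_iob(prep$tokens, tags, prep$doc$text)
    }
  ), class = "tagger_spec")
}

#' @rdname rule_tagger_spec
#' @export
lexicon_tagger_spec <- function() {
  structure(list(
    name = "lexicon",
    fit = function(preps) {
      ent <- do.call(rbind, lapply(preps, function(p) p$doc$entities))
      ent <- ent[grepl("^[A-Za-z]", ent$text) & nchar(ent$text) >= 4, ,
                 drop = FALSE]
      unique(ent[, c("text", "category")])
    },
    predict = function(fitted, prep) {
      text <- prep$doc$text
      starts <- integer(0); ends <- integer(0); cats <- character(0)
      if (nrow(fitted)) {
        ord <- order(-nchar(fitted$text))
        taken <- rep(FALSE, nchar(text))
        for (i in ord) {
          pat <- paste0("(?<![A-Za-z0-9])",
                        gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                             fitted$text[i]),
                        "(?![A-Za-z0-9])")
          m <- gregexpr(pat, text, perl = TRUE)[[1]]
          if (m[1] == -1) next
          len <- attr(m, "match.length")
          for (k in seq_along(m)) {
            s <- as.integer(m[k]) - 1L
            e <- s + len[k]
            if (any(taken[(s + 1):e])) next
            taken[(s + 1):e] <- TRUE
            starts <- c(starts, s); ends <- c(ends, e)
            cats <- c(cats, fitted$category[i])
          }
        }
      }
      phi_entities(starts, ends, cats, source_text = text)
    }
  ), class = "tagger_spec")
}

#' Pool submodel predictions into PHI candidates
#'
#' Exact-duplicate entities (same start, end and category) proposed by
#' several taggers collapse into one candidate with the union of sources;
#' overlapping but non-identical spans are all retained — arbitrating
#' between them is the stacker's job.
#'
#' @param predictions a named list (one element per registered tagger) of
#'   [phi_entities()] tables.
#' @param registry character vector of registered tagger names.
#' @return a data.frame of candidates with columns `start`, `end`,
#'   `category`, `text` and `sources` (comma-joined tagger names).
#' @export
collect_candidates <- function(predictions, registry = names(predictions)) {
  bad <- setdiff(names(predictions), registry)
  if (length(bad)) {
    stop("unregistered tagger name: ", bad[1], call. = FALSE)
  }
  rows <- list()
  for (nm in names(predictions)) {
    e <- predictions[[nm]]
    if (NROW(e) == 0) next
    e$source <- nm
    rows[[length(rows) + 1]] <- e
  }
  if (!length(rows)) {
    out <- empty_entities()
    out$sources <- character(0)
    return(out)
  }
  all <- do.call(rbind, rows)
  key <- paste(all$start, all$end, all$category)
  agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    src <- sort(unique(all$source[idx]), method = "radix")
    data.frame(start = all$start[idx[1]], end = all$end[idx[1]],
               category = all$category[idx[1]], text = all$text[idx[1]],
               sources = paste(src, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$start, out$end, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Featurize stacking candidates
#'
#' One indicator per registered tagger (who proposed this span), the count
#' of other candidates overlapping it and the maximum character-overlap
#' fraction, a one-hot encoding of the category, and the candidate length
#' in tokens.
#'
#' @param cands a candidate table from [collect_candidates()].
#' @param registry registered tagger names (fixed order).
#' @param tokens the document's token table (for length in tokens).
#' @return a numeric matrix with one row per candidate.
#' @export
featurize_candidates <- function(cands, registry, tokens = NULL) {
  n <- nrow(cands)
  cats <- phi_categories()
  cn <- c(paste0("src_", registry), "n_overlap", "max_overlap_frac",
          paste0("cat_", cats), "tok_len")
  X <- matrix(0, n, length(cn), dimnames = list(NULL, cn))
  if (n == 0) return(X)
  srcs <- strsplit(cands$sources, ",", fixed = TRUE)
  for (j in seq_along(registry)) {
    X[, j] <- vapply(srcs, function(s) registry[j] %in% s, logical(1))
  }
  for (i in seq_len(n)) {
    ov_len <- pmax(0, pmin(cands$end[i], cands$end[-i]) -
                      pmax(cands$start[i], cands$start[-i]))
    X[i, "n_overlap"] <- sum(ov_len > 0)
    X[i, "max_overlap_frac"] <- if (n > 1) {
      max(ov_len) / (cands$end[i] - cands$start[i])
    } else 0
    X[i, paste0("cat_", cands$category[i])] <- 1
    X[i, "tok_len"] <- if (!is.null(tokens)) {
      sum(tokens$start >= cands$start[i] & tokens$end <= cands$end[i])
    } else 1
  }
  X
}

#' Configuration of the stacking classifier
#'
#' RBF-kernel binary SVM with per-class misclassification weights; the
#' defaults follow the published hyper-parameter table (positive-class
#' C 5.2, negative-class C 12.48, kernel width gamma 0.009). The decision
#' threshold defaults to the classifier's native boundary (decision value
#' 0), and stacking training data is constructed out-of-fold (default 5
#' folds, submodels retrained per fold).
#'
#' @param c_pos,c_neg per-class misclassification weights.
#' @param gamma RBF kernel width.
#' @param threshold decision threshold on the SVM decision value.
#' @param folds number of folds for out-of-fold label construction.
#' @param seed seed for the fold assignment.
#' @return a `stacker_config` list.
#' @export
stacker_config <- function(c_pos = 5.2, c_neg = 12.48, gamma = 0.009,
                           threshold = 0, folds = 5L, seed = 1L) {
  stopifnot(c_pos > 0, c_neg > 0, gamma > 0, folds >= 2)
  structure(list(c_pos = c_pos, c_neg = c_neg, gamma = gamma,
                 threshold = threshold, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "stacker_config")
}

#' Train the stacked-generalization ensemble
#'
#' Documents are split into folds; each submodel is retrained on the
#' out-of-fold documents and predicts the held-out fold, so stacking
#' labels (positive iff a candidate strictly matches a gold entity) are
#' honest. The pooled candidates train the kernel classifier; the final
#' submodels are then refit on all documents.
#'
#' @param preps prepared documents from [prepare_docs()].
#' @param taggers a list of `tagger_spec`s (see [rule_tagger_spec()]).
#' @param config a [stacker_config()].
#' @return an `ensemble_model`: fitted submodels, registry, the stacking
#'   classifier and the configuration.
#' @export
train_stacker <- function(preps, taggers, config = stacker_config()) {
  registry <- vapply(taggers, `[[`, character(1), "name")
  names(taggers) <- registry
  n <- length(preps)
  set.seed(config$seed)
  fold <- sample(rep(seq_len(config$folds), length.out = n))
  X <- list(); y <- logical(0)
  for (f in seq_len(config$folds)) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    if (!length(train_idx) || !length(test_idx)) next
    fitted <- lapply(taggers, function(tg) tg$fit(preps[train_idx]))
    fold_cands <- 0L
    for (i in test_idx) {
      predictions <- lapply(registry, function(nm)
        taggers[[nm]]$predict(fitted[[nm]], preps[[i]]))
      names(predictions) <- registry
      cands <- collect_candidates(predictions, registry)
      if (nrow(cands) == 0) next
      fold_cands <- fold_cands + nrow(cands)
      gk <- paste(preps[[i]]$doc$entities$start, preps[[i]]$doc$entities$end,
                  preps[[i]]$doc$entities$category)
      lab <- paste(cands$start, cands$end, cands$category) %in% gk
      X[[length(X) + 1]] <- featurize_candidates(cands, registry,
                                                 preps[[i]]$tokens)
      y <- c(y, lab)
    }
    if (fold_cands == 0) {
      stop("fold ", f, " produced zero candidates; use more training data",
           call. = FALSE)
    }
  }
  X <- do.call(rbind, X)
  fitted_all <- lapply(taggers, function(tg) tg$fit(preps))
  svm_fit <- fit_candidate_svm(X, y, config)
  structure(list(
    taggers = taggers, fitted = fitted_all, registry = registry,
    svm = svm_fit, config = config
  ), class = "ensemble_model")
}

# binary SVM over candidate features; degenerate single-class training
# data yields a constant scorer
fit_candidate_svm <- function(X, y, config) {
  if (all(y) || !any(y)) {
    return(list(kind = "constant", score = if (all(y)) 1 else -1))
  }
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  m <- e1071::svm(
    x = X, y = yf, kernel = "radial", gamma = config$gamma, cost = 1,
    class.weights = c(neg = config$c_neg, pos = config$c_pos),
    scale = FALSE
  )
  list(kind = "svm", model = m)
}

# signed decision values, positive toward the "pos" class
candidate_scores <- function(svm_fit, X) {
  if (nrow(X) == 0) return(numeric(0))
  if (svm_fit$kind == "constant") return(rep(svm_fit$score, nrow(X)))
  pr <- predict(svm_fit$model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  v <- as.numeric(dv[, 1])
  if (colnames(dv)[1] == "neg/pos") v <- -v
  v
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: submodels [%s], %s stacker>\n",
              paste(x$registry, collapse = ", "), x$svm$kind))
  invisible(x)
}

#' Select the final PHI set from scored candidates
#'
#' Candidates scoring above the threshold are kept, then remaining overlaps
#' are resolved greedily by descending score (a candidate overlapping an
#' already-kept span is dropped). The output is therefore always a sorted,
#' non-overlapping subset of the candidate set — the ensemble never invents
#' spans.
#'
#' @param cands a candidate table from [collect_candidates()].
#' @param scores numeric stacking scores, one per candidate.
#' @param threshold decision threshold (default 0).
#' @param text the raw document text (for entity surfaces).
#' @return a [phi_entities()] table.
#' @export
select_phi <- function(cands, scores, threshold = 0, text = NULL) {
  keep <- which(scores > threshold)
  if (!length(keep)) return(empty_entities())
  keep <- keep[order(-scores[keep], cands$start[keep], cands$end[keep])]
  sel <- integer(0)
  for (i in keep) {
    clash <- any(cands$start[i] < cands$end[sel] &
                   cands$end[i] > cands$start[sel])
    if (!clash) sel <- c(sel, i)
  }
  sel <- sel[order(cands$start[sel])]
  phi_entities(cands$start[sel], cands$end[sel], cands$category[sel],
               text = cands$text[sel], source_text = text)
}

#' Tag a document with a trained ensemble
#'
#' Runs every registered submodel, pools and featurizes the candidates,
#' scores them with the stacking classifier, and returns the selected
#' non-overlapping PHI set.
#'
#' @param model an `ensemble_model` from [train_stacker()].
#' @param prep a prepared document bundle from [prepare_docs()].
#' @return a [phi_entities()] table.
#' @export
predict_ensemble <- function(model, prep) {
  predictions <- lapply(model$registry, function(nm)
    model$taggers[[nm]]$predict(model$fitted[[nm]], prep))
  names(predictions) <- model$registry
  cands <- collect_candidates(predictions, model$registry)
  if (nrow(cands) == 0) return(empty_entities())
  X <- featurize_candidates(cands, model$registry, prep$tokens)
  scores <- candidate_scores(model$svm, X)
  select_phi(cands, scores, model$config$threshold, prep$doc$text)
}
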