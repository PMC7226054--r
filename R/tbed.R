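# Transformation-based error-driven learning (Brill-style rule induction).
#
# Starting from the initial annotator's tagging, the learner repeatedly
# (1) generates, at every still-mistagged position, candidate rules that
# rewrite the current tag to the gold tag conditional on feature values
# drawn from a template inventory, (2) scores every candidate by its net
# benefit s(r) = errors fixed - correct tags broken over the whole corpus,
# and (3) greedily applies the best rule and appends it to an ordered list.
# Rules are applied simultaneously (conditions are evaluated against the
# pre-application tags), so the corpus error count drops by exactly the
# selected rule's score at every iteration.

SEP <- "\x1f"

#' Rule templates for the transformation learner
#'
#' A template is a set of 1-3 condition slots, each a `(feature, offset)`
#' pair with offsets in -2..2. `"tag"` refers to the evolving tag sequence
#' itself; any other name refers to a column of the feature table (which is
#' computed once from the text and never changes during learning). The
#' default inventory lives in `templates_default.txt` and includes the
#' classic "current token" / "previous tag" / "length of previous token"
#' perspectives.
#'
#' @param path a template file: one template per line, comma-separated
#'   `feature@offset` conditions, `#` comments.
#' @return a list of templates, each `list(conds = data.frame(feature,
#'   offset), arity, name)`.
#' @export
read_templates <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    terms <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    parts <- regmatches(terms,
                        regexec("^([A-Za-z0-9_@|]+)@([+-]?[0-9]+)$", terms))
    bad <- which(lengths(parts) != 3)
    if (length(bad)) {
      stop("malformed template condition '", terms[bad[1]], "'",
           call. = FALSE)
    }
    conds <- data.frame(
      feature = vapply(parts, `[`, character(1), 2),
      offset = as.integer(vapply(parts, `[`, character(1), 3)),
      stringsAsFactors = FALSE
    )
    if (any(abs(conds$offset) > 2)) {
      stop("template offsets must lie in -2..2: '", ln, "'", call. = FALSE)
    }
    if (nrow(conds) < 1 || nrow(conds) > 3) {
      stop("template arity must be 1-3: '", ln, "'", call. = FALSE)
    }
    list(conds = conds, arity = nrow(conds),
         name = paste(sprintf("%s@%d", conds$feature, conds$offset),
                      collapse = ","))
  })
}

#' @rdname read_templates
#' @export
default_templates <- function() {
  read_templates(system.file("extdata", "templates_default.txt",
                             package = "deidr", mustWork = TRUE))
}

#' Training state for the transformation learner
#'
#' Bundles the per-document feature tables with the current and gold tag
#' sequences, flattened over the corpus (document boundaries are kept so
#' window offsets never cross documents).
#'
#' @param features a list of feature tables (one per document, from
#'   [feature_table()], optionally with crosses).
#' @param init_tags a list of initial IOB tag vectors (one per document,
#'   e.g. from [annotate_initial()]).
#' @param gold_tags a list of gold IOB tag vectors (from [encode_iob()]).
#' @return an object of class `tbed_state`.
#' @export
tbed_state <- function(features, init_tags, gold_tags) {
  stopifnot(length(features) == length(init_tags),
            length(features) == length(gold_tags))
  for (d in seq_along(features)) {
    if (nrow(features[[d]]) != length(init_tags[[d]]) ||
        nrow(features[[d]]) != length(gold_tags[[d]])) {
      stop("document ", d, ": features/init/gold lengths differ",
           call. = FALSE)
    }
  }
  lens <- vapply(features, nrow, integer(1))
  feats <- do.call(rbind, features)
  rownames(feats) <- NULL
  structure(list(
    features = feats,
    doc = rep(seq_along(features), lens),
    doc_idx = split(seq_len(sum(lens)), rep(seq_along(features), lens)),
    current = unlist(init_tags, use.names = FALSE),
    gold = unlist(gold_tags, use.names = FALSE),
    k = 0L
  ), class = "tbed_state")
}

#' @export
print.tbed_state <- function(x, ...) {
  cat(sprintf("<tbed_state: %d docs, %d tokens, %d errors, iteration %d>\n",
              length(x$doc_idx), length(x$current),
              sum(x$current != x$gold), x$k))
  invisible(x)
}

# per-document shift of a global vector (sentinels at doc boundaries)
shift_by_doc <- function(values, doc_idx, off) {
  v <- as.character(values)
  if (off == 0) return(v)
  out <- character(length(v))
  for (idx in doc_idx) {
    out[idx] <- shift_feature(v[idx], off)
  }
  out
}

# one key string per position binding all of a template's condition values
template_keys <- function(state, tmpl) {
  vals <- lapply(seq_len(nrow(tmpl$conds)), function(j) {
    f <- tmpl$conds$feature[j]
    o <- tmpl$conds$offset[j]
    src <- if (f == "tag") state$current else {
      if (is.null(state$features[[f]])) {
        stop("template references unknown feature '", f, "'", call. = FALSE)
      }
      state$features[[f]]
    }
    shift_by_doc(src, state$doc_idx, o)
  })
  do.call(paste, c(vals, sep = SEP))
}

new_rule <- function(tmpl, values, from, to) {
  structure(list(conds = tmpl$conds, values = as.character(values),
                 from = from, to = to, template = tmpl$name),
            class = "transformation_rule")
}

#' Human-readable serialization of a transformation rule
#'
#' @param rule a rule as produced by [train_tbed()] or
#'   [generate_candidates()].
#' @return a string like
#'   `"IF token@0='Hospital' AND tag@-1='O' THEN O->I(HOSPITAL)"`.
#' @export
rule_string <- function(rule) {
  esc <- gsub("'", "\\\\'", rule$values)
  conds <- sprintf("%s@%d='%s'", rule$conds$feature, rule$conds$offset, esc)
  sprintf("IF %s THEN %s->%s", paste(conds, collapse = " AND "),
          rule$from, rule$to)
}

#' @export
print.transformation_rule <- function(x, ...) {
  cat(rule_string(x), "\n")
  invisible(x)
}

#' Generate candidate transformation rules
#'
#' At every position where the current tag disagrees with the gold tag, and
#' for every template, one candidate rule is emitted whose conditions are
#' bound to that position's feature values and whose rewrite is
#' `current tag -> gold tag`. Duplicates collapse.
#'
#' @param state a [tbed_state()].
#' @param templates a template list from [read_templates()].
#' @return a list of `transformation_rule` objects.
#' @export
generate_candidates <- function(state, templates) {
  err <- which(state$current != state$gold)
  if (!length(err)) return(list())
  rules <- list()
  seen <- character()
  for (tmpl in templates) {
    keys <- template_keys(state, tmpl)
    id <- paste(tmpl$name, keys[err], state$current[err], state$gold[err],
                sep = SEP)
    new <- which(!duplicated(id) & !id %in% seen)
    seen <- c(seen, id[new])
    for (i in new) {
      p <- err[i]
      vals <- strsplit(keys[p], SEP, fixed = TRUE)[[1]]
      rules[[length(rules) + 1]] <- new_rule(tmpl, vals, state$current[p],
                                             state$gold[p])
    }
  }
  rules
}

# positions where a rule's conditions hold and the current tag equals from
rule_sites <- function(rule, state) {
  tmpl <- list(conds = rule$conds, name = rule$template)
  keys <- template_keys(state, tmpl)
  which(keys == paste(rule$values, collapse = SEP) &
          state$current == rule$from)
}

#' Score a transformation rule
#'
#' Simulates applying `rule` at every qualifying position: `fixed` counts
#' errors corrected (the rewrite lands on the gold tag), `broken` counts
#' previously-correct tags corrupted, and the benefit is
#' `score = fixed - broken`. The state is not modified.
#'
#' @param rule a `transformation_rule`.
#' @param state a [tbed_state()].
#' @return a list `(rule, score, fixed, broken)` of class `scored_rule`.
#' @export
score_rule <- function(rule, state) {
  sites <- rule_sites(rule, state)
  fixed <- sum(state$gold[sites] == rule$to)
  broken <- sum(state$gold[sites] == rule$from)
  structure(list(rule = rule, score = fixed - broken,
                 fixed = fixed, broken = broken),
            class = "scored_rule")
}

#' @export
print.scored_rule <- function(x, ...) {
  cat(sprintf("%s  # score=%d fixed=%d broken=%d\n",
              rule_string(x$rule), x$score, x$fixed, x$broken))
  invisible(x)
}

#' Apply a transformation rule to the training state
#'
#' Simultaneous application: conditions are evaluated against the
#' pre-application tags at all positions, then every firing position is
#' rewritten at once. The corpus error count therefore decreases by exactly
#' the rule's score.
#'
#' @inheritParams score_rule
#' @return the updated state.
#' @export
apply_rule <- function(rule, state) {
  sites <- rule_sites(rule, state)
  state$current[sites] <- rule$to
  state$k <- state$k + 1L
  state
}

#' Train the transformation-based error-driven learner
#'
#' Greedy loop: generate candidates at mistagged positions, score all of
#' them, select the best-scoring rule (ties broken by fewer broken tags,
#' then smaller template arity, then lexicographic rule string), apply it,
#' and repeat until the best benefit falls below `min_score` or `max_iters`
#' is reached. The per-iteration training error is strictly decreasing.
#'
#' @param state a [tbed_state()] (initial tags from the initial annotator).
#' @param templates a template list from [read_templates()].
#' @param max_iters iteration cap (default 200).
#' @param min_score minimum acceptable benefit, at least 1 (default 1).
#' @param verbose print a one-line trace per iteration.
#' @return an object of class `tbed_rules`: `rules` (ordered list, each
#'   carrying its selection-time `score`/`fixed`/`broken`) and `trace` (a
#'   data.frame with iteration, rule, score and remaining errors).
#' @export
train_tbed <- function(state, templates = default_templates(),
                       max_iters = 200L, min_score = 1L, verbose = FALSE) {
  if (min_score < 1) stop("min_score must be >= 1", call. = FALSE)
  rules <- list()
  trace <- data.frame(iteration = integer(), rule = character(),
                      score = integer(), fixed = integer(),
                      broken = integer(), errors = integer(),
                      stringsAsFactors = FALSE)
  for (iter in seq_len(max_iters)) {
    err <- which(state$current != state$gold)
    if (!length(err)) break
    best <- NULL
    for (ti in seq_along(templates)) {
      tmpl <- templates[[ti]]
      keys <- template_keys(state, tmpl)
      grp <- paste(keys, state$current, sep = SEP)
      correct <- state$current == state$gold
      broken_tab <- table(grp[correct])
      cand_grp <- grp[err]
      cand_to <- state$gold[err]
      cand_id <- paste(cand_grp, cand_to, sep = SEP)
      fixed_tab <- table(cand_id)
      uniq <- which(!duplicated(cand_id))
      for (u in uniq) {
        id <- cand_id[u]
        fixed <- as.integer(fixed_tab[[id]])
        broken <- broken_tab[cand_grp[u]]
        broken <- if (is.na(broken)) 0L else as.integer(broken)
        sc <- fixed - broken
        if (!is.null(best) && sc < best$score) next
        p <- err[u]
        vals <- strsplit(keys[p], SEP, fixed = TRUE)[[1]]
        rule <- new_rule(tmpl, vals, state$current[p], cand_to[u])
        cand <- list(rule = rule, score = sc, fixed = fixed, broken = broken,
                     rstr = rule_string(rule), arity = tmpl$arity)
        if (is.null(best) || better_rule(cand, best)) best <- cand
      }
    }
    if (is.null(best) || best$score < min_score) break
    state <- apply_rule(best$rule, state)
    errs <- sum(state$current != state$gold)
    rules[[length(rules) + 1]] <- c(best$rule,
                                    list(score = best$score,
                                         fixed = best$fixed,
                                         broken = best$broken))
    class(rules[[length(rules)]]) <- "transformation_rule"
    trace <- rbind(trace, data.frame(
      iteration = iter, rule = best$rstr, score = best$score,
      fixed = best$fixed, broken = best$broken, errors = errs,
      stringsAsFactors = FALSE
    ))
    if (verbose) {
      message(sprintf("iter %d: %s  score=%d  errors=%d",
                      iter, best$rstr, best$score, errs))
    }
  }
  structure(list(rules = rules, trace = trace), class = "tbed_rules")
}

# tie-break: higher score, then fewer broken, then smaller arity, then
# lexicographic rule string
better_rule <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$broken != b$broken) return(a$broken < b$broken)
  if (a$arity != b$arity) return(a$arity < b$arity)
  a$rstr < b$rstr
}

#' @export
print.tbed_rules <- function(x, ...) {
  cat(sprintf("<tbed_rules: %d rules>\n", length(x$rules)))
  for (r in utils::head(x$rules, 15)) {
    cat(sprintf("  %s  # score=%d\n", rule_string(r), r$score))
  }
  if (length(x$rules) > 15) cat("  ...\n")
  invisible(x)
}

#' Tag a document with the learned rule-based tagger
#'
#' Runs the initial annotator, then applies each learned rule in order
#' (simultaneously within each rule, exactly as during training).
#'
#' @param text raw document text.
#' @param tokens token table for `text`.
#' @param ftab feature table for `text` (same columns used in training).
#' @param patterns a pattern table from [load_patterns()].
#' @param rules a `tbed_rules` object (or its `rules` list).
#' @return a character vector of IOB tags.
#' @export
tag_tbed <- function(text, tokens, ftab, patterns, rules) {
  tags <- annotate_initial(text, tokens, patterns)
  rule_list <- if (inherits(rules, "tbed_rules")) rules$rules else rules
  if (!length(rule_list)) return(tags)
  state <- structure(list(
    features = ftab,
    doc = rep(1L, nrow(ftab)),
    doc_idx = list(seq_len(nrow(ftab))),
    current = tags,
    gold = rep(NA_character_, nrow(ftab)),
    k = 0L
  ), class = "tbed_state")
  for (r in rule_list) {
    sites <- rule_sites(r, state)
    state$current[sites] <- r$to
  }
  state$current
}

#' Read and write learned rule lists
#'
#' Rules are serialized one per line in the human-readable form
#' `IF token@0='Hospital' AND tag@-1='O' THEN O->I(HOSPITAL) # score=17
#' fixed=18 broken=1`; `read_rules(write_rules(x))` reproduces the rule
#' list exactly.
#'
#' @param rules a `tbed_rules` object.
#' @param path output file.
#' @export
write_rules <- function(rules, path) {
  rule_list <- if (inherits(rules, "tbed_rules")) rules$rules else rules
  lines <- vapply(rule_list, function(r) {
    sprintf("%s # score=%d fixed=%d broken=%d", rule_string(r),
            if (is.null(r$score)) NA_integer_ else r$score,
            if (is.null(r$fixed)) NA_integer_ else r$fixed,
            if (is.null(r$broken)) NA_integer_ else r$broken)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rules <- lapply(lines, parse_rule_line)
  structure(list(rules = rules,
                 trace = data.frame()), class = "tbed_rules")
}

parse_rule_line <- function(line) {
  m <- regexec(
    "^IF (.*) THEN ([^ ]+)->([^ ]+)(?: # score=(-?[0-9NA]+) fixed=([0-9NA]+) broken=([0-9NA]+))?\\s*$",
    line)
  g <- regmatches(line, m)[[1]]
  if (!length(g)) stop("cannot parse rule line: ", line, call. = FALSE)
  cond_str <- g[2]
  cm <- gregexpr("([A-Za-z0-9_@|]+)@(-?[0-9]+)='((?:[^'\\\\]|\\\\.)*)'",
                 cond_str, perl = TRUE)[[1]]
  pieces <- regmatches(cond_str, list(cm))[[1]]
  parts <- regmatches(pieces,
                      regexec("^([A-Za-z0-9_@|]+)@(-?[0-9]+)='((?:[^'\\\\]|\\\\.)*)'$",
                              pieces, perl = TRUE))
  conds <- data.frame(
    feature = vapply(parts, `[`, character(1), 2),
    offset = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  values <- gsub("\\\\'", "'", vapply(parts, `[`, character(1), 4))
  tmpl <- list(conds = conds, arity = nrow(conds),
               name = paste(sprintf("%s@%d", conds$feature, conds$offset),
                            collapse = ","))
  rule <- new_rule(tmpl, values, g[3], g[4])
  if (length(g) >= 5 && nzchar(g[5]) && g[5] != "NA") {
    rule$score <- as.integer(g[5])
    rule$fixed <- as.integer(g[6])
    rule$broken <- as.integer(g[7])
  }
  rule
}
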