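# Shared fixtures, all built in code.

# the worked example sentence used throughout
example_sentence <- function() "Harlan Oneil is a 43 years old gentleman"

example_tokens <- function() tokenize(example_sentence())

# token table straight from texts laid out with single spaces
space_tokens <- function(words) {
  ends <- cumsum(nchar(words) + 1L) - 1L
  data.frame(text = words, start = ends - nchar(words), end = ends,
             sentence = 1L, stringsAsFactors = FALSE)
}

# a tiny annotated document with one PATIENT and one AGE entity
tiny_doc <- function(id = "t1") {
  txt <- example_sentence()
  annotated_document(id, txt, phi_entities(
    c(0L, 18L), c(12L, 20L), c("PATIENT", "AGE"), source_text = txt
  ))
}

# deterministic toy CRF language: a digit token after "on" is B(DATE)
separable_crf_data <- function(n_sentences = 50, seed = 11) {
  set.seed(seed)
  vocab <- c("visit", "went", "well", "stable", "today")
  lapply(seq_len(n_sentences), function(s) {
    n <- sample(3:6, 1)
    toks <- character(n)
    tags <- character(n)
    for (i in seq_len(n)) {
      if (i > 1 && toks[i - 1] == "on") {
        toks[i] <- as.character(sample(1000:9999, 1))
        tags[i] <- "B(DATE)"
      } else if (runif(1) < 0.3) {
        toks[i] <- "on"
        tags[i] <- "O"
      } else {
        toks[i] <- sample(vocab, 1)
        tags[i] <- "O"
      }
    }
    tt <- space_tokens(toks)
    ftab <- feature_table(paste(toks, collapse = " "), tt, heuristic_pos_ner)
    list(obs = crf_observations(ftab, NULL), tags = tags,
         tokens = tt, ftab = ftab)
  })
}

# brute-force score of a tag sequence under a CRF parameterization
brute_crf_score <- function(E, Tr, y) {
  n <- length(y)
  s <- sum(E[cbind(seq_len(n), y)])
  if (n > 1) s <- s + sum(Tr[cbind(y[-n], y[-1])])
  s
}

# all |K|^n tag index sequences
all_tag_seqs <- function(n, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), n)))
}

# exhaustive TBED oracle: enumerate every bindable rule from every error
# position and template, score each by direct simulation, return the best
# score (independent of the learner's grouped scoring path)
tbed_oracle_best <- function(state, templates) {
  cands <- generate_candidates(state, templates)
  if (!length(cands)) return(NULL)
  scored <- lapply(cands, score_rule, state = state)
  max(vapply(scored, `[[`, numeric(1), "score"))
}
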