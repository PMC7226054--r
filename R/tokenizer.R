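#' Subword tokenization for clinical notes
#'
#' Whitespace tokens do not match PHI boundaries in clinical text (the note
#' may contain `"Dr.Smith"` where only `"Smith"` is PHI), so tokenization
#' proceeds in three steps: (1) split everything except runs of consecutive
#' letters and runs of consecutive digits ([split_char_runs()]); (2) split
#' letter runs before internal uppercase letters ([split_uppercase()]);
#' (3) optionally re-merge frequent adjacent pieces with byte pair encoding
#' ([learn_bpe()], [apply_bpe()]) to fight sparseness. Character offsets are
#' preserved throughout: each token satisfies
#' `text == substr(source, start + 1, end)` and no token spans whitespace.
#'
#' Sentence boundaries (used by the sentence-length feature) are detected at
#' newlines and at `.?!` followed by whitespace and an uppercase letter.
#'
#' @param text a character scalar.
#' @param bpe an optional `bpe_model` from [learn_bpe()]; `NULL` skips
#'   step 3.
#' @return a data.frame of class `token_table` with columns `text`,
#'   `start`, `end` (0-based half-open offsets) and `sentence` (1-based
#'   sentence index).
#' @examples
#' tokenize("48-year-old in Edwin HealthCare")$text
#' @export
tokenize <- function(text, bpe = NULL) {
  toks <- split_char_runs(text)
  toks <- split_uppercase(toks)
  if (!is.null(bpe)) toks <- apply_bpe(toks, bpe)
  toks$sentence <- sentence_index(text, toks$start)
  class(toks) <- c("token_table", "data.frame")
  toks
}

#' @rdname tokenize
#' @export
split_char_runs <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\p{L}+|\\p{N}+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(
    text = substring(text, m, m + len - 1L),
    start = as.integer(m - 1L),
    end = as.integer(m + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname tokenize
#' @param tokens a token table (or, for `split_uppercase`, the output of
#'   [split_char_runs()]).
#' @export
split_uppercase <- function(tokens) {
  if (nrow(tokens) == 0) return(tokens)
  pieces <- lapply(seq_len(nrow(tokens)), function(i) {
    t <- tokens$text[i]
    if (!grepl("^\\p{L}+$", t, perl = TRUE)) {
      return(tokens[i, c("text", "start", "end"), drop = FALSE])
    }
    cuts <- gregexpr("\\p{Lu}", t, perl = TRUE)[[1]]
    cuts <- cuts[cuts > 1]
    if (length(cuts) == 0 || cuts[1] == -1) {
      return(tokens[i, c("text", "start", "end"), drop = FALSE])
    }
    bounds <- c(1L, cuts, nchar(t) + 1L)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1L
    data.frame(
      text = substring(t, starts, ends),
      start = tokens$start[i] + starts - 1L,
      end = tokens$start[i] + ends,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# whitespace-chunk id: tokens whose spans touch belong to one original
# whitespace-delimited chunk; BPE merges never cross chunk boundaries
chunk_index <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0) return(integer())
  new_chunk <- c(TRUE, tokens$start[-1] != tokens$end[-n])
  cumsum(new_chunk)
}

#' Learn a byte-pair-encoding merge list
#'
#' Greedy BPE over a corpus already tokenized with steps 1-2: at each
#' iteration the most frequent adjacent token pair within a whitespace chunk
#' is merged everywhere, and the pair is appended to the ordered merge list.
#' Frequency ties are broken by lexicographic order of the pair string, so
#' the model is a deterministic function of the corpus and `num_merges`
#' (document order is irrelevant).
#'
#' @param corpus a list of token tables (from [tokenize()] with `bpe = NULL`
#'   or [split_uppercase()]).
#' @param num_merges maximum number of merge operations to learn.
#' @param min_frequency stop once the most frequent remaining pair occurs
#'   fewer than this many times (default 2: singleton merges only memorize
#'   one chunk and cannot reduce sparseness).
#' @return an object of class `bpe_model`: a list with `merges`, a
#'   two-column character matrix in learned order.
#' @export
learn_bpe <- function(corpus, num_merges = 1000L, min_frequency = 2L) {
  if (num_merges < 0) stop("num_merges must be >= 0", call. = FALSE)
  chunks <- list()
  for (tt in corpus) {
    ci <- chunk_index(tt)
    chunks <- c(chunks, unname(split(tt$text, ci)))
  }
  chunks <- chunks[lengths(chunks) > 1]
  merges <- matrix(character(), ncol = 2)
  for (k in seq_len(num_merges)) {
    if (!length(chunks)) break
    pairs <- unlist(lapply(chunks, function(ch) {
      paste(ch[-length(ch)], ch[-1], sep = "")
    }), use.names = FALSE)
    if (!length(pairs)) break
    tab <- table(pairs)
    best_n <- max(tab)
    if (best_n < min_frequency) break
    cand <- sort(names(tab)[tab == best_n], method = "radix")
    best <- cand[1]
    lr <- strsplit(best, "", fixed = TRUE)[[1]]
    merges <- rbind(merges, lr)
    chunks <- lapply(chunks, merge_pair_in_chunk, left = lr[1], right = lr[2])
    chunks <- chunks[lengths(chunks) > 1]
  }
  dimnames(merges) <- NULL
  structure(list(merges = merges), class = "bpe_model")
}

# merge every non-overlapping left-to-right occurrence of (left, right)
merge_pair_in_chunk <- function(ch, left, right) {
  n <- length(ch)
  if (n < 2 || !any(ch == left)) return(ch)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && ch[i] == left && ch[i + 1] == right) {
      out <- c(out, paste0(left, right))
      i <- i + 2L
    } else {
      out <- c(out, ch[i])
      i <- i + 1L
    }
  }
  out
}

#' @rdname learn_bpe
#' @param tokens a token table from tokenization steps 1-2.
#' @param model a `bpe_model`.
#' @return `apply_bpe()`: the token table with merges applied in learned
#'   order; merged tokens take the union of their source spans.
#' @export
apply_bpe <- function(tokens, model) {
  if (nrow(tokens) == 0 || nrow(model$merges) == 0) return(tokens)
  ci <- chunk_index(tokens)
  txt <- tokens$text
  start <- tokens$start
  end <- tokens$end
  res_txt <- character(0)
  res_start <- integer(0)
  res_end <- integer(0)
  for (g in unique(ci)) {
    idx <- which(ci == g)
    ct <- txt[idx]
    cs <- start[idx]
    ce <- end[idx]
    for (m in seq_len(nrow(model$merges))) {
      left <- model$merges[m, 1]
      right <- model$merges[m, 2]
      if (length(ct) < 2 || !any(ct == left)) next
      i <- 1L
      nt <- character(0); ns <- integer(0); ne <- integer(0)
      while (i <= length(ct)) {
        if (i < length(ct) && ct[i] == left && ct[i + 1] == right) {
          nt <- c(nt, paste0(left, right))
          ns <- c(ns, cs[i])
          ne <- c(ne, ce[i + 1])
          i <- i + 2L
        } else {
          nt <- c(nt, ct[i]); ns <- c(ns, cs[i]); ne <- c(ne, ce[i])
          i <- i + 1L
        }
      }
      ct <- nt; cs <- ns; ce <- ne
    }
    res_txt <- c(res_txt, ct)
    res_start <- c(res_start, cs)
    res_end <- c(res_end, ce)
  }
  out <- data.frame(text = res_txt, start = res_start, end = res_end,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' @rdname learn_bpe
#' @param path file path; the merge list is stored as plain text, one
#'   `"left right"` pair per line (the de-facto standard merge-file layout).
#' @export
write_bpe <- function(model, path) {
  writeLines(paste(model$merges[, 1], model$merges[, 2]), path)
  invisible(path)
}

#' @rdname learn_bpe
#' @export
read_bpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(merges = matrix(character(), ncol = 2)),
                     class = "bpe_model"))
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("malformed BPE merge file at line ", bad[1], call. = FALSE)
  }
  structure(list(merges = do.call(rbind, parts)), class = "bpe_model")
}

#' @export
print.bpe_model <- function(x, ...) {
  cat(sprintf("<bpe_model: %d merges>\n", nrow(x$merges)))
  invisible(x)
}

# 1-based sentence index for each token start offset
sentence_index <- function(text, starts) {
  if (!length(starts)) return(integer())
  brk <- gregexpr("\\n|[.?!](?=\\s+\\p{Lu})", text, perl = TRUE)[[1]]
  if (brk[1] == -1) return(rep(1L, length(starts)))
  # a sentence begins after the break character
  boundary <- as.integer(brk)  # 0-based offset just past the break char
  findInterval(starts, sort(boundary)) + 1L
}

#' Fraction of PHI entities misaligned with token boundaries
#'
#' A gold entity is misaligned when its start or end offset falls strictly
#' inside a token, making it impossible to annotate correctly under the
#' token-level IOB scheme. Subword tokenization exists to drive this rate
#' down; this function measures what remains.
#'
#' @param docs a list of [annotated_document()]s.
#' @param bpe optional `bpe_model` applied during tokenization.
#' @return the fraction of gold entities misaligned, in `[0, 1]`.
#' @export
phi_alignment_error_rate <- function(docs, bpe = NULL) {
  total <- 0L
  bad <- 0L
  for (doc in docs) {
    toks <- tokenize(doc$text, bpe)
    ent <- doc$entities
    for (i in seq_len(nrow(ent))) {
      total <- total + 1L
      covered <- which(toks$start >= ent$start[i] & toks$end <= ent$end[i])
      aligned <- length(covered) > 0 &&
        any(toks$start[covered] == ent$start[i]) &&
        any(toks$end[covered] == ent$end[i])
      if (!aligned) bad <- bad + 1L
    }
  }
  if (total == 0) return(0)
  bad / total
}
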