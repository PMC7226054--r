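#' Per-token feature extraction
#'
#' Builds the unified feature set shared by the rule learner and the CRF:
#' token-level features (surface form, length, all-digits and
#' initial-uppercase flags, stem, prefixes and suffixes of lengths 1-4),
#' global features (sentence length in tokens, section label from header
#' heuristics), and tagging-based features (POS and general NER labels from
#' a pluggable external tagger). Extraction is pure: the same document and
#' tagger always yield the same table.
#'
#' @param text raw document text.
#' @param tokens a token table from [tokenize()].
#' @param tagger an external POS/NER tagger honoring the plug-in contract
#'   (see [tagging_features()]); `NULL` fills `"NA"` sentinels,
#'   [heuristic_pos_ner()] is the built-in fallback.
#' @return a data.frame with one row per token and one column per feature.
#' @examples
#' toks <- tokenize("Edwin is 43")
#' feature_table("Edwin is 43", toks, tagger = heuristic_pos_ner)[,
#'   c("token", "all_digits", "init_upper")]
#' @export
feature_table <- function(text, tokens, tagger = NULL) {
  tf <- token_features(tokens)
  gf <- global_features(text, tokens)
  pf <- tagging_features(tokens, tagger)
  cbind(tf, gf, pf)
}

#' @rdname feature_table
#' @export
token_features <- function(tokens) {
  txt <- tokens$text
  n <- length(txt)
  out <- data.frame(
    token = txt,
    length = nchar(txt),
    all_digits = grepl("^\\p{N}+$", txt, perl = TRUE),
    init_upper = grepl("^\\p{Lu}", txt, perl = TRUE),
    stem = word_stem(txt),
    stringsAsFactors = FALSE
  )
  for (k in 1:4) {
    out[[paste0("prefix", k)]] <- substring(txt, 1L, k)
    out[[paste0("suffix", k)]] <- substring(txt, pmax(1L, nchar(txt) - k + 1L),
                                            nchar(txt))
  }
  out
}

#' @rdname feature_table
#' @export
global_features <- function(text, tokens) {
  sent <- tokens$sentence
  if (is.null(sent)) sent <- sentence_index(text, tokens$start)
  counts <- table(sent)
  data.frame(
    sentence_length = as.integer(counts[as.character(sent)]),
    section = section_labels(text, tokens),
    stringsAsFactors = FALSE
  )
}

# Section label per token: a line that looks like a header ("Record date:",
# "HPI:", "Medications:", or any short capitalized phrase ending in a colon)
# starts a section; that line and everything after it up to the next header
# carry the normalized header name; tokens before any header are "BODY".
section_labels <- function(text, tokens) {
  n <- nrow(tokens)
  if (n == 0) return(character())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  line_start <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  known <- c("Record date", "HPI", "Medications", "Allergies", "Assessment",
             "Plan", "History", "Family History", "Social History",
             "Physical Exam", "Labs", "Impression")
  hdr_text <- sub(":.*$", "", lines)
  is_hdr <- grepl("^[A-Z][A-Za-z ]{2,40}:", lines) &
    (trimws(hdr_text) %in% known | grepl("^[A-Z][A-Za-z ]{2,40}:\\s*$", lines))
  labels <- toupper(gsub("[^A-Za-z0-9]+", "_", trimws(hdr_text)))
  hdr_idx <- which(is_hdr)
  if (!length(hdr_idx)) return(rep("BODY", n))
  tok_line <- findInterval(tokens$start, line_start)
  last_hdr <- findInterval(tok_line, hdr_idx)
  ifelse(last_hdr == 0, "BODY", labels[hdr_idx[pmax(last_hdr, 1L)]])
}

#' Tagging-based features from a pluggable external tagger
#'
#' The external-tagger contract: a function taking a token table and
#' returning `list(pos = <chr>, ner = <chr>)`, one label per token. When no
#' tagger is supplied, both features are filled with the `"NA"` sentinel and
#' a warning is logged; a tagger returning the wrong number of labels is a
#' contract error.
#'
#' @param tokens a token table.
#' @param tagger the plug-in function, or `NULL`.
#' @return a data.frame with character columns `pos` and `ner`.
#' @export
tagging_features <- function(tokens, tagger = NULL) {
  n <- nrow(tokens)
  if (is.null(tagger)) {
    warning("no external POS/NER tagger supplied; using 'NA' sentinels",
            call. = FALSE)
    return(data.frame(pos = rep("NA", n), ner = rep("NA", n),
                      stringsAsFactors = FALSE))
  }
  res <- tagger(tokens)
  if (!is.list(res) || is.null(res$pos) || is.null(res$ner) ||
      length(res$pos) != n || length(res$ner) != n) {
    stop(sprintf(
      "external tagger violated its contract: expected pos/ner of length %d, got %s/%s",
      n, length(res$pos), length(res$ner)
    ), call. = FALSE)
  }
  data.frame(pos = as.character(res$pos), ner = as.character(res$ner),
             stringsAsFactors = FALSE)
}

#' @rdname tagging_features
#' @details `heuristic_pos_ner()` is a built-in rule-of-thumb tagger
#'   (digit tokens are `CD`, punctuation `PUNCT`, capitalized tokens `NNP`
#'   and entity-like, `-ed`/`-ing` verb forms, everything else `NN`). It is
#'   a deliberately coarse stand-alone heuristic, useful when no external
#'   NLP tagger is registered.
#' @export
heuristic_pos_ner <- function(tokens) {
  txt <- tokens$text
  digits <- grepl("^\\p{N}+$", txt, perl = TRUE)
  punct <- !grepl("[\\p{L}\\p{N}]", txt, perl = TRUE)
  upper <- grepl("^\\p{Lu}", txt, perl = TRUE)
  closed <- tolower(txt) %in% c("a", "an", "the", "of", "in", "on", "at",
                                "to", "for", "with", "by", "from", "and",
                                "or", "is", "was", "were", "be")
  pos <- ifelse(digits, "CD",
         ifelse(punct, "PUNCT",
         ifelse(closed, "IN",
         ifelse(upper, "NNP",
         ifelse(grepl("ing$", txt), "VBG",
         ifelse(grepl("ed$", txt), "VBD",
         ifelse(grepl("ly$", txt), "RB", "NN")))))))
  ner <- ifelse(digits, "NUM", ifelse(upper & !closed, "ENT", "O"))
  list(pos = pos, ner = ner)
}

# value of feature column `feat` at window offset `off`, with out-of-range
# positions filled by boundary sentinels
shift_feature <- function(values, off) {
  n <- length(values)
  v <- as.character(values)
  if (off == 0) return(v)
  if (off < 0) {
    c(rep("BOS", min(-off, n)), utils::head(v, max(n + off, 0)))
  } else {
    c(utils::tail(v, max(n - off, 0)), rep("EOS", min(off, n)))
  }
}

#' Feature crosses
#'
#' A cross conjoins several base features, possibly at different window
#' offsets (-2..+2), into one composite feature whose value concatenates the
#' member values with a reserved `"|"` separator. The default specification
#' shipped with the package (`crosses_default.txt`) declares 49 crosses over
#' surface, shape, POS and section features; the inventory is configuration,
#' not code.
#'
#' @param ftab a feature table from [feature_table()] (one document).
#' @param spec a cross specification from [read_cross_spec()] or
#'   [default_cross_spec()].
#' @return `build_crosses()`: `ftab` augmented with one column per cross,
#'   named `"feat@off|feat@off"`.
#' @export
build_crosses <- function(ftab, spec) {
  for (cr in spec) {
    bad <- setdiff(cr$features, names(ftab))
    if (length(bad)) {
      stop("cross references unknown feature '", bad[1], "'", call. = FALSE)
    }
    vals <- mapply(function(f, o) shift_feature(ftab[[f]], o),
                   cr$features, cr$offsets, SIMPLIFY = FALSE)
    ftab[[cr$name]] <- do.call(paste, c(vals, sep = "|"))
  }
  ftab
}

#' @rdname build_crosses
#' @param path a cross-spec file: one cross per line, comma-separated
#'   `feature@offset` terms, `#` comments allowed.
#' @export
read_cross_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    terms <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    parts <- regmatches(terms, regexec("^([A-Za-z0-9_]+)@(-?[0-9]+)$", terms))
    bad <- which(lengths(parts) != 3)
    if (length(bad)) {
      stop("malformed cross term '", terms[bad[1]], "' in ", path,
           call. = FALSE)
    }
    feats <- vapply(parts, `[`, character(1), 2)
    offs <- as.integer(vapply(parts, `[`, character(1), 3))
    if (any(abs(offs) > 2)) {
      stop("cross offsets must lie in -2..2: '", ln, "'", call. = FALSE)
    }
    list(features = feats, offsets = offs,
         name = paste(sprintf("%s@%d", feats, offs), collapse = "|"))
  })
}

#' @rdname build_crosses
#' @export
default_cross_spec <- function() {
  read_cross_spec(system.file("extdata", "crosses_default.txt",
                              package = "deidr", mustWork = TRUE))
}
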