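#' Load initial-annotator regex patterns
#'
#' The initial-state annotator of the rule learner is a prioritized list of
#' regular expressions over the raw note text, each paired with the IOB tag
#' it assigns. The config format is one `priority<TAB>regex<TAB>tag` per
#' line with `#` comments; the default file shipped with the package
#' contains the published pattern table (usernames, hospital keywords,
#' emails, street suffixes, dates).
#'
#' @param path pattern file; defaults to the bundled pattern set.
#' @return a data.frame with columns `priority`, `pattern`, `tag`, ordered
#'   by priority then file order. Every pattern is checked to compile and
#'   every tag to name one of the 23 PHI categories.
#' @export
load_patterns <- function(path = default_patterns_file()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(priority = integer(), pattern = character(),
                      tag = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop("malformed pattern line ", lineno[bad[1]], " in ", path,
         " (need priority<TAB>regex<TAB>tag)", call. = FALSE)
  }
  pat <- data.frame(
    priority = as.integer(vapply(parts, `[`, character(1), 1)),
    pattern = vapply(parts, `[`, character(1), 2),
    tag = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(pat))) {
    ok <- tryCatch({
      regexpr(pat$pattern[i], "", perl = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop("pattern on line ", lineno[i], " of ", path,
           " does not compile: ", pat$pattern[i], call. = FALSE)
    }
    if (!tag_kind(pat$tag[i]) %in% c("B", "I") ||
        !is_phi_category(tag_category(pat$tag[i]))) {
      stop("pattern on line ", lineno[i], " of ", path,
           " has invalid tag: ", pat$tag[i], call. = FALSE)
    }
  }
  pat[order(pat$priority, seq_len(nrow(pat))), , drop = FALSE]
}

#' @rdname load_patterns
#' @export
default_patterns_file <- function() {
  system.file("extdata", "patterns_default.tsv", package = "deidr",
              mustWork = TRUE)
}

#' Apply the initial-state annotator
#'
#' Each pattern is matched against the raw text (not the token stream, so
#' patterns may span whitespace); every token lying fully inside a match
#' receives the pattern's tag. A `B(CAT)` pattern tags the first token of
#' the match `B(CAT)` and subsequent tokens `I(CAT)`; an `I(CAT)` pattern
#' tags all covered tokens `I(CAT)`. Tokens only partially overlapping a
#' match are left `O` (conservative: never corrupt a span). Conflicts are
#' resolved by priority, then longer match, then leftmost match. Unmatched
#' tokens are `O`.
#'
#' @param text raw document text.
#' @param tokens a token table from [tokenize()] over `text`.
#' @param patterns a pattern table from [load_patterns()].
#' @return a character vector of IOB tags, one per token.
#' @examples
#' pats <- load_patterns()
#' toks <- tokenize("Transfer to Parkway Hospital today")
#' annotate_initial("Transfer to Parkway Hospital today", toks, pats)
#' @export
annotate_initial <- function(text, tokens, patterns) {
  n <- nrow(tokens)
  tags <- rep("O", n)
  if (n == 0 || nrow(patterns) == 0) return(tags)
  matches <- list()
  for (i in seq_len(nrow(patterns))) {
    m <- gregexpr(patterns$pattern[i], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    keep <- len > 0
    if (!any(keep)) next
    matches[[length(matches) + 1]] <- data.frame(
      start = as.integer(m[keep] - 1L),
      end = as.integer(m[keep] + len[keep] - 1L),
      priority = patterns$priority[i],
      order = i,
      tag = patterns$tag[i],
      stringsAsFactors = FALSE
    )
  }
  if (!length(matches)) return(tags)
  md <- do.call(rbind, matches)
  md <- md[order(md$priority, md$order, -(md$end - md$start), md$start), ,
           drop = FALSE]
  assigned <- rep(FALSE, n)
  for (k in seq_len(nrow(md))) {
    covered <- which(tokens$start >= md$start[k] & tokens$end <= md$end[k] &
                       !assigned)
    if (!length(covered)) next
    cat_k <- tag_category(md$tag[k])
    if (tag_kind(md$tag[k]) == "B") {
      tags[covered[1]] <- iob_b(cat_k)
      if (length(covered) > 1) tags[covered[-1]] <- iob_i(cat_k)
    } else {
      tags[covered] <- iob_i(cat_k)
    }
    assigned[covered] <- TRUE
  }
  tags
}
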