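# Compact Porter-style suffix-stripping stemmer (English). Covers the
# high-frequency inflectional endings (plurals, -ed/-ing, -ly, common
# derivational suffixes); enough to collapse surface variants for the
# stem feature without pulling in a full snowball implementation.

has_vowel <- function(w) grepl("[aeiouy]", w)

#' Stem a token
#'
#' Porter-style suffix stripping used for the `stem` feature. Lowercases,
#' then strips plural and participle endings and a small set of common
#' derivational suffixes, guarding against over-stripping short stems.
#' Non-alphabetic tokens are returned lowercased and otherwise unchanged.
#'
#' @param w a character vector of tokens.
#' @return a character vector of stems.
#' @examples
#' word_stem(c("hospitals", "admitted", "running", "happily"))
#' @export
word_stem <- function(w) {
  vapply(tolower(w), stem_one, character(1), USE.NAMES = FALSE)
}

stem_one <- function(w) {
  if (!grepl("^[a-z]+$", w)) return(w)
  # step 1a: plurals
  if (grepl("sses$", w)) {
    w <- sub("sses$", "ss", w)
  } else if (grepl("ies$", w)) {
    w <- sub("ies$", "i", w)
  } else if (grepl("[^s]s$", w) && nchar(w) > 3) {
    w <- sub("s$", "", w)
  }
  # step 1b: -ed / -ing
  if (grepl("eed$", w)) {
    if (nchar(w) > 4) w <- sub("eed$", "ee", w)
  } else if (grepl("ed$", w) && has_vowel(sub("ed$", "", w))) {
    w <- fixup_after_strip(sub("ed$", "", w))
  } else if (grepl("ing$", w) && has_vowel(sub("ing$", "", w))) {
    w <- fixup_after_strip(sub("ing$", "", w))
  }
  # step 1c: -y -> -i after a vowel-containing stem
  if (grepl("y$", w) && has_vowel(sub("y$", "", w)) && nchar(w) > 2) {
    w <- sub("y$", "i", w)
  }
  # a few common derivational endings
  for (sfx in c("ational", "ization", "fulness", "ousness", "iveness",
                "tional", "biliti", "alism", "ation", "izer", "ment",
                "ness", "alli", "ousli", "entli", "abli")) {
    if (grepl(paste0(sfx, "$"), w) && nchar(w) - nchar(sfx) >= 3) {
      w <- sub(paste0(sfx, "$"), "", w)
      break
    }
  }
  w
}

# undo doubled consonants and restore a trailing e where obvious
fixup_after_strip <- function(w) {
  if (grepl("(at|bl|iz)$", w)) return(paste0(w, "e"))
  if (grepl("([^aeioulsz])\\1$", w)) return(sub(".$", "", w))
  w
}
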