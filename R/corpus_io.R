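#' Read an annotated document from disk
#'
#' Two standoff formats are supported. `"json"` is the package's plain
#' fixture dialect: `{"doc_id", "text", "entities": [{"start", "end",
#' "category"}]}` with 0-based half-open offsets. `"xml"` is i2b2-2014-style
#' standoff XML: a `TEXT` element holding the raw note plus `PHI` tags with
#' `start`/`end`/`TYPE` attributes under `TAGS`. Both are UTF-8.
#'
#' All invariants of [annotated_document()] are enforced on load; overlapping
#' or out-of-range gold spans are rejected with an error naming the offending
#' entity.
#'
#' @param path file path.
#' @param format `"json"` or `"xml"`; default guesses from the extension.
#' @return an [annotated_document()].
#' @seealso [write_annotated()]
#' @export
read_annotated <- function(path, format = c("auto", "json", "xml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$doc_id) || is.null(obj$text)) {
      stop("malformed JSON document (need doc_id and text): ", path,
           call. = FALSE)
    }
    ent <- obj$entities
    if (is.null(ent) || length(ent) == 0 || NROW(ent) == 0) {
      ent <- empty_entities()
    } else {
      ent <- phi_entities(ent$start, ent$end, ent$category,
                          source_text = obj$text)
    }
    annotated_document(obj$doc_id, obj$text, ent)
  } else {
    x <- xml2::read_xml(path)
    text_node <- xml2::xml_find_first(x, ".//TEXT")
    if (inherits(text_node, "xml_missing")) {
      stop("malformed XML document (no TEXT element): ", path, call. = FALSE)
    }
    text <- xml2::xml_text(text_node)
    phi_nodes <- xml2::xml_find_all(x, ".//TAGS/*")
    doc_id <- xml2::xml_attr(x, "id")
    if (is.na(doc_id)) doc_id <- sub("\\.xml$", "", basename(path))
    if (length(phi_nodes) == 0) {
      ent <- empty_entities()
    } else {
      ent <- phi_entities(
        start = as.integer(xml2::xml_attr(phi_nodes, "start")),
        end = as.integer(xml2::xml_attr(phi_nodes, "end")),
        category = xml2::xml_attr(phi_nodes, "TYPE"),
        source_text = text
      )
    }
    annotated_document(doc_id, text, ent)
  }
}

#' Write an annotated document to disk
#'
#' Inverse of [read_annotated()]: `read_annotated(write_annotated(doc))`
#' reproduces `doc` exactly, and files produced here round-trip
#' byte-identically through a read/write cycle.
#'
#' @param doc an [annotated_document()].
#' @param path output file path.
#' @param format `"json"` or `"xml"` (see [read_annotated()]).
#' @return `path`, invisibly.
#' @export
write_annotated <- function(doc, path, format = c("json", "xml")) {
  format <- match.arg(format)
  validate_document(doc)
  if (format == "json") {
    ent <- doc$entities
    entities <- if (nrow(ent) == 0) list() else {
      lapply(seq_len(nrow(ent)), function(i) {
        list(start = ent$start[i], end = ent$end[i], category = ent$category[i])
      })
    }
    json <- jsonlite::toJSON(
      list(doc_id = doc$doc_id, text = doc$text, entities = entities),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(json, path, useBytes = TRUE)
  } else {
    root <- xml2::xml_new_root("deIdDoc", id = doc$doc_id)
    text_node <- xml2::xml_add_child(root, "TEXT")
    xml2::xml_add_child(text_node, xml2::xml_cdata(doc$text))
    tags <- xml2::xml_add_child(root, "TAGS")
    ent <- doc$entities
    for (i in seq_len(nrow(ent))) {
      xml2::xml_add_child(
        tags, "PHI",
        id = sprintf("P%d", i - 1L),
        start = as.character(ent$start[i]),
        end = as.character(ent$end[i]),
        text = ent$text[i],
        TYPE = ent$category[i]
      )
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Convert character-offset entities to per-token IOB tags
#'
#' The first token of each entity is tagged `B(CAT)`, subsequent tokens
#' `I(CAT)`, and all other tokens `O`. Every entity boundary must coincide
#' with a token boundary; run the subword tokenizer first (see
#' [tokenize()] and [phi_alignment_error_rate()]).
#'
#' @param tokens a token table from [tokenize()].
#' @param entities a [phi_entities()] table (non-overlapping).
#' @param on_misaligned `"error"` (default) stops naming the entity and the
#'   straddling token; `"skip"` drops misaligned entities with a warning
#'   (the count is attached as attribute `"skipped"`).
#' @return a character vector of IOB tags, one per token.
#' @examples
#' toks <- tokenize("Harlan Oneil is a 43 years old gentleman")
#' encode_iob(toks, phi_entities(c(0, 18), c(12, 20), c("PATIENT", "AGE"),
#'   source_text = "Harlan Oneil is a 43 years old gentleman"))
#' @export
encode_iob <- function(tokens, entities, on_misaligned = c("error", "skip")) {
  on_misaligned <- match.arg(on_misaligned)
  tags <- rep("O", nrow(tokens))
  skipped <- 0L
  for (i in seq_len(NROW(entities))) {
    s <- entities$start[i]
    e <- entities$end[i]
    covered <- which(tokens$start >= s & tokens$end <= e)
    aligned <- length(covered) > 0 &&
      any(tokens$start[covered] == s) && any(tokens$end[covered] == e)
    if (!aligned) {
      if (on_misaligned == "error") {
        straddle <- which(tokens$start < s & tokens$end > s |
                            tokens$start < e & tokens$end > e)
        tok_msg <- if (length(straddle)) {
          sprintf(" (boundary inside token '%s' [%d,%d))",
                  tokens$text[straddle[1]], tokens$start[straddle[1]],
                  tokens$end[straddle[1]])
        } else " (no covering tokens)"
        stop(sprintf(
          "entity %d '%s' [%d,%d) is not aligned with token boundaries%s",
          i, entities$category[i], s, e, tok_msg
        ), call. = FALSE)
      }
      skipped <- skipped + 1L
      next
    }
    tags[covered[1]] <- iob_b(entities$category[i])
    if (length(covered) > 1) {
      tags[covered[-1]] <- iob_i(entities$category[i])
    }
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d entit%s misaligned with token boundaries",
                    skipped, if (skipped == 1) "y" else "ies"), call. = FALSE)
  }
  attr(tags, "skipped") <- skipped
  tags
}

#' Normalize an ill-formed IOB tag sequence
#'
#' Taggers can emit `I(CAT)` after `O` or after a different category; such
#' tags are repaired by treating each offending `I` as `B` of its own
#' category, so decoding never fails.
#'
#' @param tags a character vector of IOB tags.
#' @return the repaired tag vector.
#' @export
repair_iob <- function(tags) {
  if (!length(tags)) return(tags)
  out <- tags
  for (i in seq_along(out)) {
    if (tag_kind(out[i]) != "I") next
    ok <- i > 1 &&
      tag_kind(out[i - 1]) %in% c("B", "I") &&
      identical(tag_category(out[i - 1]), tag_category(out[i]))
    if (!ok) out[i] <- iob_b(tag_category(out[i]))
  }
  out
}

#' Convert per-token IOB tags back to character-offset entities
#'
#' Maximal `B, I...I` runs of one category become one entity whose offsets
#' come from the first and last token of the run. Ill-formed sequences are
#' first normalized with [repair_iob()], so `decode_iob(encode_iob(...))` is
#' the identity for aligned, non-overlapping entities and never errors on
#' tagger output.
#'
#' @param tokens a token table from [tokenize()].
#' @param tags a character vector of IOB tags, one per token.
#' @param text optional raw document text used to fill entity surface
#'   strings (recommended; without it multi-token surfaces are reconstructed
#'   from token texts joined by single spaces).
#' @return a [phi_entities()] table, sorted and non-overlapping.
#' @export
decode_iob <- function(tokens, tags, text = NULL) {
  stopifnot(length(tags) == nrow(tokens))
  tags <- repair_iob(tags)
  starts <- integer()
  ends <- integer()
  cats <- character()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    if (tag_kind(tags[i]) == "B") {
      cat_i <- tag_category(tags[i])
      j <- i
      while (j < n && tag_kind(tags[j + 1]) == "I" &&
             identical(tag_category(tags[j + 1]), cat_i)) {
        j <- j + 1L
      }
      starts <- c(starts, tokens$start[i])
      ends <- c(ends, tokens$end[j])
      cats <- c(cats, cat_i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) return(empty_entities())
  if (is.null(text)) {
    surf <- vapply(seq_along(starts), function(k) {
      idx <- tokens$start >= starts[k] & tokens$end <= ends[k]
      paste(tokens$text[idx], collapse = " ")
    }, character(1))
    phi_entities(starts, ends, cats, text = surf)
  } else {
    phi_entities(starts, ends, cats, source_text = text)
  }
}
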