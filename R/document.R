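#' Construct a PHI entity table
#'
#' Entities are stored as a data.frame with one row per PHI span. Offsets are
#' 0-based, half-open `[start, end)` character positions into the raw note
#' text (whitespace included), so `text` always equals
#' `substr(note, start + 1, end)`.
#'
#' @param start,end integer character offsets, 0-based half-open.
#' @param category PHI category names (see [phi_categories()]).
#' @param text surface strings; if omitted they are filled from `source_text`.
#' @param source_text optional raw document text used to fill/check `text`.
#' @return a data.frame with columns `start`, `end`, `category`, `text`,
#'   sorted by `start`.
#' @examples
#' phi_entities(0, 6, "PATIENT", source_text = "Harlan Oneil is here")
#' @export
phi_entities <- function(start = integer(), end = integer(),
                         category = character(), text = NULL,
                         source_text = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  category <- as.character(category)
  if (is.null(text)) {
    if (length(start) == 0) {
      text <- character(0)
    } else if (!is.null(source_text)) {
      text <- substring(source_text, start + 1L, end)
    } else {
      text <- rep(NA_character_, length(start))
    }
  }
  ent <- data.frame(
    start = start, end = end, category = category,
    text = as.character(text), stringsAsFactors = FALSE
  )
  ent[order(ent$start, ent$end), , drop = FALSE]
}

#' @rdname phi_entities
#' @export
empty_entities <- function() {
  phi_entities()
}

#' Create and validate an annotated document
#'
#' An annotated document bundles a raw note text with its gold (or predicted)
#' PHI entities. Validation enforces the entity invariants: offsets in range,
#' `start < end`, surface text equal to the document substring, category in
#' the closed 23-name set, and no overlapping gold spans.
#'
#' @param doc_id document identifier string.
#' @param text raw note text.
#' @param entities a data.frame as built by [phi_entities()].
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `annotated_document`.
#' @examples
#' d <- annotated_document("d1", "Harlan Oneil is a 43 years old gentleman",
#'   phi_entities(c(0, 18), c(12, 20), c("PATIENT", "AGE"),
#'     source_text = "Harlan Oneil is a 43 years old gentleman"))
#' d
#' @export
annotated_document <- function(doc_id, text, entities = empty_entities(),
                               validate = TRUE) {
  if (is.null(entities) || nrow(entities) == 0) {
    entities <- empty_entities()
  } else {
    entities <- phi_entities(entities$start, entities$end, entities$category,
                             entities$text, source_text = text)
  }
  doc <- structure(
    list(doc_id = as.character(doc_id), text = as.character(text),
         entities = entities),
    class = "annotated_document"
  )
  if (validate) validate_document(doc)
  doc
}

#' @rdname annotated_document
#' @param doc an `annotated_document`.
#' @export
validate_document <- function(doc) {
  ent <- doc$entities
  n <- nchar(doc$text)
  if (nrow(ent) == 0) return(invisible(doc))
  bad <- which(!(ent$start >= 0 & ent$start < ent$end & ent$end <= n))
  if (length(bad)) {
    stop(sprintf(
      "document '%s': entity %d has invalid span [%d, %d) for text of length %d",
      doc$doc_id, bad[1], ent$start[bad[1]], ent$end[bad[1]], n
    ), call. = FALSE)
  }
  bad <- which(!is_phi_category(ent$category))
  if (length(bad)) {
    stop(sprintf("document '%s': unknown PHI category '%s'",
                 doc$doc_id, ent$category[bad[1]]), call. = FALSE)
  }
  sub <- substring(doc$text, ent$start + 1L, ent$end)
  bad <- which(!is.na(ent$text) & ent$text != sub)
  if (length(bad)) {
    stop(sprintf(
      "document '%s': entity %d text '%s' does not match substring '%s'",
      doc$doc_id, bad[1], ent$text[bad[1]], sub[bad[1]]
    ), call. = FALSE)
  }
  if (nrow(ent) > 1) {
    prev_end <- ent$end[-nrow(ent)]
    next_start <- ent$start[-1]
    bad <- which(next_start < prev_end)
    if (length(bad)) {
      stop(sprintf(
        "document '%s': overlapping gold entities at rows %d and %d ([%d,%d) vs [%d,%d))",
        doc$doc_id, bad[1], bad[1] + 1L,
        ent$start[bad[1]], ent$end[bad[1]],
        ent$start[bad[1] + 1L], ent$end[bad[1] + 1L]
      ), call. = FALSE)
    }
  }
  invisible(doc)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document '%s': %d chars, %d PHI entities>\n",
              x$doc_id, nchar(x$text), nrow(x$entities)))
  if (nrow(x$entities)) {
    print(utils::head(x$entities, 10))
    if (nrow(x$entities) > 10) cat("...\n")
  }
  invisible(x)
}

#' @export
format.annotated_document <- function(x, ...) {
  sprintf("<annotated_document '%s'>", x$doc_id)
}

documents_equal <- function(a, b) {
  identical(a$doc_id, b$doc_id) && identical(a$text, b$text) &&
    isTRUE(all.equal(a$entities, b$entities, check.attributes = FALSE)) &&
    nrow(a$entities) == nrow(b$entities)
}
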