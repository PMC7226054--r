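#' Strict entity match
#'
#' A predicted entity counts as correct only if its start offset, end
#' offset, and category all equal a gold entity's — the primary metric of
#' the de-identification shared tasks.
#'
#' @param pred,gold single-row [phi_entities()] rows (or lists with
#'   `start`, `end`, `category`).
#' @return `TRUE` or `FALSE`.
#' @export
strict_match <- function(pred, gold) {
  pred$start == gold$start && pred$end == gold$end &&
    pred$category == gold$category
}

#' Strict entity-level micro precision, recall and F1
#'
#' Scores predictions against gold annotations under strict matching, with
#' one-to-one matching per document (each gold entity can satisfy at most
#' one prediction; duplicate identical predictions are counted once).
#' Micro-averaged over all documents:
#' `P = 100 TP / (TP + FP)`, `R = 100 TP / (TP + FN)`, `F1` their harmonic
#' mean, each defined as 0 when its denominator is 0. A per-category
#' breakdown accompanies the overall counts and always sums to them.
#'
#' @param pred a list of [annotated_document()]s holding predictions.
#' @param gold a list of [annotated_document()]s holding gold entities;
#'   must cover exactly the same `doc_id`s.
#' @return an object of class `deid_eval`: a list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` and a `by_category` data.frame.
#' @examples
#' g <- annotated_document("d", "a 43 yo", phi_entities(2, 4, "AGE",
#'   source_text = "a 43 yo"))
#' p <- annotated_document("d", "a 43 yo", phi_entities(2, 4, "AGE",
#'   source_text = "a 43 yo"))
#' evaluate_deid(list(p), list(g))
#' @export
evaluate_deid <- function(pred, gold) {
  pid <- vapply(pred, `[[`, character(1), "doc_id")
  gid <- vapply(gold, `[[`, character(1), "doc_id")
  if (!setequal(pid, gid) || anyDuplicated(pid) || anyDuplicated(gid)) {
    stop("prediction and gold document id sets differ", call. = FALSE)
  }
  cats <- phi_categories()
  tp <- fp <- fn <- setNames(integer(length(cats)), cats)
  for (g in gold) {
    p <- pred[[which(pid == g$doc_id)]]
    pe <- p$entities
    pe <- pe[!duplicated(pe[, c("start", "end", "category")]), , drop = FALSE]
    ge <- g$entities
    pkey <- paste(pe$start, pe$end, pe$category)
    gkey <- paste(ge$start, ge$end, ge$category)
    hit <- pkey %in% gkey
    for (i in which(hit)) tp[[pe$category[i]]] <- tp[[pe$category[i]]] + 1L
    for (i in which(!hit)) fp[[pe$category[i]]] <- fp[[pe$category[i]]] + 1L
    miss <- !(gkey %in% pkey)
    for (i in which(miss)) fn[[ge$category[i]]] <- fn[[ge$category[i]]] + 1L
  }
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  overall <- prf(sum(tp), sum(fp), sum(fn))
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    m <- prf(tp[[cc]], fp[[cc]], fn[[cc]])
    data.frame(category = cc, tp = tp[[cc]], fp = fp[[cc]], fn = fn[[cc]],
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], stringsAsFactors = FALSE)
  }))
  rownames(by_cat) <- NULL
  structure(list(
    tp = sum(tp), fp = sum(fp), fn = sum(fn),
    precision = overall[["precision"]], recall = overall[["recall"]],
    f1 = overall[["f1"]], by_category = by_cat
  ), class = "deid_eval")
}

#' @export
print.deid_eval <- function(x, ...) {
  cat(sprintf("Strict entity-level evaluation (micro): P = %.2f  R = %.2f  F1 = %.2f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  TP = %d  FP = %d  FN = %d\n", x$tp, x$fp, x$fn))
  shown <- x$by_category[x$by_category$tp + x$by_category$fp +
                           x$by_category$fn > 0, , drop = FALSE]
  if (nrow(shown)) {
    shown$precision <- sprintf("%.2f", shown$precision)
    shown$recall <- sprintf("%.2f", shown$recall)
    shown$f1 <- sprintf("%.2f", shown$f1)
    print(shown, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname evaluate_deid
#' @param x a `deid_eval`.
#' @param path output path for a JSON report.
#' @export
write_eval_report <- function(x, path) {
  obj <- list(
    precision = round(x$precision, 2), recall = round(x$recall, 2),
    f1 = round(x$f1, 2), tp = x$tp, fp = x$fp, fn = x$fn,
    by_category = x$by_category
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
             path, useBytes = TRUE)
  invisible(path)
}
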