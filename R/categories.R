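#' PHI categories and their HIPAA grouping
#'
#' The 2014 i2b2 de-identification challenge extended the 18 HIPAA classes of
#' protected health information (PHI) into 23 fine-grained subcategories.
#' `phi_categories()` returns the closed set of subcategory names used
#' throughout the package; `phi_category_table()` additionally gives the
#' HIPAA parent class and the subcategory frequencies observed in the i2b2
#' training split, which the synthetic generator uses as default sampling
#' weights.
#'
#' @return `phi_categories()`: a character vector of 23 category names.
#'   `phi_category_table()`: a data.frame with columns `category`, `hipaa`
#'   and `weight`.
#' @examples
#' phi_categories()
#' head(phi_category_table())
#' @export
phi_categories <- function() {
  phi_category_table()$category
}

#' @rdname phi_categories
#' @export
phi_category_table <- function() {
  data.frame(
    category = c(
      "DATE",
      "DOCTOR", "PATIENT", "USERNAME",
      "AGE",
      "PHONE", "FAX", "EMAIL", "URL",
      "MEDICALRECORD", "IDNUM", "DEVICE", "BIOID", "HEALTHPLAN",
      "HOSPITAL", "CITY", "STATE", "STREET", "ZIP", "ORGANIZATION",
      "COUNTRY", "LOCATION-OTHER",
      "PROFESSION"
    ),
    hipaa = c(
      "DATE",
      "NAME", "NAME", "NAME",
      "AGE",
      "CONTACT", "CONTACT", "CONTACT", "CONTACT",
      "ID", "ID", "ID", "ID", "ID",
      "LOCATION", "LOCATION", "LOCATION", "LOCATION", "LOCATION",
      "LOCATION", "LOCATION", "LOCATION",
      "PROFESSION"
    ),
    weight = c(
      7502,
      2885, 1316, 264,
      1233,
      309, 8, 4, 2,
      611, 261, 7, 1, 1,
      1437, 394, 314, 216, 212, 124,
      66, 4,
      234
    ),
    stringsAsFactors = FALSE
  )
}

is_phi_category <- function(x) {
  x %in% phi_categories()
}

#' IOB tag helpers
#'
#' Per-token tags follow the IOB scheme: `"O"` for tokens outside any PHI,
#' `"B(CAT)"` for the first token of an entity of category `CAT`, and
#' `"I(CAT)"` for subsequent tokens.
#'
#' @param category a PHI category name.
#' @param tag an IOB tag string.
#' @return `iob_b()`/`iob_i()` build tags; `tag_category()` extracts the
#'   category (`NA` for `"O"`); `tag_kind()` returns `"B"`, `"I"` or `"O"`.
#' @examples
#' iob_b("DATE")
#' tag_category("I(HOSPITAL)")
#' @export
iob_b <- function(category) paste0("B(", category, ")")

#' @rdname iob_b
#' @export
iob_i <- function(category) paste0("I(", category, ")")

#' @rdname iob_b
#' @export
tag_category <- function(tag) {
  out <- rep(NA_character_, length(tag))
  hit <- grepl("^[BI]\\(.+\\)$", tag)
  out[hit] <- sub("^[BI]\\((.+)\\)$", "\\1", tag[hit])
  out
}

#' @rdname iob_b
#' @export
tag_kind <- function(tag) {
  ifelse(grepl("^B\\(", tag), "B", ifelse(grepl("^I\\(", tag), "I", "O"))
}

valid_tag <- function(tag) {
  tag == "O" | (tag_kind(tag) %in% c("B", "I") & is_phi_category(tag_category(tag)))
}
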