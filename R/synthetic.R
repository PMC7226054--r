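# Synthetic clinical-note generator. Documents interleave templated
# narrative with surrogate PHI sampled from small, clearly fictional
# lexicons; every inserted PHI is recorded with exact character offsets, so
# the generated corpora are drop-in gold standards for the whole pipeline.
# The generator targets structural coverage (all 23 categories, section
# headers, regex-matchable surface forms, subword-relevant chunks like
# "Dr.Smith"), not linguistic realism.

synth_lexicons <- function() {
  list(
    first = c("Harlan", "Talissa", "Edwin", "Fay", "Mirella", "Quentin",
              "Beatrix", "Orson", "Petra", "Silas", "Ingrid", "Casper",
              "Lavinia", "Duncan", "Ophelia", "Randal", "Sybil", "Toby",
              "Ursula", "Vernon", "Wilhelmina", "Xavier", "Yolanda",
              "Zebediah", "Annika", "Bartholomew"),
    last = c("Oneil", "Irish", "Foust", "Quimby", "Ashdown", "Birchwood",
             "Cavanagh", "Dunmore", "Eastgate", "Fairweather", "Greenhalgh",
             "Hollowell", "Ironside", "Jessop", "Kingsley", "Lockhart",
             "Marchbanks", "Norwood", "Oakhurst", "Pemberton", "Quill",
             "Ravenscroft", "Stroud", "Thackeray", "Underhill", "Vance"),
    hospital = c("Edwin HealthCare", "Marigold General Hospital",
                 "Saint Orchid Hospital", "Blue Finch Medical Center",
                 "Parkway Hospital", "Cedar Hollow Clinic",
                 "Harborview Memorial Hospital", "Twin Pines Hospital",
                 "Northgate Community Hospital", "Silver Birch Infirmary"),
    city = c("Sulphur", "Brightwater", "Cedar Hollow", "Graniteville",
             "Mosswood", "Pine Flats", "Quarry Bend", "Saltmarsh",
             "Thistledown", "Windmere"),
    state = c("Arkansas", "New Jersey", "New Hampshire", "Vermont",
              "North Dakota", "West Virginia", "Montana", "Delaware",
              "Rhode Island", "New Mexico"),
    street_name = c("Newburgh", "Alder", "Foxglove", "Juniper", "Larkspur",
                    "Mulberry", "Primrose", "Tamarack", "Wisteria", "Yarrow"),
    street_suffix = c("Street", "Avenue", "Lane", "Drive", "Road", "Circle",
                      "Place"),
    organization = c("Acme Farms", "Granite Works", "Beacon Textiles",
                     "Harvest Grocers", "Ironwood Timber", "Lantern Press"),
    country = c("Canada", "Portugal", "Norway", "Chile", "Morocco",
                "Iceland"),
    loc_other = c("Rose Garden Park", "Harbor Market", "Civic Arena"),
    profession = c("carpenter", "teacher", "electrician", "florist",
                   "machinist", "pharmacist", "welder", "librarian",
                   "plumber", "bookkeeper")
  )
}

#' Configuration for the synthetic note generator
#'
#' Category sampling weights default to the published training-split PHI
#' distribution (DATE most frequent at 7502, then DOCTOR 2885, PATIENT
#' 1316, ...), so generated corpora have DATE as the modal category and
#' realistic rarity for FAX/BIOID/HEALTHPLAN. `hard = TRUE` additionally
#' injects confusion material: four-digit lab values that look like dates
#' ("a CK of 1028"), and multi-token state names ("New Jersey") in
#' ambiguous travel sentences — the disagreements a rule/CRF ensemble has
#' to arbitrate.
#'
#' @param n_docs number of documents to generate.
#' @param weights named nonnegative numeric, sampling weight per category;
#'   default proportional to the published training counts.
#' @param phi_per_doc integer range, PHI entities per document.
#' @param hard inject confusion cases (default `FALSE`).
#' @param seed integer seed; the same configuration always yields a
#'   byte-identical corpus.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_docs = 100L, weights = NULL,
                             phi_per_doc = c(5L, 10L), hard = FALSE,
                             seed = 1L) {
  tab <- phi_category_table()
  w <- setNames(as.numeric(tab$weight), tab$category)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), tab$category)
    if (length(bad)) stop("unknown category in weights: ", bad[1],
                          call. = FALSE)
    w[names(weights)] <- as.numeric(weights)
  }
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be nonnegative with at least one positive",
         call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), weights = w,
                 phi_per_doc = as.integer(phi_per_doc), hard = hard,
                 seed = as.integer(seed)),
            class = "generator_config")
}

synth_surface <- function(category, lex) {
  pick <- function(x) x[sample.int(length(x), 1L)]
  switch(category,
    DATE = {
      style <- sample.int(3L, 1L)
      if (style == 1) {
        sprintf("%04d-%02d-%02d", sample(2060:2079, 1), sample(1:12, 1),
                sample(1:28, 1))
      } else if (style == 2) {
        sprintf("%02d-%02d-%02d", sample(1:28, 1), sample(1:12, 1),
                sample(60:79, 1))
      } else {
        sprintf("%04d", sample(2060:2079, 1))
      }
    },
    DOCTOR = if (runif(1) < 0.5) pick(lex$last) else
      paste(pick(lex$first), pick(lex$last)),
    PATIENT = paste(pick(lex$first), pick(lex$last)),
    USERNAME = paste0(
      paste(sample(letters, sample(2:3, 1), replace = TRUE), collapse = ""),
      " ", paste(sample(0:9, sample(2:3, 1), replace = TRUE), collapse = "")),
    AGE = as.character(sample(21:89, 1)),
    PHONE = sprintf("555-%03d-%04d", sample(100:999, 1), sample(0:9999, 1)),
    FAX = sprintf("555-%03d-%04d", sample(100:999, 1), sample(0:9999, 1)),
    EMAIL = paste0(tolower(pick(lex$first)), "@hmail.org"),
    URL = "www.clinicportal.org",
    MEDICALRECORD = sprintf("%08d", sample.int(9999999L, 1L) + 10000000L),
    IDNUM = paste0(paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
                   sprintf("%06d", sample.int(999999L, 1L))),
    DEVICE = sprintf("DEV-%04d", sample(1000:9999, 1)),
    BIOID = sprintf("%06d", sample.int(999999L, 1L)),
    HEALTHPLAN = sprintf("HP%07d", sample.int(9999999L, 1L)),
    HOSPITAL = pick(lex$hospital),
    CITY = pick(lex$city),
    STATE = pick(lex$state),
    STREET = paste(sample(100:999, 1), pick(lex$street_name),
                   pick(lex$street_suffix)),
    ZIP = sprintf("%05d", sample.int(99999L, 1L)),
    ORGANIZATION = pick(lex$organization),
    COUNTRY = pick(lex$country),
    `LOCATION-OTHER` = pick(lex$loc_other),
    PROFESSION = pick(lex$profession),
    stop("no surface generator for category ", category, call. = FALSE)
  )
}

synth_carriers <- function() {
  list(
    DATE = c("Seen on {PHI} for follow up .",
             "Visit scheduled for {PHI} .",
             "Discharged home on {PHI} ."),
    DOCTOR = c("Seen by Dr . {PHI} in clinic .",
               "Evaluated today by Dr.{PHI} .",
               "Plan discussed with Dr . {PHI} ."),
    PATIENT = c("{PHI} presents for evaluation .",
                "Family contact for {PHI} updated ."),
    USERNAME = c("Electronically signed by {PHI} ."),
    AGE = c("This is a {PHI} year old patient .",
            "The patient is {PHI} years old ."),
    PHONE = c("Call {PHI} with any results ."),
    FAX = c("Fax the report to {PHI} ."),
    EMAIL = c("Questions may be sent to {PHI} ."),
    URL = c("Instructions posted at {PHI} ."),
    MEDICALRECORD = c("MRN {PHI} confirmed at registration ."),
    IDNUM = c("Case number {PHI} was assigned ."),
    DEVICE = c("Device id {PHI} was implanted ."),
    BIOID = c("Biometric id {PHI} is on file ."),
    HEALTHPLAN = c("Health plan {PHI} remains active ."),
    HOSPITAL = c("Transferred to {PHI} overnight .",
                 "Previously admitted at {PHI} ."),
    CITY = c("Lives in {PHI} with family ."),
    STATE = c("Moved here from {PHI} last year ."),
    STREET = c("Resides at {PHI} in town ."),
    ZIP = c("Mailing zip is {PHI} for correspondence ."),
    ORGANIZATION = c("Employed by {PHI} for years ."),
    COUNTRY = c("Traveled to {PHI} recently ."),
    `LOCATION-OTHER` = c("Collapsed near the {PHI} yesterday ."),
    PROFESSION = c("Works as a {PHI} locally .")
  )
}

synth_fillers <- function() {
  c("The patient reports mild chest pain for three days .",
    "Vital signs were stable on arrival .",
    "No acute distress was noted on exam .",
    "Breath sounds are clear bilaterally .",
    "Medications were reviewed and continued .",
    "Follow up as needed for recurrent symptoms .")
}

synth_confusions <- function() {
  c("A CK of {NUM} was noted on labs .",
    "With SVR of {NUM} on pressors .",
    "Platelet count {NUM} this morning .",
    "Repeat glucose of {NUM} after insulin .")
}

#' Generate a synthetic annotated corpus
#'
#' Each document starts with a `"Record date:"` header carrying a DATE
#' entity, followed by an `"HPI:"` section mixing single-PHI carrier
#' sentences (categories sampled from the configured weights), PHI-free
#' filler, and — in hard mode — number confusion sentences. Every entity's
#' surface string equals the document substring at its recorded offsets,
#' spans never overlap, and empirical category frequencies converge to the
#' configured weights.
#'
#' @param config a [generator_config()].
#' @return a list of [annotated_document()]s.
#' @examples
#' docs <- generate_corpus(generator_config(n_docs = 2, seed = 7))
#' docs[[1]]
#' @export
generate_corpus <- function(config = generator_config()) {
  set.seed(config$seed)
  lex <- synth_lexicons()
  carriers <- synth_carriers()
  fillers <- synth_fillers()
  confusions <- synth_confusions()
  lapply(seq_len(config$n_docs), function(d) {
    n_phi <- sample(config$phi_per_doc[1]:config$phi_per_doc[2], 1L)
    cats <- sample(names(config$weights), n_phi, replace = TRUE,
                   prob = config$weights)
    lines <- character(0)
    starts <- integer(0); ends <- integer(0); ecat <- character(0)
    cursor <- 0L
    add_line <- function(line) {
      lines <<- c(lines, line)
      cursor <<- cursor + nchar(line) + 1L  # newline-terminated
    }
    add_carrier <- function(template, category, surface) {
      at <- regexpr("{PHI}", template, fixed = TRUE)
      prefix <- substr(template, 1L, at - 1L)
      suffix <- substr(template, at + 5L, nchar(template))
      starts <<- c(starts, cursor + nchar(prefix))
      ends <<- c(ends, cursor + nchar(prefix) + nchar(surface))
      ecat <<- c(ecat, category)
      add_line(paste0(prefix, surface, suffix))
    }
    # header with a guaranteed DATE, then the HPI section
    add_carrier("Record date: {PHI}", "DATE", synth_surface("DATE", lex))
    add_line("HPI:")
    for (cat_i in cats) {
      tmpl <- carriers[[cat_i]][sample.int(length(carriers[[cat_i]]), 1L)]
      add_carrier(tmpl, cat_i, synth_surface(cat_i, lex))
      if (runif(1) < 0.35) {
        add_line(fillers[sample.int(length(fillers), 1L)])
      }
      if (config$hard && runif(1) < 0.4) {
        conf <- confusions[sample.int(length(confusions), 1L)]
        add_line(sub("{NUM}", sprintf("%04d", sample(1000:4999, 1)), conf,
                     fixed = TRUE))
      }
    }
    text <- paste0(paste(lines, collapse = "\n"), "\n")
    annotated_document(
      sprintf("synth-%04d", d), text,
      phi_entities(starts, ends, ecat, source_text = text)
    )
  })
}

#' Build a planted-rule corpus for transformation-learner recovery tests
#'
#' Gold tags are computed by [encode_iob()]; initial tags are derived from
#' gold by applying each corruption at every qualifying site (e.g. "retag
#' `I(HOSPITAL)` as `O` wherever the token is `Hospital`"), so the inverse
#' transformations are exactly recoverable. Each corruption must be
#' expressible by a shipped rule template — a template containing its
#' `(feature, offset)` condition must exist — otherwise an error is raised.
#'
#' @param docs a list of [annotated_document()]s.
#' @param corruptions a list of corruption specs, each
#'   `list(feature, offset, value, from, to)`.
#' @param templates the template inventory the learner will use.
#' @param tagger external POS/NER tagger for the feature tables.
#' @return a list with `tokens`, `features`, `init_tags`, `gold_tags` (one
#'   element per document) and `site_counts` (sites per corruption).
#' @export
plant_rule_corpus <- function(docs, corruptions,
                              templates = default_templates(),
                              tagger = heuristic_pos_ner) {
  for (cr in corruptions) {
    hit <- any(vapply(templates, function(t) {
      any(t$conds$feature == cr$feature & t$conds$offset == cr$offset)
    }, logical(1)))
    if (!hit) {
      stop(sprintf(
        "corruption on %s@%d is not expressible by any shipped template",
        cr$feature, cr$offset), call. = FALSE)
    }
    if (identical(cr$from, cr$to)) {
      stop("corruption must change the tag", call. = FALSE)
    }
  }
  tokens <- lapply(docs, function(d) tokenize(d$text))
  features <- mapply(function(d, tt) feature_table(d$text, tt, tagger),
                     docs, tokens, SIMPLIFY = FALSE)
  gold_tags <- mapply(function(d, tt) encode_iob(tt, d$entities),
                      docs, tokens, SIMPLIFY = FALSE)
  init_tags <- gold_tags
  site_counts <- integer(length(corruptions))
  for (ci in seq_along(corruptions)) {
    cr <- corruptions[[ci]]
    for (d in seq_along(docs)) {
      vals <- shift_feature(features[[d]][[cr$feature]], cr$offset)
      sites <- which(vals == cr$value & gold_tags[[d]] == cr$from)
      init_tags[[d]][sites] <- cr$to
      site_counts[ci] <- site_counts[ci] + length(sites)
    }
  }
  list(tokens = tokens, features = features, init_tags = init_tags,
       gold_tags = gold_tags, site_counts = site_counts)
}
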