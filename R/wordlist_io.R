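#' Read a wordlist from CLDF-style tables
#'
#' Reads three delimited tables — forms, languages, concepts — and assembles
#' a validated wordlist. The forms table follows the CLDF FormTable dialect
#' (`Language_ID`, `Parameter_ID`, `Form`, optional space-separated
#' `Segments`); the languages table has `ID`, `Family` and optionally
#' `Glottocode`, `Latitude`, `Longitude`; the concept list has `ID`,
#' `Gloss`, `Domain`. The delimiter is auto-detected from the file
#' extension (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' On load, duplicated (variety, concept, form) triples are collapsed to one
#' record, rows with an empty form are removed, and rows whose variety or
#' concept does not resolve against the metadata tables are dropped; all
#' removals are counted in the attached load report.
#'
#' @param forms_path,languages_path,concepts_path File paths.
#' @return A `colex_wordlist`: a list with tibbles `forms`
#'   (`variety_id`, `concept_id`, `form`, `segments`), `varieties`
#'   (`variety_id`, `glottocode`, `family`, `latitude`, `longitude`),
#'   `concepts` (`concept_id`, `gloss`, `domain`) and a `report` list
#'   counting raw, deduplicated and dropped rows.
#' @export
read_wordlist <- function(forms_path, languages_path, concepts_path) {
  forms_raw <- read_auto(forms_path)
  langs_raw <- read_auto(languages_path)
  conc_raw <- read_auto(concepts_path)

  require_columns(forms_raw, c("Language_ID", "Parameter_ID", "Form"),
                  "forms")
  require_columns(langs_raw, c("ID", "Family"), "languages")
  require_columns(conc_raw, c("ID", "Gloss", "Domain"), "concepts")
  if (nrow(forms_raw) == 0) abort("forms table is empty")

  varieties <- tibble(
    variety_id = as.character(langs_raw$ID),
    glottocode = chr_or_na(langs_raw, "Glottocode"),
    family = as.character(langs_raw$Family),
    latitude = num_or_na(langs_raw, "Latitude"),
    longitude = num_or_na(langs_raw, "Longitude")
  )
  if (anyDuplicated(varieties$variety_id)) {
    abort("duplicated variety IDs in languages table")
  }
  concepts <- tibble(
    concept_id = as.character(conc_raw$ID),
    gloss = as.character(conc_raw$Gloss),
    domain = as.character(conc_raw$Domain)
  )
  if (anyDuplicated(concepts$concept_id)) {
    abort("duplicated concept IDs in concept list")
  }
  bad_domain <- setdiff(unique(concepts$domain),
                        c("body", "colour", "emotion"))
  if (length(bad_domain) > 0) {
    abort(paste0("unknown concept domain(s): ",
                 paste(bad_domain, collapse = ", ")))
  }

  forms <- tibble(
    variety_id = as.character(forms_raw$Language_ID),
    concept_id = as.character(forms_raw$Parameter_ID),
    form = trimws(as.character(forms_raw$Form)),
    segments = chr_or_na(forms_raw, "Segments")
  )
  n_raw <- nrow(forms)
  forms <- filter(forms, !is.na(.data$form) & .data$form != "")
  n_empty <- n_raw - nrow(forms)
  before_dedup <- nrow(forms)
  forms <- distinct(forms, .data$variety_id, .data$concept_id, .data$form,
                    .keep_all = TRUE)
  n_dup <- before_dedup - nrow(forms)
  resolvable <- forms$variety_id %in% varieties$variety_id &
    forms$concept_id %in% concepts$concept_id
  n_dropped <- sum(!resolvable)
  forms <- forms[resolvable, ]

  new_wordlist(forms, varieties, concepts,
               report = list(n_raw = n_raw, n_empty_form = n_empty,
                             n_duplicates = n_dup, dropped = n_dropped,
                             n_forms = nrow(forms)))
}

new_wordlist <- function(forms, varieties, concepts, report = list()) {
  structure(
    list(forms = as_tibble(forms), varieties = as_tibble(varieties),
         concepts = as_tibble(concepts), report = report),
    class = "colex_wordlist"
  )
}

#' @export
print.colex_wordlist <- function(x, ...) {
  cat(sprintf(
    "<colex_wordlist> %d forms, %d varieties (%d families), %d concepts\n",
    nrow(x$forms), nrow(x$varieties), n_distinct(x$varieties$family),
    nrow(x$concepts)
  ))
  invisible(x)
}

#' Write a wordlist back to CLDF-style tables
#'
#' Writes `forms.csv`, `languages.csv` and `concepts.tsv` into `dir` in the
#' same dialects [read_wordlist()] reads, so loading is idempotent:
#' read, write, read yields an identical wordlist.
#'
#' @param wl A `colex_wordlist`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_wordlist <- function(wl, dir) {
  stopifnot(inherits(wl, "colex_wordlist"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(
    tibble(Language_ID = wl$forms$variety_id,
           Parameter_ID = wl$forms$concept_id,
           Form = wl$forms$form, Segments = wl$forms$segments),
    file.path(dir, "forms.csv")
  )
  readr::write_csv(
    tibble(ID = wl$varieties$variety_id, Glottocode = wl$varieties$glottocode,
           Family = wl$varieties$family, Latitude = wl$varieties$latitude,
           Longitude = wl$varieties$longitude),
    file.path(dir, "languages.csv")
  )
  readr::write_tsv(
    tibble(ID = wl$concepts$concept_id, Gloss = wl$concepts$gloss,
           Domain = wl$concepts$domain),
    file.path(dir, "concepts.tsv")
  )
  invisible(dir)
}

read_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.(tsv|tab)$", tolower(path))) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s) in ", what, " table: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

chr_or_na <- function(df, col) {
  if (col %in% names(df)) as.character(df[[col]]) else
    rep(NA_character_, nrow(df))
}

num_or_na <- function(df, col) {
  if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else
    rep(NA_real_, nrow(df))
}

#' Keep only datasets with broad concept coverage
#'
#' Retains wordlists whose number of distinct attested concepts is at least
#' `min_concepts`. Mirrors the inclusion rule used when assembling large
#' cross-linguistic samples: only wordlist datasets covering at least 250
#' concepts enter the analysis.
#'
#' @param wordlists A list of `colex_wordlist` objects (one per source
#'   dataset).
#' @param min_concepts Inclusive lower bound on distinct concepts.
#' @return The filtered list (possibly empty).
#' @export
filter_datasets <- function(wordlists, min_concepts = 250) {
  stopifnot(is.list(wordlists))
  keep <- vapply(wordlists, function(wl) {
    stopifnot(inherits(wl, "colex_wordlist"))
    n_distinct(wl$forms$concept_id) >= min_concepts
  }, logical(1))
  wordlists[keep]
}

#' Apply the concept inclusion filter
#'
#' A concept is kept when it is well attested across language families.
#' Under the default `rule = "per_family"`, a concept is retained iff at
#' least `min_families` families each contribute at least `min_words`
#' attested word forms for it. The alternative `rule = "total"` keeps a
#' concept iff it has at least `min_words` forms in total and is attested
#' in at least `min_families` families. Both readings of the exclusion
#' criterion are exposed; per-family is the default.
#'
#' @param wl A `colex_wordlist` whose varieties carry family labels.
#' @param min_words Minimum attested word forms (per family, or in total).
#' @param min_families Minimum number of qualifying families.
#' @param rule Which reading of the filter to apply.
#' @return A tibble of retained concept rows (`concept_id`, `gloss`,
#'   `domain`), a subset of `wl$concepts`.
#' @export
filter_concepts <- function(wl, min_words = 5, min_families = 10,
                            rule = c("per_family", "total")) {
  stopifnot(inherits(wl, "colex_wordlist"))
  rule <- match.arg(rule)
  fam <- wl$forms |>
    left_join(select(wl$varieties, "variety_id", "family"),
              by = "variety_id")
  kept <- if (rule == "per_family") {
    fam |>
      count(.data$concept_id, .data$family, name = "n_words") |>
      filter(.data$n_words >= min_words) |>
      count(.data$concept_id, name = "n_fam_ok") |>
      filter(.data$n_fam_ok >= min_families) |>
      pull("concept_id")
  } else {
    fam |>
      group_by(.data$concept_id) |>
      summarise(n_words = n(), n_fam = n_distinct(.data$family)) |>
      filter(.data$n_words >= min_words, .data$n_fam >= min_families) |>
      pull("concept_id")
  }
  filter(wl$concepts, .data$concept_id %in% kept)
}
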