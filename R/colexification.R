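#' Normalise an orthographic word form
#'
#' Lower-cases the form, removes parenthesised material (annotations such as
#' `"lima (archaic)"`), collapses internal whitespace runs to single spaces
#' and strips leading/trailing whitespace. Forms that become empty are
#' unusable for colexification matching and are returned as `NA`.
#'
#' @param form Character vector of raw forms.
#' @return Character vector of normalised forms; `NA` where the result is
#'   empty.
#' @export
#' @examples
#' normalize_form(c(" Laŋ ", "lima (archaic)", "foot  bone"))
normalize_form <- function(form) {
  out <- gsub("\\([^)]*\\)", "", as.character(form))
  out <- tolower(trimws(gsub("\\s+", " ", out)))
  ifelse(is.na(out) | out == "", NA_character_, out)
}

#' Full colexifications attested in one language variety
#'
#' Two distinct concepts are colexified in a variety when the variety uses
#' at least one identical normalised word form for both (full
#' colexification: whole-form identity). Forms shorter than
#' `min_form_length` characters are ignored to suppress chance identity of
#' very short forms. Each concept pair is reported at most once per
#' variety, regardless of how many shared synonym forms exist; the
#' lexically smallest shared form is kept as the representative.
#'
#' @param wl A `colex_wordlist`.
#' @param variety_id A single variety present in `wl`.
#' @param concepts Tibble of concepts (as from [filter_concepts()]) to
#'   restrict the search to; defaults to all concepts in `wl`.
#' @param min_form_length Minimum normalised form length in characters.
#' @return Tibble with columns `concept_a`, `concept_b` (canonical order)
#'   and `form` (the shared normalised form).
#' @export
find_variety_colexifications <- function(wl, variety_id, concepts = NULL,
                                         min_form_length = 2) {
  stopifnot(inherits(wl, "colex_wordlist"))
  if (!variety_id %in% wl$varieties$variety_id) {
    abort(paste0("unknown variety: ", variety_id))
  }
  concepts <- concepts %||% wl$concepts
  vid <- variety_id
  fr <- wl$forms |>
    filter(.data$variety_id == vid,
           .data$concept_id %in% concepts$concept_id) |>
    mutate(nform = normalize_form(.data$form)) |>
    filter(!is.na(.data$nform), nchar(.data$nform) >= min_form_length) |>
    distinct(.data$concept_id, .data$nform, .keep_all = TRUE)
  if (nrow(fr) < 2) {
    return(tibble(concept_a = character(0), concept_b = character(0),
                  form = character(0)))
  }
  shared <- split(fr, fr$nform)
  shared <- shared[vapply(shared, function(g) n_distinct(g$concept_id) >= 2,
                          logical(1))]
  if (length(shared) == 0) {
    return(tibble(concept_a = character(0), concept_b = character(0),
                  form = character(0)))
  }
  pairs <- bind_rows(lapply(shared, function(g) {
    ids <- concept_sort(unique(g$concept_id))
    cp <- t(combn(ids, 2))
    tibble(concept_a = cp[, 1], concept_b = cp[, 2], form = g$nform[[1]])
  }))
  pairs |>
    arrange(.data$concept_a, .data$concept_b, .data$form) |>
    distinct(.data$concept_a, .data$concept_b, .keep_all = TRUE)
}

#' Build a weighted colexification network from a wordlist
#'
#' Scans every variety for full colexifications among `concepts` and
#' aggregates them into one edge per concept pair, counting the distinct
#' attesting varieties and families. `cognate_set_count` is initialised to
#' `family_count` (one inherited colexification per family) until
#' [refine_network_counts()] clusters the witnessing forms into cognate
#' sets. Nodes are all concepts attested in the wordlist, so isolated
#' concepts (never colexified) remain part of the network.
#'
#' @inheritParams find_variety_colexifications
#' @param concepts Tibble of concepts defining the semantic domain of the
#'   network (pairs are only built within this list).
#' @param weight_field Which count serves as the edge weight.
#' @return A [new_colex_network()] object with witness records attached.
#' @export
build_network <- function(wl, concepts = NULL,
                          weight_field = c("varieties", "families",
                                           "cognates"),
                          min_form_length = 2) {
  stopifnot(inherits(wl, "colex_wordlist"))
  weight_field <- match.arg(weight_field)
  concepts <- concepts %||% wl$concepts
  if (nrow(concepts) == 0) abort("empty concept list")

  fams <- select(wl$varieties, "variety_id", "family")
  attested_vids <- intersect(wl$varieties$variety_id,
                             unique(wl$forms$variety_id))
  wit <- purrr::map(attested_vids, function(v) {
    px <- find_variety_colexifications(wl, v, concepts, min_form_length)
    if (nrow(px) == 0) return(NULL)
    px$variety_id <- v
    px
  }) |> bind_rows()

  nodes <- concepts |>
    semi_join(wl$forms, by = "concept_id")

  if (is.null(wit) || nrow(wit) == 0) {
    return(new_colex_network(
      nodes,
      tibble(concept_a = character(0), concept_b = character(0),
             variety_count = integer(0), family_count = integer(0),
             cognate_set_count = integer(0)),
      witnesses = tibble(concept_a = character(0), concept_b = character(0),
                         variety_id = character(0), family = character(0),
                         form = character(0), segments = character(0)),
      scope = "global", weight_field = weight_field,
      n_varieties = length(attested_vids)
    ))
  }

  wit <- wit |>
    left_join(fams, by = "variety_id") |>
    left_join(
      wl$forms |>
        mutate(nform = normalize_form(.data$form)) |>
        select("variety_id", concept_id_a = "concept_id",
               form_match = "nform", "segments") |>
        distinct(.data$variety_id, .data$concept_id_a, .data$form_match,
                 .keep_all = TRUE),
      by = c(variety_id = "variety_id", concept_a = "concept_id_a",
             form = "form_match")
    ) |>
    select("concept_a", "concept_b", "variety_id", "family", "form",
           "segments")

  edges <- wit |>
    group_by(.data$concept_a, .data$concept_b) |>
    summarise(
      variety_count = n_distinct(.data$variety_id),
      family_count = n_distinct(.data$family),
      .groups = "drop"
    ) |>
    mutate(cognate_set_count = .data$family_count) |>
    arrange(.data$concept_a, .data$concept_b)

  new_colex_network(nodes, edges, witnesses = wit, scope = "global",
                    weight_field = weight_field,
                    n_varieties = length(attested_vids))
}

#' Restrict a colexification network to one language family
#'
#' Recomputes every edge using only the witnesses from the given family;
#' edges with no witness in the family are removed and edge weight becomes
#' the within-family variety count (edge thickness in family network
#' figures). Nodes are the concepts attested by the family's varieties.
#' `n_varieties` records how many of the family's varieties are attested in
#' the wordlist, for degree normalisation.
#'
#' @param net A `colex_network` built by [build_network()] (witnesses
#'   required).
#' @param wl The `colex_wordlist` the network was built from.
#' @param family Family name, present in `wl$varieties$family`.
#' @return A `colex_network` with `scope = family`.
#' @export
subnetwork_by_family <- function(net, wl, family) {
  stopifnot(inherits(net, "colex_network"), inherits(wl, "colex_wordlist"))
  if (!family %in% wl$varieties$family) {
    abort(paste0("unknown family: ", family))
  }
  if (is.null(net$witnesses)) {
    abort("network has no witness records; build it with build_network()")
  }
  fam_vids <- wl$varieties$variety_id[wl$varieties$family == family]
  fam_attested <- intersect(fam_vids, unique(wl$forms$variety_id))

  nodes <- net$nodes |>
    semi_join(filter(wl$forms, .data$variety_id %in% fam_vids),
              by = "concept_id")
  wit <- filter(net$witnesses, .data$variety_id %in% fam_vids)
  edges <- wit |>
    group_by(.data$concept_a, .data$concept_b) |>
    summarise(variety_count = n_distinct(.data$variety_id),
              .groups = "drop") |>
    mutate(family_count = 1L, cognate_set_count = 1L) |>
    arrange(.data$concept_a, .data$concept_b)

  new_colex_network(nodes, edges, witnesses = wit, scope = family,
                    weight_field = "varieties",
                    n_varieties = length(fam_attested))
}
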