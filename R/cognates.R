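#' Normalised edit distance between word forms
#'
#' Levenshtein distance over phonetic segment tokens, divided by the length
#' of the longer form, giving a symmetric dissimilarity in \[0, 1\]. A form
#' containing whitespace is treated as a space-separated segment string
#' (`"l i m a"` is four segments); a form without whitespace is compared
#' character by character. Comparing sound segments rather than raw
#' orthography is what makes the distance usable for cognate clustering.
#'
#' @param x,y Character vectors of forms or segment strings (recycled to a
#'   common length).
#' @return Numeric vector of distances in \[0, 1\].
#' @export
#' @examples
#' form_distance("l i m a", "n i m a") # one substitution over four segments
form_distance <- function(x, y) {
  x <- as.character(x)
  y <- as.character(y)
  if (length(x) != length(y)) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n)
    y <- rep_len(y, n)
  }
  if (any(is.na(x) | is.na(y) | x == "" | y == "")) {
    abort("form_distance requires non-empty forms")
  }
  mapply(form_distance1, x, y, USE.NAMES = FALSE)
}

tokenize_form <- function(s) {
  s <- trimws(s)
  if (grepl("\\s", s)) strsplit(s, "\\s+")[[1]] else strsplit(s, "")[[1]]
}

form_distance1 <- function(x, y) {
  tx <- tokenize_form(x)
  ty <- tokenize_form(y)
  if (length(tx) == 0 || length(ty) == 0) abort("empty form after tokenization")
  vocab <- unique(c(tx, ty))
  # encode each token as one unicode codepoint so utils::adist computes a
  # token-level Levenshtein distance
  ex <- intToUtf8(match(tx, vocab) + 256L)
  ey <- intToUtf8(match(ty, vocab) + 256L)
  as.numeric(adist(ex, ey)) / max(length(tx), length(ty))
}

#' Cluster the witnesses of one colexification into cognate sets
#'
#' Single-linkage flat clustering: witnesses are vertices, an edge connects
#' two witnesses whose [form_distance()] is at most `threshold`, and the
#' connected components are the cognate sets. At `threshold = 0` only
#' identical forms cluster; at `threshold = 1` all witnesses merge into one
#' set. Set ids are assigned deterministically, ordered by the smallest
#' member `variety_id`.
#'
#' @param witnesses Tibble with `variety_id` and `form` (and optionally
#'   `segments`, preferred for the distance when present), all from one
#'   (family, concept pair).
#' @param threshold Distance cutoff in \[0, 1\].
#' @return The witnesses tibble with an integer `set_id` column, rows in
#'   input order.
#' @export
cluster_cognates <- function(witnesses, threshold = 0.45) {
  witnesses <- as_tibble(witnesses)
  stopifnot(all(c("variety_id", "form") %in% names(witnesses)))
  n <- nrow(witnesses)
  if (n == 0) {
    witnesses$set_id <- integer(0)
    return(witnesses)
  }
  rep_form <- if ("segments" %in% names(witnesses)) {
    coalesce(witnesses$segments, witnesses$form)
  } else {
    witnesses$form
  }
  comp <- seq_len(n)
  if (n > 1) {
    idx <- t(combn(n, 2))
    d <- form_distance(rep_form[idx[, 1]], rep_form[idx[, 2]])
    linked <- idx[d <= threshold, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(linked) > 0) g <- igraph::add_edges(g, t(linked))
    comp <- as.integer(igraph::components(g)$membership)
  }
  # deterministic ids: components ordered by their smallest member
  # variety_id (form as tie-break when one variety has synonym witnesses)
  members <- split(seq_len(n), comp)
  key <- vapply(members, function(ix) {
    paste(concept_sort(witnesses$variety_id[ix])[1],
          concept_sort(rep_form[ix])[1])
  }, character(1))
  ord <- order(key, as.integer(names(members)), method = "radix")
  remap <- setNames(seq_along(ord), names(members)[ord])
  witnesses$set_id <- as.integer(remap[as.character(comp)])
  witnesses
}

#' Refine colexification counts by cognate clustering
#'
#' For every edge, clusters the witnessing forms within each family into
#' cognate sets and replaces `cognate_set_count` by the total number of
#' sets across families. A colexification transmitted from a common
#' ancestor to many related varieties is thereby counted once per origin
#' rather than once per variety, while independent innovations of the same
#' colexification within a family still count separately. The invariant
#' `family_count <= cognate_set_count <= variety_count` holds on the
#' result.
#'
#' @param net A `colex_network` with witness records.
#' @param wl Unused; accepted for pipeline symmetry.
#' @param threshold Cognate distance cutoff passed to
#'   [cluster_cognates()].
#' @return The network with refined `cognate_set_count` (and refreshed
#'   weights when `weight_field = "cognates"`).
#' @export
refine_network_counts <- function(net, wl = NULL, threshold = 0.45) {
  stopifnot(inherits(net, "colex_network"))
  if (nrow(net$edges) == 0) return(net)
  if (is.null(net$witnesses)) {
    abort("network has no witness records; build it with build_network()")
  }
  counts <- net$witnesses |>
    group_by(.data$concept_a, .data$concept_b, .data$family) |>
    summarise(
      n_sets = max(cluster_cognates(
        dplyr::pick("variety_id", "form", "segments"),
        threshold = threshold
      )$set_id),
      .groups = "drop"
    ) |>
    group_by(.data$concept_a, .data$concept_b) |>
    summarise(cognate_set_count = as.integer(sum(.data$n_sets)),
              .groups = "drop")
  net$edges <- net$edges |>
    select(-"cognate_set_count") |>
    left_join(counts, by = c("concept_a", "concept_b"))
  net$edges <- set_edge_weight(net$edges, net$weight_field)
  net
}

#' Export cognate sets for every edge of a network
#'
#' @param net A refined `colex_network` with witnesses.
#' @param threshold Cognate distance cutoff.
#' @return Tibble with one row per witness: `family`, `concept_a`,
#'   `concept_b`, `set_id`, `variety_id`, `form`.
#' @export
cognate_sets <- function(net, threshold = 0.45) {
  stopifnot(inherits(net, "colex_network"))
  if (is.null(net$witnesses) || nrow(net$witnesses) == 0) {
    return(tibble(family = character(0), concept_a = character(0),
                  concept_b = character(0), set_id = integer(0),
                  variety_id = character(0), form = character(0)))
  }
  net$witnesses |>
    group_by(.data$concept_a, .data$concept_b, .data$family) |>
    dplyr::group_modify(~ cluster_cognates(.x, threshold = threshold)) |>
    ungroup() |>
    select("family", "concept_a", "concept_b", "set_id", "variety_id",
           "form")
}
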