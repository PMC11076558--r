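#' Read a perceptual-feature coding table
#'
#' Colexified concept pairs are coded 0/1 for three perceptual features:
#' spatial *contiguity* (the parts are adjacent on the body), shared
#' *function* (e.g. hand and arm both grasp/reach), and shared *shape*
#' (e.g. head and knee as rounded protrusions). Multiple features may be
#' present for one pair; all-zero rows are permitted but flagged.
#'
#' The packaged example table
#' (`system.file("extdata", "feature_coding_synthetic.tsv", package =
#' "colexnet")`) contains the two attested codings documented for hand–arm
#' (contiguity 1, function 1, shape 0) and head–knee (contiguity 0,
#' function 0, shape 1), plus synthetic placeholder codings for other
#' frequent pairs — replace it with a complete coding for real analyses.
#'
#' @param path TSV with columns `ConceptA`, `ConceptB`, `Contiguity`,
#'   `Function`, `Shape` (0/1).
#' @return Tibble with `concept_a`, `concept_b` (canonical order),
#'   `contiguity`, `function`, `shape` and attribute `all_zero` listing
#'   flagged pairs.
#' @export
read_feature_coding <- function(path) {
  raw <- read_auto(path)
  require_columns(raw, c("ConceptA", "ConceptB", "Contiguity", "Function",
                         "Shape"), "feature coding")
  cp <- canonical_pair(raw$ConceptA, raw$ConceptB)
  out <- tibble(
    concept_a = cp$concept_a,
    concept_b = cp$concept_b,
    contiguity = as.integer(raw$Contiguity),
    `function` = as.integer(raw$Function),
    shape = as.integer(raw$Shape)
  )
  vals <- c(out$contiguity, out$`function`, out$shape)
  if (!all(vals %in% c(0L, 1L))) abort("feature codings must be 0 or 1")
  zero <- out[out$contiguity + out$`function` + out$shape == 0, ]
  attr(out, "all_zero") <- zero
  out
}

#' Body-region lookup for the bundled body concepts
#'
#' @return Tibble with `concept_id`, `gloss` and `region` (head, upper
#'   limb, trunk, lower limb) for the 36 bundled body-part concepts.
#' @export
body_regions <- function() {
  path <- system.file("extdata", "body_regions.tsv", package = "colexnet")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  tibble(concept_id = raw$ID, gloss = raw$Gloss, region = raw$Region)
}

#' The bundled body-part concept list
#'
#' The 36 body-part concepts (Concepticon-style ids) that survive the
#' cross-linguistic inclusion filter, with glosses and domain `"body"`.
#'
#' @return Tibble with `concept_id`, `gloss`, `domain`.
#' @export
body_concepts <- function() {
  path <- system.file("extdata", "body_concepts.tsv", package = "colexnet")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  tibble(concept_id = raw$ID, gloss = raw$Gloss, domain = raw$Domain)
}

#' Feature-restricted colexification subnetwork
#'
#' Keeps only the edges whose coding marks the requested perceptual
#' feature present, and annotates nodes with their body region (for the
#' bundled body concepts). Every edge of the network must be covered by
#' the coding table.
#'
#' @param net A `colex_network`.
#' @param coding Tibble from [read_feature_coding()].
#' @param feature One of `"contiguity"`, `"function"`, `"shape"`.
#' @return A `colex_network` whose nodes carry a `region` column.
#' @export
feature_subnetworks <- function(net, coding,
                                feature = c("contiguity", "function",
                                            "shape")) {
  stopifnot(inherits(net, "colex_network"))
  feature <- match.arg(feature)
  cov <- left_join(net$edges[, c("concept_a", "concept_b")], coding,
                   by = c("concept_a", "concept_b"))
  uncovered <- cov[is.na(cov[[feature]]), c("concept_a", "concept_b")]
  if (nrow(uncovered) > 0) {
    abort(paste0(
      "edges not covered by the feature coding: ",
      paste(paste(uncovered$concept_a, uncovered$concept_b, sep = "-"),
            collapse = ", ")
    ))
  }
  keep <- cov[[feature]] == 1L
  edges <- net$edges[keep, ]
  wit <- if (!is.null(net$witnesses)) {
    semi_join(net$witnesses, edges, by = c("concept_a", "concept_b"))
  }
  nodes <- net$nodes |>
    left_join(select(body_regions(), "concept_id", "region"),
              by = "concept_id")
  new_colex_network(nodes, edges, witnesses = wit,
                    scope = paste0(net$scope, ":", feature),
                    weight_field = net$weight_field,
                    n_varieties = net$n_varieties)
}

#' Per-family perceptual-feature counts and proportions
#'
#' For each family network, counts the colexified pairs whose coding marks
#' each feature present (a pair coded for two features increments both
#' counts) and normalises counts to proportions. `total` is the family's
#' number of distinct colexified pairs (the pie-chart size in
#' feature-distribution maps).
#'
#' @param nets Named list (family -> `colex_network`).
#' @param coding Tibble from [read_feature_coding()]; must cover every
#'   edge of every network.
#' @return Tibble with `family`, `feature`, `count`, `proportion`,
#'   `total`.
#' @export
family_feature_proportions <- function(nets, coding) {
  stopifnot(is.list(nets), !is.null(names(nets)))
  feats <- c("contiguity", "function", "shape")
  purrr::map(sort(names(nets)), function(f) {
    net <- nets[[f]]
    ed <- left_join(net$edges[, c("concept_a", "concept_b")], coding,
                    by = c("concept_a", "concept_b"))
    if (anyNA(ed$contiguity)) {
      miss <- ed[is.na(ed$contiguity), ]
      abort(paste0("family ", f, ": edges not covered by coding: ",
                   paste(paste(miss$concept_a, miss$concept_b, sep = "-"),
                         collapse = ", ")))
    }
    counts <- unname(vapply(feats, function(ft) sum(ed[[ft]]), numeric(1)))
    tot_feat <- sum(counts)
    tibble(
      family = f,
      feature = feats,
      count = as.integer(counts),
      proportion = if (tot_feat > 0) counts / tot_feat else rep(NA_real_, 3),
      total = nrow(ed)
    )
  }) |> bind_rows()
}

#' Language-family homeland by recursive spherical centroid
#'
#' Computes a representative geographic origin point for a set of language
#' varieties. Without a tree, the point is the spherical centroid of all
#' variety coordinates: coordinates are converted to 3-D unit vectors,
#' averaged, renormalised and converted back — well behaved at the
#' antimeridian, unlike naive lat/lon averaging. With a `tree` (a nested
#' list whose leaves are variety ids), the centroid is applied recursively:
#' each internal group contributes the spherical centroid of its immediate
#' daughters, so large subgroups do not swamp small ones.
#'
#' Snapping the point to the nearest land requires a coastline resource;
#' supply one as `snap_fun` (a function `(lat, lon) -> c(lat, lon)`),
#' applied to the final centroid. By default no snapping is done and the
#' `method` column records which variant produced the point.
#'
#' @param varieties Tibble with `variety_id`, `latitude`, `longitude`
#'   (rows without coordinates are ignored); an optional single-valued
#'   `family` column is carried into the output.
#' @param tree Optional nested list of variety ids.
#' @param snap_fun Optional land-snapping hook.
#' @return One-row tibble: `family`, `latitude`, `longitude`, `method`.
#' @export
homeland <- function(varieties, tree = NULL, snap_fun = NULL) {
  varieties <- as_tibble(varieties)
  coords <- varieties |>
    filter(!is.na(.data$latitude), !is.na(.data$longitude))
  if (nrow(coords) == 0) abort("no varieties with coordinates")
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180)) {
    abort("coordinates out of range")
  }
  lookup <- setNames(
    split(cbind(coords$latitude, coords$longitude), seq_len(nrow(coords))),
    coords$variety_id
  )
  point <- if (is.null(tree)) {
    sph_centroid(as.matrix(coords[, c("latitude", "longitude")]))
  } else {
    centroid_recursive(tree, lookup)
  }
  method <- "centroid"
  if (!is.null(snap_fun)) {
    point <- snap_fun(point[1], point[2])
    method <- "centroid_land_snapped"
  }
  fam <- if ("family" %in% names(varieties) &&
             n_distinct(varieties$family) == 1) {
    varieties$family[[1]]
  } else {
    NA_character_
  }
  tibble(family = fam, latitude = point[1], longitude = point[2],
         method = method)
}

centroid_recursive <- function(node, lookup) {
  if (is.character(node) && length(node) == 1) {
    pt <- lookup[[node]]
    if (is.null(pt)) abort(paste0("variety without coordinates in tree: ",
                                  node))
    return(c(pt[1], pt[2]))
  }
  daughters <- lapply(node, centroid_recursive, lookup = lookup)
  sph_centroid(do.call(rbind, daughters))
}

# spherical centroid: mean of unit vectors, renormalised; errors on a
# degenerate (near-zero, e.g. antipodal) mean
sph_centroid <- function(latlon) {
  rad <- pi / 180
  lat <- latlon[, 1] * rad
  lon <- latlon[, 2] * rad
  v <- cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  m <- colMeans(v)
  len <- sqrt(sum(m^2))
  if (len < 1e-9) abort("degenerate (antipodal) coordinate set")
  m <- m / len
  c(asin(m[3]) / rad, atan2(m[2], m[1]) / rad)
}
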