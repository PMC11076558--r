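#' Colexification network objects
#'
#' A `colex_network` bundles a node table, a weighted edge table and (when
#' built from a wordlist) the witness records behind every edge. Edges are
#' unordered concept pairs stored canonically (`concept_a` precedes
#' `concept_b` under a fixed string order) and carry three counts:
#'
#' * `variety_count` — number of distinct language varieties attesting the
#'   colexification,
#' * `family_count` — number of distinct language families among them,
#' * `cognate_set_count` — number of distinct cognate sets among the
#'   witnessing forms (initialised to `family_count` until refined by
#'   [refine_network_counts()]).
#'
#' The invariant `family_count <= cognate_set_count <= variety_count` holds
#' for every edge of a refined network.
#'
#' @param nodes Tibble with at least `concept_id`; optionally `gloss`,
#'   `domain`.
#' @param edges Tibble with `concept_a`, `concept_b` and count/weight
#'   columns.
#' @param witnesses Optional tibble with one row per attesting
#'   (pair, variety, form): columns `concept_a`, `concept_b`, `variety_id`,
#'   `family`, `form`, `segments`.
#' @param scope `"global"`, a family name, or another label describing what
#'   the network covers.
#' @param weight_field Which quantity serves as the edge weight:
#'   `"varieties"`, `"families"`, `"cognates"`, or `"weight"` (a literal
#'   `weight` column, used by synthetic generators).
#' @param n_varieties Number of language varieties in scope (used to
#'   normalise weighted degrees).
#'
#' @return An object of class `colex_network`.
#' @export
new_colex_network <- function(nodes, edges, witnesses = NULL,
                              scope = "global",
                              weight_field = c("varieties", "families",
                                               "cognates", "weight"),
                              n_varieties = NA_integer_) {
  weight_field <- match.arg(weight_field)
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot("concept_id" %in% names(nodes))
  if (nrow(edges) > 0) {
    stopifnot(all(c("concept_a", "concept_b") %in% names(edges)))
    if (any(edges$concept_a == edges$concept_b)) {
      abort("self-loop edges are not allowed in a colexification network")
    }
    missing_ep <- setdiff(
      unique(c(edges$concept_a, edges$concept_b)), nodes$concept_id
    )
    if (length(missing_ep) > 0) {
      abort(paste0("edge endpoints absent from node table: ",
                   paste(missing_ep, collapse = ", ")))
    }
  }
  structure(
    list(
      nodes = nodes,
      edges = set_edge_weight(edges, weight_field),
      witnesses = if (is.null(witnesses)) NULL else as_tibble(witnesses),
      scope = scope,
      weight_field = weight_field,
      n_varieties = as.integer(n_varieties)
    ),
    class = "colex_network"
  )
}

set_edge_weight <- function(edges, weight_field) {
  if (nrow(edges) == 0) {
    if (!"weight" %in% names(edges)) edges$weight <- numeric(0)
    return(edges)
  }
  edges$weight <- switch(weight_field,
    varieties = as.numeric(edges$variety_count),
    families  = as.numeric(edges$family_count),
    cognates  = as.numeric(edges$cognate_set_count),
    weight    = as.numeric(edges$weight)
  )
  edges
}

#' @export
print.colex_network <- function(x, ...) {
  cat(sprintf(
    "<colex_network> scope=%s  %d nodes, %d edges (weight = %s)\n",
    x$scope, nrow(x$nodes), nrow(x$edges), x$weight_field
  ))
  if (nrow(x$edges) > 0) print(head(as_tibble(x$edges), 5))
  invisible(x)
}

#' Convert a colexification network to an igraph graph
#'
#' Vertices are concept ids (with gloss/domain vertex attributes when
#' present); edges carry the network's active weight.
#'
#' @param net A `colex_network`.
#' @return An undirected weighted [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "colex_network"))
  verts <- net$nodes
  names(verts)[names(verts) == "concept_id"] <- "name"
  el <- net$edges[, c("concept_a", "concept_b", "weight")]
  names(el) <- c("from", "to", "weight")
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = as.data.frame(verts))
}

#' Export a network as a weighted edge-list tibble
#'
#' @param x A `colex_network`.
#' @param ... Unused.
#' @return A tibble with one row per edge: concept pair, the three counts
#'   and the active weight, plus the network scope.
#' @method tidy colex_network
#' @export
tidy.colex_network <- function(x, ...) {
  out <- as_tibble(x$edges)
  out$scope <- x$scope
  out
}

#' One-row summary of a colexification network
#'
#' @param x A `colex_network`.
#' @param ... Unused.
#' @return A tibble with node/edge counts, density over attested nodes, and
#'   the number of isolated nodes.
#' @method glance colex_network
#' @export
glance.colex_network <- function(x, ...) {
  n <- nrow(x$nodes)
  m <- nrow(x$edges)
  deg <- node_degrees(x)
  tibble(
    scope = x$scope,
    n_nodes = n,
    n_edges = m,
    n_isolated = sum(deg == 0),
    density = if (n >= 2) m / choose(n, 2) else NA_real_,
    total_weight = sum(x$edges$weight),
    n_varieties = x$n_varieties
  )
}

# unweighted degree per node, named by concept_id (isolated nodes included)
node_degrees <- function(net) {
  d <- setNames(rep(0L, nrow(net$nodes)), net$nodes$concept_id)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$concept_a, net$edges$concept_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

# weighted degree (strength) per node, named by concept_id
node_strengths <- function(net) {
  s <- setNames(rep(0, nrow(net$nodes)), net$nodes$concept_id)
  if (nrow(net$edges) > 0) {
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      s[[e$concept_a]] <- s[[e$concept_a]] + e$weight
      s[[e$concept_b]] <- s[[e$concept_b]] + e$weight
    }
  }
  s
}

#' Plot a colexification network
#'
#' Fruchterman–Reingold layout (seeded, so repeated calls draw the same
#' picture); edge width is proportional to the active edge weight. Nodes are
#' labelled with glosses when available and coloured by `colour_by` (a node
#' column such as `region` or `domain`).
#'
#' @param object A `colex_network`.
#' @param colour_by Optional name of a node column to map to colour.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @method autoplot colex_network
#' @export
autoplot.colex_network <- function(object, colour_by = NULL, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble(
    concept_id = igraph::V(g)$name,
    x = xy[, 1], y = xy[, 2]
  )
  nd <- left_join(lay, object$nodes, by = "concept_id")
  nd$label <- if ("gloss" %in% names(nd)) coalesce(nd$gloss, nd$concept_id) else nd$concept_id
  ed <- object$edges
  p <- ggplot2::ggplot()
  if (nrow(ed) > 0) {
    ed <- ed |>
      left_join(lay, by = c(concept_a = "concept_id")) |>
      left_join(lay, by = c(concept_b = "concept_id"),
                suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$weight),
      colour = "grey60", alpha = 0.8
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2.5))
  }
  if (!is.null(colour_by) && colour_by %in% names(nd)) {
    p <- p + ggplot2::geom_point(
      data = nd,
      ggplot2::aes(.data$x, .data$y, colour = .data[[colour_by]]), size = 3
    )
  } else {
    p <- p + ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y),
                                 size = 3, colour = "steelblue")
  }
  p +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Colexification network (", object$scope, ")"))
}

#' Write a network's edge list to a TSV file
#'
#' Columns: `ConceptA`, `ConceptB`, `VarietyCount`, `FamilyCount`,
#' `CognateSetCount`.
#'
#' @param net A `colex_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "colex_network"))
  out <- tibble(
    ConceptA = net$edges$concept_a,
    ConceptB = net$edges$concept_b,
    VarietyCount = net$edges$variety_count,
    FamilyCount = net$edges$family_count,
    CognateSetCount = net$edges$cognate_set_count
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a network to GML
#'
#' Node attributes `gloss` and `domain` are exported when present, for
#' interoperability with external graph tools.
#'
#' @inheritParams write_edgelist
#' @export
write_gml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}
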