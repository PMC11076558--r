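#' Community partitions of a colexification network
#'
#' Two algorithms are provided. [infomap_partition()] minimises the map
#' equation (description length of a random walker) on the weighted
#' undirected graph, the method used for descriptive network figures.
#' [walk_partition()] is agglomerative random-walk clustering (walktrap)
#' with a configurable walk length, the method used for cross-family
#' partition comparison; the dendrogram is cut at maximum modularity.
#'
#' Both return canonical partitions: community labels are contiguous
#' integers starting at 0, with communities ordered by their smallest
#' member concept id, so partitions are directly comparable across runs
#' and across families. Isolated nodes are retained as singleton
#' communities (their `degree` column is 0, which downstream comparisons
#' use to restrict to attested concepts).
#'
#' @param net A `colex_network` with positive edge weights.
#' @param seed Integer seed controlling the stochastic Infomap
#'   optimisation; a fixed seed makes the result deterministic.
#' @param trials Number of Infomap optimisation trials; the best attempt is
#'   kept.
#' @return A `colex_partition`: a tibble with `concept_id`, `community`
#'   (0-based integer), `degree` (unweighted) and `strength` (weighted
#'   degree), with attributes `scope` and `algorithm`.
#' @name communities
NULL

#' @rdname communities
#' @export
infomap_partition <- function(net, seed = 42L, trials = 100L) {
  g <- partition_graph(net)
  if (igraph::ecount(g) == 0) {
    membership <- setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
  } else {
    set.seed(seed)
    cm <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                                  nb.trials = trials)
    membership <- setNames(igraph::membership(cm), igraph::V(g)$name)
  }
  new_colex_partition(membership, net, algorithm = "infomap")
}

#' @rdname communities
#' @param steps Random-walk length.
#' @export
walk_partition <- function(net, steps = 5L) {
  g <- partition_graph(net)
  deg <- igraph::degree(g)
  isolated <- names(deg)[deg == 0]
  g2 <- igraph::delete_vertices(g, isolated)
  if (igraph::ecount(g2) == 0) {
    membership <- setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
  } else {
    cm <- igraph::cluster_walktrap(g2, weights = igraph::E(g2)$weight,
                                   steps = steps)
    membership <- setNames(igraph::membership(cm), igraph::V(g2)$name)
    if (length(isolated) > 0) {
      extra <- setNames(max(membership) + seq_along(isolated), isolated)
      membership <- c(membership, extra)
    }
  }
  new_colex_partition(membership, net,
                      algorithm = paste0("walk", steps))
}

partition_graph <- function(net) {
  stopifnot(inherits(net, "colex_network"))
  if (nrow(net$nodes) < 1) abort("network has no nodes")
  if (nrow(net$edges) > 0 && any(net$edges$weight <= 0)) {
    abort("edge weights must be positive for community detection")
  }
  as_igraph(net)
}

new_colex_partition <- function(membership, net, algorithm) {
  labels <- canonicalize_labels(membership)
  deg <- node_degrees(net)
  str <- node_strengths(net)
  ids <- concept_sort(names(labels))
  out <- tibble(
    concept_id = ids,
    community = as.integer(labels[ids]),
    degree = as.integer(deg[ids]),
    strength = as.numeric(str[ids])
  )
  structure(out, scope = net$scope, algorithm = algorithm,
            class = c("colex_partition", class(out)))
}

# relabel community labels to contiguous 0-based integers, communities
# ordered by their smallest member concept_id; a pure function of the
# (label, node name) mapping, independent of node insertion order
canonicalize_labels <- function(membership) {
  stopifnot(!is.null(names(membership)))
  min_member <- vapply(split(names(membership), membership),
                       function(v) concept_sort(v)[1], character(1))
  ord <- names(min_member)[order(min_member, method = "radix")]
  remap <- setNames(seq_along(ord) - 1L, ord)
  setNames(remap[as.character(membership)], names(membership))
}

#' @export
print.colex_partition <- function(x, ...) {
  cat(sprintf("<colex_partition> scope=%s algorithm=%s: %d nodes, %d communities\n",
              attr(x, "scope"), attr(x, "algorithm"), nrow(x),
              n_distinct(x$community)))
  NextMethod()
}

#' Community membership as a plain tibble
#'
#' @param x A `colex_partition`.
#' @param ... Unused.
#' @return Tibble with `scope`, `concept_id`, `community`, `algorithm`.
#' @method tidy colex_partition
#' @export
tidy.colex_partition <- function(x, ...) {
  tibble(scope = attr(x, "scope"), concept_id = x$concept_id,
         community = x$community, algorithm = attr(x, "algorithm"))
}

#' One-row summary of a partition
#'
#' @param x A `colex_partition`.
#' @param ... Unused.
#' @return Tibble with node, community and singleton counts.
#' @method glance colex_partition
#' @export
glance.colex_partition <- function(x, ...) {
  sizes <- table(x$community)
  tibble(
    scope = attr(x, "scope"),
    algorithm = attr(x, "algorithm"),
    n_nodes = nrow(x),
    n_communities = length(sizes),
    n_singletons = sum(sizes == 1),
    largest_community = max(sizes)
  )
}
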