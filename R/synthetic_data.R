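#' Configuration for the synthetic wordlist generator
#'
#' Describes the study conditions a simulated multilingual wordlist should
#' emulate: several language families whose varieties are related by random
#' rooted binary trees, per-concept proto-forms that mutate along tree
#' edges, planted colexification events that are either inherited from an
#' ancestor (vertical) or innovated independently per variety, and
#' per-concept coverage gaps.
#'
#' @param concepts Tibble with `concept_id`, `gloss`, `domain`.
#' @param colex_pairs Tibble with `concept_a`, `concept_b`, `mode`
#'   (`"vertical"` or `"independent"`), `rate` and optional `n_origins`
#'   (vertical only; number of independent origin events per family,
#'   default 1). For a vertical pair, `rate` is the probability that the
#'   pair is planted in a family at all; for an independent pair it is the
#'   per-variety innovation probability.
#' @param n_families Number of language families.
#' @param varieties_per_family A single count or a `c(min, max)` range.
#' @param mutation_rate Per-segment substitution probability applied along
#'   every tree edge.
#' @param coverage Probability that a (variety, concept) cell is attested.
#' @param seed Mandatory integer seed; the same seed yields a byte-identical
#'   wordlist and ledger.
#' @return A `sim_config` list.
#' @export
sim_config <- function(concepts, colex_pairs = NULL, n_families = 3,
                       varieties_per_family = 8, mutation_rate = 0.02,
                       coverage = 0.95, seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  concepts <- as_tibble(concepts)
  stopifnot(all(c("concept_id", "gloss", "domain") %in% names(concepts)))
  if (is.null(colex_pairs)) {
    colex_pairs <- tibble(concept_a = character(0), concept_b = character(0),
                          mode = character(0), rate = numeric(0),
                          n_origins = integer(0))
  }
  colex_pairs <- as_tibble(colex_pairs)
  if (nrow(colex_pairs) > 0) {
    if (!"n_origins" %in% names(colex_pairs)) colex_pairs$n_origins <- 1L
    cp <- canonical_pair(colex_pairs$concept_a, colex_pairs$concept_b)
    colex_pairs$concept_a <- cp$concept_a
    colex_pairs$concept_b <- cp$concept_b
    stopifnot(all(colex_pairs$mode %in% c("vertical", "independent")))
    bad <- setdiff(unique(c(colex_pairs$concept_a, colex_pairs$concept_b)),
                   concepts$concept_id)
    if (length(bad) > 0) {
      abort(paste0("colex pair concepts not in concept list: ",
                   paste(bad, collapse = ", ")))
    }
    if (any(colex_pairs$rate < 0 | colex_pairs$rate > 1)) {
      abort("colexification rates must be in [0, 1]")
    }
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must be in [0, 1]")
  }
  if (coverage < 0 || coverage > 1) abort("coverage must be in [0, 1]")
  structure(
    list(concepts = concepts, colex_pairs = colex_pairs,
         n_families = as.integer(n_families),
         varieties_per_family = varieties_per_family,
         mutation_rate = mutation_rate, coverage = coverage,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 20-symbol segment alphabet: chance identity of independently drawn
# length-3..6 forms is negligible
sim_alphabet <- function() strsplit("ptkbdgmnszlrwjfvaeiu", "")[[1]]

random_form <- function(avoid = character(0)) {
  ab <- sim_alphabet()
  repeat {
    f <- paste(sample(ab, sample(3:6, 1), replace = TRUE), collapse = "")
    if (!f %in% avoid) return(f)
  }
}

# choose k origin nodes with pairwise-disjoint tip sets, uniformly among
# all such k-subsets when enumerable; greedy sequential fallback otherwise
sample_disjoint_origins <- function(cand_nodes, tipsets, k) {
  k <- as.integer(k)
  if (k <= 1 || length(cand_nodes) == 1) {
    return(if (length(cand_nodes) == 1) cand_nodes
           else sample(cand_nodes, 1))
  }
  if (k <= length(cand_nodes) && choose(length(cand_nodes), k) <= 20000) {
    sets <- combn(length(cand_nodes), k)
    ok <- apply(sets, 2, function(ix) {
      tips <- lapply(cand_nodes[ix], function(nd) tipsets[[nd]])
      length(unlist(tips)) == length(unique(unlist(tips)))
    })
    if (any(ok)) {
      pick <- if (sum(ok) == 1) which(ok) else sample(which(ok), 1)
      return(cand_nodes[sets[, pick]])
    }
  }
  used <- integer(0)
  out <- integer(0)
  for (j in seq_len(k)) {
    free <- vapply(cand_nodes, function(nd) {
      length(intersect(tipsets[[nd]], used)) == 0
    }, logical(1))
    if (!any(free)) break
    nd <- if (sum(free) == 1) cand_nodes[free] else sample(cand_nodes[free], 1)
    used <- c(used, tipsets[[nd]])
    out <- c(out, nd)
  }
  out
}

# a fresh innovated form, rejected until clearly distinct from the forms
# that founded earlier cognate sets of the same pair
random_innovation <- function(origin_forms, protos, min_dist = 0.7,
                              max_tries = 500) {
  for (i in seq_len(max_tries)) {
    g <- random_form(avoid = protos)
    if (length(origin_forms) == 0 ||
        all(form_distance(rep(g, length(origin_forms)),
                          origin_forms) >= min_dist)) {
      return(g)
    }
  }
  g
}

mutate_form <- function(f, rate, times = 1) {
  ab <- sim_alphabet()
  ch <- strsplit(f, "")[[1]]
  for (k in seq_len(times)) {
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit],
                        function(s) sample(setdiff(ab, s), 1), character(1))
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a multilingual wordlist with known ground truth
#'
#' For each family a random rooted binary tree over its varieties is drawn;
#' each concept receives a family proto-form which mutates along every tree
#' edge (per-segment substitution). A vertical colexification event
#' activates on a random tree edge and propagates to all descendant
#' varieties, which then share one (mutated, hence cognate) form for both
#' concepts; when several origins are planted for a pair, later origins use
#' freshly innovated forms on disjoint subtrees so that each origin founds
#' its own cognate set. An independent event makes a single variety
#' colexify the pair with a fresh form. Finally each (variety, concept)
#' cell is dropped with probability `1 - coverage`.
#'
#' The returned ledger records every planted event, the surviving
#' (post-coverage) per-variety colexifications, realized origin counts per
#' (family, pair), and the planted family homeland, which is sufficient to
#' score every pipeline stage exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list with `wordlist` (a `colex_wordlist`) and `ledger`.
#' @export
simulate_wordlist <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  concepts <- cfg$concepts
  cids <- concepts$concept_id
  fam_ids <- sprintf("Fam%02d", seq_len(cfg$n_families))

  all_forms <- list()
  all_vars <- list()
  events <- list()
  homelands <- list()

  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]
    n_v <- if (length(cfg$varieties_per_family) == 2) {
      sample(cfg$varieties_per_family[1]:cfg$varieties_per_family[2], 1)
    } else {
      as.integer(cfg$varieties_per_family)
    }
    vids <- sprintf("%s_v%02d", fam, seq_len(n_v))

    fam_sim <- simulate_family_forms(n_v, cids, cfg)

    forms <- fam_sim$forms      # n_v x concepts character matrix
    present <- matrix(runif(n_v * length(cids)) < cfg$coverage,
                      nrow = n_v, dimnames = list(NULL, cids))

    for (ev in fam_sim$events) {
      events[[length(events) + 1]] <- tibble(
        family = fam, concept_a = ev$concept_a, concept_b = ev$concept_b,
        mode = ev$mode, origin_id = ev$origin_id,
        variety_id = vids[ev$tips],
        surviving = present[ev$tips, ev$concept_a] &
          present[ev$tips, ev$concept_b]
      )
    }

    center <- c(runif(1, -50, 50), runif(1, -150, 150))
    homelands[[fam]] <- tibble(family = fam, latitude = center[1],
                               longitude = center[2])
    all_vars[[fam]] <- tibble(
      variety_id = vids,
      glottocode = sprintf("%s%04d", tolower(substr(fam, 1, 3)),
                           fi * 100 + seq_len(n_v)),
      family = fam,
      latitude = pmax(-89, pmin(89, center[1] + runif(n_v, -5, 5))),
      longitude = center[2] + runif(n_v, -5, 5)
    )

    idx <- which(present, arr.ind = TRUE)
    all_forms[[fam]] <- tibble(
      variety_id = vids[idx[, 1]],
      concept_id = cids[idx[, 2]],
      form = forms[idx],
      segments = vapply(forms[idx],
                        function(f) paste(strsplit(f, "")[[1]],
                                          collapse = " "),
                        character(1), USE.NAMES = FALSE)
    )
  }

  forms_tbl <- bind_rows(all_forms) |>
    arrange(.data$variety_id, .data$concept_id, .data$form)
  vars_tbl <- bind_rows(all_vars)
  wl <- new_wordlist(forms_tbl, vars_tbl, concepts,
                     report = list(simulated = TRUE, seed = cfg$seed))

  events_tbl <- bind_rows(events)
  if (nrow(events_tbl) == 0) {
    events_tbl <- tibble(family = character(0), concept_a = character(0),
                         concept_b = character(0), mode = character(0),
                         origin_id = integer(0), variety_id = character(0),
                         surviving = logical(0))
  }
  realized <- filter(events_tbl, .data$surviving)
  origin_counts <- realized |>
    group_by(.data$family, .data$concept_a, .data$concept_b) |>
    summarise(n_origins = n_distinct(.data$origin_id), .groups = "drop")
  edge_truth <- realized |>
    group_by(.data$concept_a, .data$concept_b) |>
    summarise(variety_count = n_distinct(.data$variety_id),
              family_count = n_distinct(.data$family), .groups = "drop")

  ledger <- list(
    planted_events = events_tbl,
    realized_colex = select(realized, -"surviving"),
    origin_counts = origin_counts,
    edge_truth = edge_truth,
    homelands = bind_rows(homelands),
    seed = cfg$seed
  )
  list(wordlist = wl, ledger = ledger)
}

# simulate one family: tree, proto-forms, mutation, colex events.
# Returns tip-level form matrix and the planted events (tip indices).
simulate_family_forms <- function(n_v, cids, cfg) {
  rate <- cfg$mutation_rate
  protos <- character(0)
  for (cid in cids) protos[cid] <- random_form(avoid = protos)

  if (n_v == 1) {
    tipsets <- list(`1` = 1L)
    tip_depth <- c(`1` = 0L)
    edges <- matrix(integer(0), ncol = 2)
    node_forms <- list(`1` = protos)
  } else {
    tree <- ape::rtree(n_v, rooted = TRUE, br = NULL)
    edges <- tree$edge
    root <- n_v + 1L
    children <- split(edges[, 2], edges[, 1])
    n_nodes <- n_v + tree$Nnode
    node_forms <- vector("list", n_nodes)
    node_depth <- integer(n_nodes)
    node_forms[[root]] <- protos
    walk <- function(node) {
      for (ch in children[[as.character(node)]] %||% integer(0)) {
        node_forms[[ch]] <<- vapply(node_forms[[node]], mutate_form,
                                    character(1), rate = rate)
        node_depth[ch] <<- node_depth[node] + 1L
        walk(ch)
      }
    }
    walk(root)
    desc_tips <- function(node) {
      if (node <= n_v) return(node)
      unlist(lapply(children[[as.character(node)]], desc_tips))
    }
    tipsets <- lapply(seq_len(n_nodes), desc_tips)
    tip_depth <- node_depth
  }

  forms <- matrix(NA_character_, nrow = n_v, ncol = length(cids),
                  dimnames = list(NULL, cids))
  if (n_v == 1) {
    forms[1, ] <- protos
  } else {
    for (t in seq_len(n_v)) forms[t, ] <- node_forms[[t]]
  }

  events <- list()
  cp <- cfg$colex_pairs
  for (k in seq_len(nrow(cp))) {
    a <- cp$concept_a[k]
    b <- cp$concept_b[k]
    if (cp$mode[k] == "vertical") {
      if (runif(1) > cp$rate[k]) next
      # candidate origin points: tree edges (their child subtree receives
      # the colexification); for a single-variety family, the tip itself
      cand_nodes <- if (n_v == 1) 1L else edges[, 2]
      chosen <- sample_disjoint_origins(cand_nodes, tipsets,
                                        cp$n_origins[k])
      origin_forms <- character(0)
      for (j in seq_along(chosen)) {
        nd <- chosen[j]
        tips <- tipsets[[nd]]
        if (j == 1) {
          # inherited: descendants already carry cognate copies of the
          # concept-a form at the origin node
          forms[tips, b] <- forms[tips, a]
          origin_forms <- node_forms[[nd]][[a]]
        } else {
          # further origins innovate a fresh form, founding a new cognate
          # set; kept distant from earlier origin forms so each origin is
          # identifiable as its own set
          g <- random_innovation(origin_forms, protos)
          for (t in tips) {
            d <- if (n_v == 1) 0L else tip_depth[t] - tip_depth[nd]
            ft <- mutate_form(g, rate, times = d)
            forms[t, a] <- ft
            forms[t, b] <- ft
          }
          origin_forms <- c(origin_forms, g)
        }
        events[[length(events) + 1]] <- list(
          concept_a = a, concept_b = b, mode = "vertical",
          origin_id = j, tips = tips
        )
      }
    } else {
      taken <- integer(0)
      for (ev in events) {
        if (ev$concept_a == a && ev$concept_b == b) {
          taken <- c(taken, ev$tips)
        }
      }
      oid <- 1000L
      for (t in setdiff(seq_len(n_v), taken)) {
        if (runif(1) <= cp$rate[k]) {
          g <- random_form(avoid = c(protos, forms))
          forms[t, a] <- g
          forms[t, b] <- g
          oid <- oid + 1L
          events[[length(events) + 1]] <- list(
            concept_a = a, concept_b = b, mode = "independent",
            origin_id = oid, tips = t
          )
        }
      }
    }
  }
  list(forms = forms, events = events)
}

#' Random weighted network with a planted block partition
#'
#' Within-block node pairs receive an edge with probability `p_in`,
#' between-block pairs with probability `p_out`; edge weights are drawn
#' uniformly from `weight_range`. The planted partition is returned as
#' ground truth for community-recovery benchmarks.
#'
#' @param blocks List of disjoint character vectors of node ids.
#' @param p_in,p_out Edge probabilities, `p_in > p_out`.
#' @param weight_range `c(min, max)` for edge weights.
#' @param seed Integer seed.
#' @return List with `network` (a `colex_network`) and `truth`
#'   (a `colex_partition`).
#' @export
planted_partition_network <- function(blocks, p_in, p_out,
                                      weight_range = c(1, 1), seed) {
  stopifnot(is.list(blocks), p_in > p_out, p_in <= 1, p_out >= 0)
  nodes <- unlist(blocks)
  if (anyDuplicated(nodes)) abort("blocks must be disjoint")
  set.seed(seed)
  membership <- setNames(rep(seq_along(blocks), lengths(blocks)), nodes)
  nodes <- concept_sort(nodes)
  edges <- tibble(concept_a = character(0), concept_b = character(0),
                  variety_count = integer(0), family_count = integer(0),
                  cognate_set_count = integer(0), weight = numeric(0))
  if (length(nodes) >= 2) {
    prs <- t(combn(nodes, 2))
    same <- membership[prs[, 1]] == membership[prs[, 2]]
    prob <- ifelse(same, p_in, p_out)
    keep <- runif(nrow(prs)) < prob
    w <- runif(sum(keep), weight_range[1], weight_range[2])
    edges <- tibble(
      concept_a = prs[keep, 1], concept_b = prs[keep, 2],
      variety_count = 1L, family_count = 1L, cognate_set_count = 1L,
      weight = w
    )
  }
  net <- new_colex_network(
    tibble(concept_id = nodes, gloss = nodes, domain = NA_character_),
    edges, scope = "planted", weight_field = "weight", n_varieties = 1L
  )
  truth <- new_colex_partition(membership, net, algorithm = "planted")
  list(network = net, truth = truth)
}

#' Generate a pair of partitions with a known similarity regime
#'
#' Test harness for chance-corrected partition indices: `"identical"`
#' yields ARI = AMI = 1, `"independent"` yields values with expectation
#' approximately 0 over seeds, `"nested"` splits each cluster of the first
#' partition in two.
#'
#' @param n Number of nodes (>= 4).
#' @param target Similarity regime.
#' @param seed Integer seed.
#' @return List of two tibbles `p`, `q` with `concept_id`, `community`.
#' @export
partition_pair_with_ari <- function(n,
                                    target = c("identical", "independent",
                                               "nested"),
                                    seed) {
  target <- match.arg(target)
  stopifnot(n >= 4)
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  rand_labels <- function() sample(0:2, n, replace = TRUE)
  if (target == "identical") {
    lab <- rand_labels()
    p <- lab
    q <- lab
  } else if (target == "independent") {
    p <- rand_labels()
    q <- rand_labels()
  } else {
    p <- rep(0:1, each = ceiling(n / 2), length.out = n)
    q <- integer(n)
    for (cl in unique(p)) {
      idx <- which(p == cl)
      q[idx] <- cl * 2L + as.integer(seq_along(idx) > length(idx) / 2)
    }
  }
  list(p = tibble(concept_id = ids, community = as.integer(p)),
       q = tibble(concept_id = ids, community = as.integer(q)))
}

#' Simulate per-family domain networks from planted partitions
#'
#' Emulates the cross-family comparison conditions: when `shared = TRUE`
#' every family's network is drawn from one universal planted partition of
#' the domain's concepts (a body-part-like domain, whose community
#' structure is similar across families); when `shared = FALSE` each family
#' receives its own independent random partition (an emotion-like domain).
#'
#' @param node_ids Character vector of the domain's concept ids.
#' @param n_families Number of families.
#' @param n_blocks Number of planted communities.
#' @param p_in,p_out Within/between-block edge probabilities.
#' @param shared Whether all families share one planted partition.
#' @param weight_range Edge-weight interval.
#' @param seed Integer seed.
#' @return List with `nets` (named list of `colex_network`s) and `truth`
#'   (named list of planted `colex_partition`s).
#' @export
simulate_family_networks <- function(node_ids, n_families, n_blocks = 3,
                                     p_in = 0.6, p_out = 0.05,
                                     shared = TRUE, weight_range = c(1, 3),
                                     seed) {
  set.seed(seed)
  fam_ids <- sprintf("Fam%02d", seq_len(n_families))
  fam_seeds <- sample.int(.Machine$integer.max - 1L, n_families)
  make_blocks <- function() {
    split(sample(node_ids), rep(seq_len(n_blocks), length.out =
                                  length(node_ids)))
  }
  shared_blocks <- make_blocks()
  block_sets <- lapply(seq_len(n_families), function(i) {
    if (shared) shared_blocks else make_blocks()
  })
  sims <- purrr::map(seq_len(n_families), function(i) {
    planted_partition_network(block_sets[[i]], p_in, p_out,
                              weight_range = weight_range,
                              seed = fam_seeds[i])
  })
  nets <- setNames(lapply(sims, `[[`, "network"), fam_ids)
  truth <- setNames(lapply(sims, `[[`, "truth"), fam_ids)
  for (f in fam_ids) nets[[f]]$scope <- f
  list(nets = nets, truth = truth)
}

#' Write a simulated wordlist and its ledger to disk
#'
#' Writes the same CSV/TSV dialects [read_wordlist()] reads, plus
#' `ledger.json` with the ground truth.
#'
#' @param sim Result of [simulate_wordlist()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_wordlist(sim$wordlist, dir)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      lapply(sim$ledger, function(x) if (is.data.frame(x)) x else x),
      file.path(dir, "ledger.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  } else {
    warn("jsonlite not installed; ledger.json not written")
  }
  invisible(dir)
}
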