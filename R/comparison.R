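#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert–Arabie). From the
#' contingency table of the two labelings with cell counts \eqn{n_{ij}},
#' row sums \eqn{a_i} and column sums \eqn{b_j}:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}
#'   {\tfrac12\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E},
#'   \quad E = \frac{\sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}}{\binom{n}{2}}.}
#' Equals 1 iff the partitions are identical; has expectation ~0 for
#' independent random partitions with the same margins.
#'
#' @param p,q Partitions over identical node sets: either
#'   `colex_partition`/data frames with `concept_id` and `community`
#'   columns, or plain label vectors of equal length.
#' @return A single number `<= 1`.
#' @export
adjusted_rand_index <- function(p, q) {
  al <- align_partitions(p, q)
  ct <- table(al$x, al$y)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (abs(denom) < 1e-14) {
    # both partitions trivial (all singletons or one block): identical -> 1
    return(if (isTRUE(all.equal(sum_ij, expected))) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected information-theoretic agreement:
#' \deqn{AMI = \frac{MI - E[MI]}{\tfrac12(H(p) + H(q)) - E[MI]}}
#' with the exact expected mutual information under the hypergeometric
#' (fixed-margins permutation) model and arithmetic-mean normalisation.
#' Equals 1 iff the partitions are identical; a partition with zero entropy
#' (one block) yields 0 against anything non-identical.
#'
#' @inheritParams adjusted_rand_index
#' @return A single number `<= 1`.
#' @export
adjusted_mutual_information <- function(p, q) {
  al <- align_partitions(p, q)
  ct <- table(al$x, al$y)
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  mi <- mutual_information(ct)
  emi <- expected_mutual_information(a, b, n)
  h <- function(m) {
    pr <- m[m > 0] / n
    -sum(pr * log(pr))
  }
  denom <- (h(a) + h(b)) / 2 - emi
  if (abs(denom) < 1e-12) {
    canon <- function(v) match(v, unique(v))
    same <- identical(canon(al$x), canon(al$y))
    return(if (same) 1 else 0)
  }
  (mi - emi) / denom
}

mutual_information <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- ct[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
    }
  }
  unname(mi)
}

# exact E[MI] under the fixed-margins hypergeometric model (natural log)
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  lg <- lgamma
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lg(ai + 1) + lg(bj + 1) + lg(n - ai + 1) + lg(n - bj + 1) -
          lg(n + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
          lg(n - ai - bj + nij + 1)
        emi <- emi + (nij / n) * log(n * nij / (ai * bj)) * exp(lp)
      }
    }
  }
  emi
}

align_partitions <- function(p, q) {
  if (is.data.frame(p) || is.data.frame(q)) {
    stopifnot(is.data.frame(p), is.data.frame(q))
    if (!setequal(p$concept_id, q$concept_id) ||
        nrow(p) != nrow(q)) {
      abort("partitions are over different node sets")
    }
    if (nrow(p) < 2) abort("partitions must cover at least 2 nodes")
    ids <- concept_sort(p$concept_id)
    list(x = p$community[match(ids, p$concept_id)],
         y = q$community[match(ids, q$concept_id)])
  } else {
    if (length(p) != length(q)) {
      abort("label vectors differ in length")
    }
    if (length(p) < 2) abort("partitions must cover at least 2 nodes")
    list(x = p, y = q)
  }
}

#' Pairwise family similarity of community partitions
#'
#' For every unordered pair of families, restricts both partitions to the
#' concepts attested (degree >= 1) in *both* family networks, skips pairs
#' sharing fewer than `min_shared` such concepts, and computes ARI and AMI
#' on the restriction.
#'
#' @param partitions Named list (family -> `colex_partition`), all from one
#'   semantic domain, as produced by [walk_partition()] on family
#'   subnetworks.
#' @param domain Label recorded in the output.
#' @param min_shared Minimum number of shared attested concepts.
#' @return A `colex_similarity` tibble: `family_a`, `family_b`, `domain`,
#'   `shared_nodes`, `ari`, `ami`. Use [similarity_summary()] for per-domain
#'   means and standard deviations.
#' @export
pairwise_family_similarity <- function(partitions, domain = NA_character_,
                                       min_shared = 3) {
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  if (length(partitions) < 2) abort("need at least 2 family partitions")
  fams <- sort(names(partitions))
  prs <- t(combn(fams, 2))
  rows <- purrr::map(seq_len(nrow(prs)), function(k) {
    fa <- prs[k, 1]
    fb <- prs[k, 2]
    pa <- partitions[[fa]]
    pb <- partitions[[fb]]
    shared <- intersect(pa$concept_id[pa$degree >= 1],
                        pb$concept_id[pb$degree >= 1])
    if (length(shared) < min_shared) return(NULL)
    ra <- pa[match(shared, pa$concept_id), c("concept_id", "community")]
    rb <- pb[match(shared, pb$concept_id), c("concept_id", "community")]
    tibble(family_a = fa, family_b = fb, domain = domain,
           shared_nodes = length(shared),
           ari = adjusted_rand_index(as.data.frame(ra), as.data.frame(rb)),
           ami = adjusted_mutual_information(as.data.frame(ra),
                                             as.data.frame(rb)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(family_a = character(0), family_b = character(0),
                  domain = character(0), shared_nodes = integer(0),
                  ari = numeric(0), ami = numeric(0))
  }
  structure(out, class = c("colex_similarity", class(out)))
}

#' Per-domain summary of pairwise similarities
#'
#' @param sim A `colex_similarity` tibble (rows may mix domains).
#' @return Tibble with `domain`, `n_pairs`, `ari_mean`, `ari_sd`,
#'   `ami_mean`, `ami_sd`.
#' @export
similarity_summary <- function(sim) {
  sim |>
    as_tibble() |>
    group_by(.data$domain) |>
    summarise(n_pairs = n(),
              ari_mean = mean(.data$ari), ari_sd = stats::sd(.data$ari),
              ami_mean = mean(.data$ami), ami_sd = stats::sd(.data$ami),
              .groups = "drop")
}

#' Density plot of pairwise ARI/AMI distributions by domain
#'
#' @param object A `colex_similarity` tibble.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @method autoplot colex_similarity
#' @export
autoplot.colex_similarity <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(c("ari", "ami"), names_to = "index",
                        values_to = "value") |>
    mutate(index = toupper(.data$index))
  ggplot2::ggplot(long, ggplot2::aes(.data$value, colour = .data$domain,
                                     fill = .data$domain)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "pairwise partition similarity", y = "density") +
    ggplot2::theme_minimal()
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch–Satterthwaite degrees of freedom
#' and a two-sided p value, as used to compare per-domain ARI or
#' weighted-degree distributions.
#'
#' @param xs,ys Numeric vectors, each with at least 2 values and nonzero
#'   variance.
#' @return Tibble with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(xs, ys) {
  if (length(xs) < 2 || length(ys) < 2) {
    abort("each sample needs at least 2 values")
  }
  if (var(xs) == 0 || var(ys) == 0) {
    abort("degenerate (zero-variance) sample")
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Weighted-degree resampling across semantic domains
#'
#' Runs `trials` resampling trials per domain. In each trial one node
#' sample of size `n` is drawn uniformly without replacement from the
#' domain's concept pool and applied to *all* of that domain's family
#' networks; each family's score is the summed weighted degree of the
#' sampled nodes in its subnetwork, divided by the family's variety count.
#' This makes sparse networks of different sizes comparable across domains.
#'
#' @param nets Named list (domain -> named list of family
#'   `colex_network`s).
#' @param node_pool Named list (domain -> character vector of concept ids
#'   eligible for sampling).
#' @param n Sample size per domain: a single number, a named vector by
#'   domain, or `NULL` for the full pool size.
#' @param trials Number of trials per domain.
#' @param seed Integer seed; results depend only on the seed, not on node
#'   or family insertion order.
#' @return A `colex_degree_trials` tibble: `domain`, `family`, `trial`,
#'   `weighted_degree`. Use [degree_summary()] for per-domain means, sds
#'   and pairwise Welch tests.
#' @export
degree_resampling <- function(nets, node_pool, n = NULL, trials = 1000,
                              seed = 42L) {
  stopifnot(is.list(nets), !is.null(names(nets)))
  if (trials < 1) abort("trials must be >= 1")
  domains <- sort(names(nets))
  set.seed(seed)
  out <- purrr::map(domains, function(dom) {
    pool <- concept_sort(unique(node_pool[[dom]]))
    nd <- if (is.null(n)) length(pool)
          else if (!is.null(names(n))) n[[dom]]
          else n
    nd <- as.integer(nd)
    if (nd > length(pool)) {
      abort(sprintf("sample size %d exceeds pool size %d for domain %s",
                    nd, length(pool), dom))
    }
    fam_nets <- nets[[dom]]
    fams <- sort(names(fam_nets))
    strengths <- lapply(fam_nets, node_strengths)
    nvar <- vapply(fam_nets, function(x) x$n_varieties, integer(1))
    per_trial <- purrr::map(seq_len(trials), function(tr) {
      picked <- sample(pool, nd)
      wd <- vapply(fams, function(f) {
        s <- strengths[[f]]
        sum(s[intersect(picked, names(s))]) / nvar[[f]]
      }, numeric(1))
      tibble(domain = dom, family = fams, trial = tr,
             weighted_degree = unname(wd))
    })
    bind_rows(per_trial)
  })
  out <- bind_rows(out)
  structure(out, class = c("colex_degree_trials", class(out)))
}

#' Summarise degree-resampling trials
#'
#' @param trials A `colex_degree_trials` tibble.
#' @return A list with `summary` (per-domain mean/sd of weighted degree)
#'   and `tests` (pairwise Welch t-tests between domain distributions).
#' @export
degree_summary <- function(trials) {
  trials <- as_tibble(trials)
  summ <- trials |>
    group_by(.data$domain) |>
    summarise(degree_mean = mean(.data$weighted_degree),
              degree_sd = stats::sd(.data$weighted_degree),
              .groups = "drop")
  doms <- sort(unique(trials$domain))
  tests <- NULL
  if (length(doms) >= 2) {
    prs <- t(combn(doms, 2))
    tests <- purrr::map(seq_len(nrow(prs)), function(k) {
      xa <- trials$weighted_degree[trials$domain == prs[k, 1]]
      xb <- trials$weighted_degree[trials$domain == prs[k, 2]]
      tt <- welch_t_test(xa, xb)
      tibble(domain_a = prs[k, 1], domain_b = prs[k, 2],
             t = tt$t, df = tt$df, p_value = tt$p_value)
    }) |> bind_rows()
  }
  list(summary = summ, tests = tests)
}

#' Density plot of weighted-degree distributions by domain
#'
#' @param object A `colex_degree_trials` tibble.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @method autoplot colex_degree_trials
#' @export
autoplot.colex_degree_trials <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$weighted_degree, colour = .data$domain,
                               fill = .data$domain)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::labs(x = "weighted degree (per variety)", y = "density") +
    ggplot2::theme_minimal()
}
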