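test_that("form normalization lower-cases, trims and strips annotations", {
  expect_equal(normalize_form(" Laŋ "), "laŋ")
  expect_equal(normalize_form("lima (archaic)"), "lima")
  expect_equal(normalize_form("foot  bone"), "foot bone")
  expect_true(is.na(normalize_form("(only brackets)")))
})

belhare_wl <- function() {
  make_wordlist(
    tibble::tibble(
      variety_id = c("belhare", "belhare", "belhare",
                     "washo", "washo", "washo"),
      concept_id = c("foot", "leg", "hand", "foot", "hand", "leg"),
      form = c("laŋ", "laŋ", "chuk", "mayap", "mayap", "dewdu"),
      segments = NA_character_
    ),
    variety_meta(c("belhare", "washo"), c("Sino-Tibetan", "Washo")),
    concept_list(c("foot", "leg", "hand"))
  )
}

test_that("per-variety colexifications find whole-form identity", {
  wl <- belhare_wl()
  bel <- find_variety_colexifications(wl, "belhare")
  expect_equal(nrow(bel), 1)
  expect_equal(bel$form, "laŋ")
  expect_setequal(c(bel$concept_a, bel$concept_b), c("foot", "leg"))

  was <- find_variety_colexifications(wl, "washo")
  expect_setequal(c(was$concept_a, was$concept_b), c("foot", "hand"))

  expect_error(find_variety_colexifications(wl, "nope"), "unknown variety")
})

test_that("a variety with all-distinct forms yields no colexifications", {
  wl <- make_wordlist(
    tibble::tibble(variety_id = "v1", concept_id = sprintf("c%d", 1:6),
                   form = sprintf("form%d", 1:6), segments = NA_character_),
    variety_meta("v1", "F1"), concept_list(sprintf("c%d", 1:6))
  )
  expect_equal(nrow(find_variety_colexifications(wl, "v1")), 0)
})

test_that("short forms are ignored below the minimum length", {
  wl <- make_wordlist(
    tibble::tibble(variety_id = "v1", concept_id = c("a1", "a2"),
                   form = c("i", "i"), segments = NA_character_),
    variety_meta("v1", "F1"), concept_list(c("a1", "a2"))
  )
  expect_equal(nrow(find_variety_colexifications(wl, "v1")), 0)
  expect_equal(nrow(find_variety_colexifications(wl, "v1",
                                                 min_form_length = 1)), 1)
})

test_that("network counts distinct varieties and families", {
  # two varieties of one family + one of another share a pair
  wl <- make_wordlist(
    tibble::tibble(
      variety_id = c("v1", "v1", "v2", "v2", "v3", "v3"),
      concept_id = rep(c("foot", "leg"), 3),
      form = c("pela", "pela", "pela", "pela", "kanu", "kanu"),
      segments = NA_character_
    ),
    variety_meta(c("v1", "v2", "v3"), c("FamA", "FamA", "FamB")),
    concept_list(c("foot", "leg"))
  )
  net <- build_network(wl)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$variety_count, 3L)
  expect_equal(net$edges$family_count, 2L)
  expect_equal(net$edges$cognate_set_count, net$edges$family_count)
  expect_equal(net$edges$weight, 3)

  # a variety with two shared synonym forms still counts once
  wl2 <- make_wordlist(
    tibble::tibble(
      variety_id = "v1",
      concept_id = c("foot", "leg", "foot", "leg"),
      form = c("pela", "pela", "kanu", "kanu"),
      segments = NA_character_
    ),
    variety_meta("v1", "FamA"), concept_list(c("foot", "leg"))
  )
  net2 <- build_network(wl2)
  expect_equal(net2$edges$variety_count, 1L)

  expect_error(build_network(wl, concepts = concept_list(character(0))),
               "empty concept list")
})

test_that("edge set matches the planted pairs of a synthetic corpus", {
  cids <- sprintf("c%02d", 1:8)
  pairs <- tibble::tibble(
    concept_a = c("c01", "c03", "c05"), concept_b = c("c02", "c04", "c06"),
    mode = "vertical", rate = 1, n_origins = 1L
  )
  sim <- simulate_wordlist(sim_config(
    concepts = concept_list(cids), colex_pairs = pairs,
    n_families = 3, varieties_per_family = 6, mutation_rate = 0,
    coverage = 1, seed = 21
  ))
  net <- build_network(sim$wordlist)
  got <- dplyr::arrange(net$edges[, c("concept_a", "concept_b")],
                        concept_a)
  truth <- dplyr::arrange(
    sim$ledger$edge_truth[, c("concept_a", "concept_b")], concept_a
  )
  expect_equal(as.data.frame(got), as.data.frame(truth))
})

test_that("family subnetworks recount within the family", {
  wl <- make_wordlist(
    tibble::tibble(
      variety_id = c("v1", "v1", "v2", "v2", "v3", "v3", "v3"),
      concept_id = c("foot", "leg", "foot", "leg", "hand", "arm", "foot"),
      form = c("pela", "pela", "pela", "pela", "mano", "mano", "tok"),
      segments = NA_character_
    ),
    variety_meta(c("v1", "v2", "v3"), c("FamA", "FamA", "FamB")),
    concept_list(c("foot", "leg", "hand", "arm"))
  )
  net <- build_network(wl)
  sub_a <- subnetwork_by_family(net, wl, "FamA")
  expect_equal(nrow(sub_a$edges), 1)
  expect_equal(sub_a$edges$variety_count, 2L)
  expect_equal(sub_a$n_varieties, 2L)

  # the foot-leg edge is witnessed only by FamA, so FamB's subnetwork
  # drops it; FamB still has its own hand-arm edge and attested nodes
  sub_b <- subnetwork_by_family(net, wl, "FamB")
  expect_equal(nrow(sub_b$edges), 1)
  expect_setequal(c(sub_b$edges$concept_a, sub_b$edges$concept_b),
                  c("hand", "arm"))
  expect_true("foot" %in% sub_b$nodes$concept_id)

  expect_error(subnetwork_by_family(net, wl, "FamC"), "unknown family")
})

test_that("an edge's family count equals the number of family subnetworks containing it", {
  set.seed(31)
  for (rep in 1:5) {
    wl <- random_mini_wordlist(n_var = 6, n_con = 5, n_fam = 3)
    net <- build_network(wl)
    if (nrow(net$edges) == 0) next
    fams <- unique(wl$varieties$family)
    presence <- sapply(fams, function(f) {
      sub <- subnetwork_by_family(net, wl, f)
      paste(net$edges$concept_a, net$edges$concept_b) %in%
        paste(sub$edges$concept_a, sub$edges$concept_b)
    })
    expect_equal(unname(rowSums(matrix(presence, nrow = nrow(net$edges)))),
                 as.numeric(net$edges$family_count))
  }
})

test_that("network construction matches the brute-force oracle on mini-wordlists", {
  set.seed(41)
  for (rep in 1:40) {
    wl <- random_mini_wordlist()
    net <- build_network(wl)
    oracle <- brute_colex_edges(wl, wl$concepts)
    got <- dplyr::arrange(
      net$edges[, c("concept_a", "concept_b", "variety_count",
                    "family_count")],
      concept_a, concept_b
    )
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("adding a variety never removes an edge or decreases a count", {
  set.seed(51)
  for (rep in 1:5) {
    wl_small <- random_mini_wordlist(n_var = 4)
    extra <- tibble::tibble(
      variety_id = "v99",
      concept_id = wl_small$concepts$concept_id,
      form = sample(c("baku", "mina", "kuna"),
                    nrow(wl_small$concepts), replace = TRUE),
      segments = NA_character_
    )
    wl_big <- make_wordlist(
      dplyr::bind_rows(wl_small$forms, extra),
      dplyr::bind_rows(wl_small$varieties, variety_meta("v99", "F9")),
      wl_small$concepts
    )
    e_small <- build_network(wl_small)$edges
    e_big <- build_network(wl_big)$edges
    joined <- dplyr::left_join(
      e_small, e_big, by = c("concept_a", "concept_b"),
      suffix = c("_small", "_big")
    )
    expect_false(anyNA(joined$variety_count_big))
    expect_true(all(joined$variety_count_big >= joined$variety_count_small))
    expect_true(all(joined$family_count_big >= joined$family_count_small))
  }
})
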