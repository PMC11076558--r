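# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: ARI from raw pair counts, expected MI by
# enumerating label permutations, modularity by exhaustive evaluation,
# colexification edges by a brute-force double loop.

# all set partitions of n elements as restricted-growth label vectors
all_set_partitions <- function(n) {
  res <- list()
  rec <- function(labels, k) {
    if (length(labels) == n) {
      res[[length(res) + 1]] <<- labels
      return(invisible())
    }
    for (j in seq_len(k + 1)) rec(c(labels, j), max(k, j))
  }
  rec(integer(0), 0L)
  res
}

# Hubert-Arabie ARI from the four pair-agreement counts
ari_pair_oracle <- function(x, y) {
  n <- length(x)
  idx <- t(combn(n, 2))
  sx <- x[idx[, 1]] == x[idx[, 2]]
  sy <- y[idx[, 1]] == y[idx[, 2]]
  a <- sum(sx & sy)
  b <- sum(sx & !sy)
  cc <- sum(!sx & sy)
  d <- sum(!sx & !sy)
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

mi_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (u in unique(x)) {
    for (v in unique(y)) {
      nij <- sum(x == u & y == v)
      if (nij > 0) {
        mi <- mi + (nij / n) * log(n * nij / (sum(x == u) * sum(y == v)))
      }
    }
  }
  mi
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# E[MI] under the fixed-margins permutation model, by full enumeration
emi_perm_oracle <- function(x, y) {
  perms <- all_permutations(length(x))
  mean(vapply(perms, function(p) mi_oracle(x[p], y), numeric(1)))
}

ami_oracle <- function(x, y) {
  n <- length(x)
  h <- function(z) {
    p <- table(z) / n
    -sum(p * log(p))
  }
  mi <- mi_oracle(x, y)
  emi <- emi_perm_oracle(x, y)
  denom <- (h(x) + h(y)) / 2 - emi
  if (abs(denom) < 1e-12) {
    canon <- function(v) match(v, unique(v))
    return(if (identical(canon(x), canon(y))) 1 else 0)
  }
  (mi - emi) / denom
}

# Newman modularity of a labeling on a weighted undirected edge list
modularity_oracle <- function(edges, labels) {
  m2 <- 2 * sum(edges$weight)
  strength <- tapply(
    c(edges$weight, edges$weight),
    c(edges$concept_a, edges$concept_b), sum
  )
  q <- 0
  for (i in seq_len(nrow(edges))) {
    if (labels[[edges$concept_a[i]]] == labels[[edges$concept_b[i]]]) {
      q <- q + edges$weight[i] / (m2 / 2)
    }
  }
  for (u in names(strength)) {
    for (v in names(strength)) {
      if (labels[[u]] == labels[[v]]) {
        q <- q - strength[[u]] * strength[[v]] / m2^2
      }
    }
  }
  q
}

# brute-force colexification network: double loop over concept pairs and
# varieties, whole-normalized-form identity
brute_colex_edges <- function(wl, concepts, min_form_length = 2) {
  ids <- sort(concepts$concept_id)
  fams <- setNames(wl$varieties$family, wl$varieties$variety_id)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      a <- ids[j]
      b <- ids[i]
      pr <- colexnet:::canonical_pair(a, b)
      vids <- character(0)
      for (v in unique(wl$forms$variety_id)) {
        fa <- normalize_form(
          wl$forms$form[wl$forms$variety_id == v & wl$forms$concept_id == a]
        )
        fb <- normalize_form(
          wl$forms$form[wl$forms$variety_id == v & wl$forms$concept_id == b]
        )
        fa <- fa[!is.na(fa) & nchar(fa) >= min_form_length]
        fb <- fb[!is.na(fb) & nchar(fb) >= min_form_length]
        if (length(intersect(fa, fb)) > 0) vids <- c(vids, v)
      }
      if (length(vids) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          concept_a = pr$concept_a, concept_b = pr$concept_b,
          variety_count = length(vids),
          family_count = length(unique(fams[vids]))
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(concept_a = character(0), concept_b = character(0),
                          variety_count = integer(0),
                          family_count = integer(0)))
  }
  dplyr::arrange(out, concept_a, concept_b)
}

# a random mini-wordlist over few varieties/concepts with a tiny alphabet,
# so identical forms (hence colexifications) are common
random_mini_wordlist <- function(n_var = 5, n_con = 6, n_fam = 2) {
  vids <- sprintf("v%02d", seq_len(n_var))
  cids <- sprintf("c%02d", seq_len(n_con))
  forms <- expand.grid(variety_id = vids, concept_id = cids,
                       stringsAsFactors = FALSE)
  pool <- apply(expand.grid(c("ba", "ku", "mi"), c("", "na")), 1, paste0,
                collapse = "")
  forms$form <- sample(pool, nrow(forms), replace = TRUE)
  forms$segments <- NA_character_
  # random coverage gaps
  forms <- forms[runif(nrow(forms)) < 0.85, ]
  colexnet:::new_wordlist(
    forms,
    tibble::tibble(variety_id = vids, glottocode = NA_character_,
                   family = sprintf("F%d", ((seq_len(n_var) - 1) %% n_fam) + 1),
                   latitude = NA_real_, longitude = NA_real_),
    tibble::tibble(concept_id = cids, gloss = cids, domain = "body")
  )
}

# in-code wordlist constructor for hand-built fixtures
make_wordlist <- function(forms, varieties, concepts) {
  colexnet:::new_wordlist(tibble::as_tibble(forms),
                          tibble::as_tibble(varieties),
                          tibble::as_tibble(concepts))
}

variety_meta <- function(ids, families) {
  tibble::tibble(variety_id = ids, glottocode = NA_character_,
                 family = families, latitude = NA_real_,
                 longitude = NA_real_)
}

concept_list <- function(ids, domain = "body") {
  tibble::tibble(concept_id = ids, gloss = ids, domain = domain)
}
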