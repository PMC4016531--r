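# Independent brute-force oracles and shared fixtures. Every oracle works
# from a plain edge data.frame / domain list, never through the package's
# graph structure, so agreement tests are a genuine dual route.

# the small worked network used across modules:
# A-B:3, B-C:5, A-C:1, C-D:2, A-D:4, D-E:6
g0_edges <- function() {
  data.frame(a = c("A", "B", "A", "C", "A", "D"),
             b = c("B", "C", "C", "D", "D", "E"),
             weight = c(3, 5, 1, 2, 4, 6),
             stringsAsFactors = FALSE)
}
g0_network <- function() ppi_network(g0_edges())

# Erdos-Renyi weighted graph on <= 12 vertices for property tests
random_graph_edges <- function(n_vertices, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    v <- sprintf("V%02d", seq_len(n_vertices))
    pairs <- t(utils::combn(v, 2))
    pick <- stats::runif(nrow(pairs)) < p
    data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
               weight = round(stats::runif(sum(pick), 0.5, 10), 3),
               stringsAsFactors = FALSE)
  })
}

random_domains <- function(proteins, n_domains = 4, max_per = 3, seed = 1) {
  withr::with_seed(seed, {
    doms <- sprintf("d%d", seq_len(n_domains))
    stats::setNames(lapply(proteins, function(p) {
      k <- sample(0:max_per, 1)
      if (k == 0) character(0) else sample(doms, k, replace = TRUE)
    }), proteins)
  })
}

# oracle: does the pair (p, q) have an edge in the raw edge table?
oracle_weight <- function(edges, p, q) {
  hit <- (edges$a == p & edges$b == q) | (edges$a == q & edges$b == p)
  if (any(hit)) max(edges$weight[hit]) else NA_real_
}

# oracle: connected iff >= 2 of the 3 pairs carry an edge
oracle_connected <- function(edges, trip) {
  pairs <- utils::combn(sort(trip), 2)
  n_present <- sum(apply(pairs, 2, function(pq) {
    !is.na(oracle_weight(edges, pq[1], pq[2]))
  }))
  n_present >= 2
}

# oracle: all connected triplets by cubic scan over vertex 3-subsets
oracle_all_triplets <- function(edges) {
  v <- sort(unique(c(edges$a, edges$b)))
  if (length(v) < 3) return(character(0))
  subs <- utils::combn(v, 3, simplify = FALSE)
  keep <- vapply(subs, function(s) oracle_connected(edges, s), TRUE)
  sort(vapply(subs[keep], triplet_key, ""))
}

# oracle: neighboring sets by filtering the brute-force triplet list
oracle_neighbors <- function(edges, trip) {
  all_keys <- oracle_all_triplets(edges)
  self <- triplet_key(trip)
  share <- vapply(triplet_members(all_keys), function(m) {
    length(intersect(m, trip)) >= 1
  }, TRUE)
  sort(setdiff(all_keys[share], self))
}

# oracle: the 7 features by direct enumeration of all pairs
oracle_phase1 <- function(edges, dom_list, trip) {
  trip <- sort(trip)
  ipairs <- utils::combn(trip, 2)
  internal <- apply(ipairs, 2, function(pq) {
    oracle_weight(edges, pq[1], pq[2])
  })
  internal <- internal[!is.na(internal)]
  v <- sort(unique(c(edges$a, edges$b)))
  ext <- expand.grid(p = trip, r = setdiff(v, trip),
                     stringsAsFactors = FALSE)
  ext$w <- mapply(function(p, r) oracle_weight(edges, p, r), ext$p, ext$r)
  ext <- ext[!is.na(ext$w), , drop = FALSE]
  f3 <- if (nrow(ext) > 0) max(ext$w) else 0
  f4 <- if (nrow(ext) > 0) min(ext$w) else 0
  f5 <- 0
  for (r in unique(ext$r)) {
    wr <- ext$w[ext$r == r]
    if (length(wr) >= 2) {
      for (i in seq_along(wr)) for (j in seq_along(wr)) {
        if (i < j) f5 <- max(f5, min(wr[i], wr[j]))
      }
    }
  }
  counts <- vapply(trip, function(p) {
    if (p %in% names(dom_list)) length(dom_list[[p]]) else 0L
  }, 1L)
  c(F1 = max(internal), F2 = min(internal), F3 = f3, F4 = f4, F5 = f5,
    F6 = max(counts), F7 = min(counts))
}

# oracle: composition equivalence by explicit iteration over all 6
# permutations, comparing sorted domain multisets
oracle_kc <- function(dom_list, t1, t2) {
  comp <- function(p) {
    if (p %in% names(dom_list)) sort(dom_list[[p]]) else character(0)
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (s in perms) {
    if (all(vapply(1:3, function(k) {
      identical(comp(t1[k]), comp(t2[s[k]]))
    }, TRUE))) {
      return(1)
    }
  }
  0
}

# small planted fixture shared by the two-phase and evaluation tests
small_benchmark <- function(seed = 3) {
  generate_synthetic(synthetic_spec(n_background_proteins = 30,
                                    n_heterotrimers = 12,
                                    n_large_complexes = 4,
                                    seed = seed))
}
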