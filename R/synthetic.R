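#' Specification of a synthetic planted-complex benchmark
#'
#' Describes a random weighted interaction network with planted
#' heterotrimers (triangles with high internal weights), planted larger
#' complexes (cliques, the negative-example source), sparse background
#' edges with lower weights, and random domain annotations. The defaults
#' describe the package's standard small benchmark: disjoint planted
#' trimers (the regime the two-phase method assumes, where heterotrimers
#' rarely share proteins) whose internal interaction weights clearly exceed
#' the background.
#'
#' @param n_background_proteins proteins in addition to planted-complex
#'   members
#' @param n_heterotrimers number of planted 3-protein complexes
#' @param n_large_complexes number of planted larger complexes
#' @param large_size_range inclusive size range of the larger complexes
#' @param internal_weight `c(mean, sd)` of planted intra-complex edge
#'   weights (truncated to be positive)
#' @param background_weight `c(mean, sd)` of random background edge weights
#' @param background_edge_prob probability of a background edge between any
#'   protein pair
#' @param n_domain_types number of distinct domain identifiers
#' @param domains_per_protein inclusive range of per-protein domain counts
#' @param overlap_prob probability that a planted heterotrimer reuses one
#'   protein of a previously planted heterotrimer
#' @param domain_signal_prob probability that a planted heterotrimer's
#'   members receive a shared, complex-specific domain signature instead of
#'   random domains, so the domain composition kernel carries signal
#'   (0 disables, the default: domains are then pure noise)
#' @param seed integer seed
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_background_proteins = 100,
                           n_heterotrimers = 40,
                           n_large_complexes = 10,
                           large_size_range = c(4, 6),
                           internal_weight = c(mean = 50, sd = 10),
                           background_weight = c(mean = 10, sd = 5),
                           background_edge_prob = 0.02,
                           n_domain_types = 30,
                           domains_per_protein = c(1, 3),
                           overlap_prob = 0,
                           domain_signal_prob = 0,
                           seed = 7) {
  spec <- list(n_background_proteins = n_background_proteins,
               n_heterotrimers = n_heterotrimers,
               n_large_complexes = n_large_complexes,
               large_size_range = large_size_range,
               internal_weight = internal_weight,
               background_weight = background_weight,
               background_edge_prob = background_edge_prob,
               n_domain_types = n_domain_types,
               domains_per_protein = domains_per_protein,
               overlap_prob = overlap_prob,
               domain_signal_prob = domain_signal_prob,
               seed = seed)
  stopifnot(n_background_proteins >= 0,
            internal_weight[1] > background_weight[1],
            background_edge_prob >= 0, background_edge_prob <= 1,
            overlap_prob >= 0, overlap_prob <= 1,
            domain_signal_prob >= 0, domain_signal_prob <= 1,
            n_heterotrimers >= 0, n_large_complexes >= 0,
            large_size_range[1] >= 4)
  structure(spec, class = "synthetic_spec")
}

#' Benchmark preset mirroring the 80-positive / 100-negative design
#'
#' Plants 80 heterotrimers and 12 larger complexes of size 4 to 6 (whose
#' connected 3-subsets supply a negative pool comfortably above 100);
#' otherwise identical to [synthetic_spec()] defaults.
#'
#' @param seed integer seed
#' @return a `synthetic_spec`
#' @export
benchmark_spec <- function(seed = 7) {
  synthetic_spec(n_heterotrimers = 80, n_large_complexes = 12, seed = seed)
}

# positive truncated-normal draws (resample any non-positive values)
rtruncnorm_pos <- function(n, mean, sd) {
  w <- stats::rnorm(n, mean, sd)
  while (any(w <= 0)) {
    bad <- w <= 0
    w[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  w
}

#' Generate a synthetic network, domain annotation and complex catalogue
#'
#' Planted heterotrimers are triangles and larger complexes complete
#' cliques, with edge weights drawn from the internal weight distribution;
#' background edges are sprinkled independently with the background
#' distribution. When an edge is planted more than once (or coincides with
#' a background edge), the maximum weight wins, matching the reader's
#' duplicate rule. Domains are assigned uniformly at random. Each
#' generation stage draws from its own seed derived from `spec$seed`, so
#' sub-streams are independently reproducible; the whole output is
#' deterministic under a fixed spec.
#'
#' @param spec a [synthetic_spec()]
#' @return list with elements `net` ([ppi_network]), `dom`
#'   ([domain_annotation]), `cat` ([complex_catalogue]) and `truth` (list:
#'   `heterotrimers`, `large_complexes` as lists of member vectors)
#' @export
generate_synthetic <- function(spec) {
  trimer_proteins <- 3L * spec$n_heterotrimers
  # sizes cycle deterministically through the range so the negative pool
  # (3-subsets of the larger complexes) has a fixed, spec-determined size
  large_sizes <- if (spec$n_large_complexes > 0) {
    rep_len(seq(spec$large_size_range[1], spec$large_size_range[2]),
            spec$n_large_complexes)
  } else integer(0)
  n_total <- spec$n_background_proteins + trimer_proteins + sum(large_sizes)
  if (n_total < 3L) stop("infeasible spec: fewer than 3 proteins in total")
  proteins <- sprintf("P%04d", seq_len(n_total))

  # plant heterotrimers; with overlap_prob, reuse one protein of an
  # earlier trimer (the default regime keeps them vertex-disjoint)
  trimers <- list()
  fresh <- proteins
  withr::with_seed(spec$seed + 23L, {
    for (i in seq_len(spec$n_heterotrimers)) {
      members <- fresh[1:3]
      fresh <- fresh[-(1:3)]
      if (i > 1L && spec$overlap_prob > 0 &&
          stats::runif(1) < spec$overlap_prob) {
        prev <- unlist(trimers)
        members[1] <- sample(prev, 1)
        members <- unique(members)
        while (length(members) < 3L) {
          members <- unique(c(members, fresh[1]))
          fresh <- fresh[-1]
        }
      }
      trimers[[i]] <- sort(members)
    }
  })
  larges <- list()
  for (s in large_sizes) {
    larges[[length(larges) + 1L]] <- sort(fresh[seq_len(s)])
    fresh <- fresh[-seq_len(s)]
  }

  planted_pairs <- function(members) t(utils::combn(members, 2))
  planted <- do.call(rbind, c(lapply(trimers, planted_pairs),
                              lapply(larges, planted_pairs)))
  edges <- if (is.null(planted)) {
    data.frame(a = character(), b = character(), weight = numeric())
  } else {
    data.frame(a = planted[, 1], b = planted[, 2],
               weight = withr::with_seed(spec$seed + 37L,
                 rtruncnorm_pos(nrow(planted), spec$internal_weight[1],
                                spec$internal_weight[2])),
               stringsAsFactors = FALSE)
  }

  if (spec$background_edge_prob > 0 && n_total >= 2L) {
    pairs <- t(utils::combn(proteins, 2))
    withr::with_seed(spec$seed + 53L, {
      pick <- stats::runif(nrow(pairs)) < spec$background_edge_prob
      if (any(pick)) {
        bg <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                         weight = rtruncnorm_pos(sum(pick),
                                                 spec$background_weight[1],
                                                 spec$background_weight[2]),
                         stringsAsFactors = FALSE)
        edges <- rbind(edges, bg)
      }
    })
  }
  net <- suppressWarnings(ppi_network(edges))

  domain_ids <- sprintf("D%03d", seq_len(spec$n_domain_types))
  dom_list <- withr::with_seed(spec$seed + 71L, {
    counts <- sample(seq(spec$domains_per_protein[1],
                         spec$domains_per_protein[2]),
                     n_total, replace = TRUE)
    dl <- stats::setNames(lapply(counts, function(k) {
      sample(domain_ids, k, replace = TRUE)
    }), proteins)
    if (spec$domain_signal_prob > 0) {
      # shared signature: member k of a signalled trimer always carries
      # composition sig_comps[[k]], making such trimers equivalent under
      # the domain composition kernel
      sig_comps <- list("Dsig1", c("Dsig1", "Dsig2"), "Dsig2")
      for (tri in trimers) {
        if (stats::runif(1) < spec$domain_signal_prob) {
          for (k in 1:3) dl[[tri[k]]] <- sig_comps[[k]]
        }
      }
    }
    dl
  })
  dom <- domain_annotation(dom_list)

  cat <- complex_catalogue(c(trimers, larges))
  list(net = net, dom = dom, cat = cat,
       truth = list(heterotrimers = trimers, large_complexes = larges))
}

#' Write a generated benchmark to TSV files
#'
#' @param data output of [generate_synthetic()]
#' @param dir output directory (created if missing)
#' @return named character vector of the three file paths
#' @export
write_synthetic <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             domains = file.path(dir, "domains.tsv"),
             catalogue = file.path(dir, "catalogue.tsv"))
  write_interaction_table(data$net, paths["network"])
  write_domain_table(data$dom, paths["domains"])
  write_complex_catalogue(data$cat, paths["catalogue"])
  paths
}
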