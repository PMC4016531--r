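#' Canonical protein triplet
#'
#' A candidate heterotrimer: an unordered set of exactly three distinct
#' protein IDs, represented canonically as a lexicographically sorted
#' character vector of length 3. All equality and hashing go through this
#' canonical form.
#'
#' @param members character vector of three distinct protein IDs (any order)
#' @return sorted character vector of length 3, class `protein_triplet`
#' @export
triplet <- function(members) {
  members <- as.character(members)
  if (length(members) != 3L || anyDuplicated(members)) {
    stop("a triplet requires exactly three distinct protein IDs")
  }
  structure(sort(members), class = "protein_triplet")
}

#' Canonical string key of a triplet
#'
#' @param x character vector of 3 protein IDs (sorted or not)
#' @return single string usable as hash key
#' @export
triplet_key <- function(x) paste(sort(as.character(x)), collapse = "\r")

key_to_triplet <- function(k) strsplit(k, "\r", fixed = TRUE)

#' Is a triplet connected in the network?
#'
#' Three proteins are connected when the interaction edges present among them
#' (2 or 3 of the possible 3) form a single connected subgraph: a path or a
#' triangle. With at most 3 vertices, this is equivalent to having at least
#' two of the three possible edges.
#'
#' @param net a [ppi_network]
#' @param x triplet (character vector of 3 distinct protein IDs)
#' @return logical
#' @export
is_connected_triplet <- function(net, x) {
  x <- sort(as.character(x))
  if (length(x) != 3L || anyDuplicated(x)) return(FALSE)
  n12 <- !is.na(edge_weight(net, x[1], x[2]))
  n13 <- !is.na(edge_weight(net, x[1], x[3]))
  n23 <- !is.na(edge_weight(net, x[2], x[3]))
  (n12 + n13 + n23) >= 2L
}

#' Enumerate all connected triplets of a network
#'
#' Walks the edge list: each edge (i, j) is extended by every neighbor of i
#' or j, so enumeration cost scales with edges times degree rather than with
#' all 3-subsets of vertices. Every connected triplet contains at least one
#' edge plus a third vertex adjacent to an endpoint, so each is found; output
#' is deduplicated and sorted for reproducible order.
#'
#' @param net a [ppi_network]
#' @return character vector of canonical triplet keys, sorted; use
#'   [triplet_members()] to recover the member IDs
#' @export
enumerate_connected_triplets <- function(net) {
  e <- net$edges
  if (nrow(e) == 0L) return(character(0))
  keys <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- e$a[i]; b <- e$b[i]
    cand <- setdiff(unique(c(names(neighbors(net, a)),
                             names(neighbors(net, b)))), c(a, b))
    if (length(cand) == 0L) next
    m <- rbind(rep(a, length(cand)), rep(b, length(cand)), cand)
    keys[[i]] <- apply(apply(m, 2, sort), 2, paste, collapse = "\r")
  }
  ks <- unlist(keys)
  if (is.null(ks)) return(character(0))
  sort(unique(ks))
}

#' Member IDs of triplet keys
#'
#' @param keys character vector of canonical triplet keys
#' @return list of character vectors of length 3
#' @export
triplet_members <- function(keys) key_to_triplet(keys)

#' Connected triplets containing a given protein
#'
#' Local enumeration: for each neighbor q of p, extend the edge (p, q) by
#' neighbors of p or q; additionally p may hang off an edge (q, r) between
#' two of its neighbors, which the same extension covers since r is then a
#' neighbor of p. No full network scan is performed.
#'
#' @param net a [ppi_network]
#' @param p protein ID
#' @return character vector of canonical triplet keys
#' @noRd
triplets_containing <- function(net, p) {
  nb <- names(neighbors(net, p))
  if (length(nb) == 0L) return(character(0))
  keys <- character(0)
  for (q in nb) {
    cand <- setdiff(unique(c(nb, names(neighbors(net, q)))), c(p, q))
    if (length(cand) == 0L) next
    m <- rbind(rep(p, length(cand)), rep(q, length(cand)), cand)
    keys <- c(keys, apply(apply(m, 2, sort), 2, paste, collapse = "\r"))
  }
  sort(unique(keys))
}

#' Neighboring triplets N(x)
#'
#' Every connected triplet that shares at least one protein with `x`,
#' excluding `x` itself. The neighborhood is defined over the whole network,
#' not over any labeled dataset.
#'
#' @param net a [ppi_network]
#' @param x triplet (character vector of 3 distinct protein IDs)
#' @return character vector of canonical triplet keys
#' @export
neighboring_triplets <- function(net, x) {
  x <- sort(as.character(x))
  stopifnot(length(x) == 3L, !anyDuplicated(x))
  keys <- unique(unlist(lapply(x, function(p) triplets_containing(net, p))))
  sort(setdiff(keys, triplet_key(x)))
}
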