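#' Phase-1 graph features of a protein triplet
#'
#' Computes the 7-dimensional feature vector describing a connected triplet
#' of proteins in a weighted interaction network:
#' \describe{
#'   \item{F1, F2}{maximum and minimum weight over the interaction edges
#'     present among the three members (2 or 3 edges; the minimum ranges over
#'     existing edges only, never over absent pairs)}
#'   \item{F3, F4}{maximum and minimum weight over edges between a member and
#'     an external neighboring protein}
#'   \item{F5}{maximum over external proteins r adjacent to at least two
#'     distinct members p, q of min(w_pr, w_qr); when r is adjacent to all
#'     three members this is the second-largest of its three weights
#'     (the best member pair). Evidence that a competing complex involving r
#'     exists.}
#'   \item{F6, F7}{maximum and minimum of the members' domain counts
#'     (multiset cardinality: repeated domains count each occurrence)}
#' }
#' Empty ranges (no external neighbors, no domains) yield 0.
#'
#' @param net a [ppi_network]
#' @param dom a [domain_annotation]
#' @param x triplet (character vector of 3 distinct protein IDs), connected
#'   in `net`
#' @return named numeric vector `c(F1, ..., F7)`
#' @export
phase1_features <- function(net, dom, x) {
  x <- sort(as.character(x))
  if (!is_connected_triplet(net, x)) {
    stop("triplet is not connected in the network: ",
         paste(x, collapse = ", "))
  }
  nb1 <- neighbors(net, x[1])
  nb2 <- neighbors(net, x[2])
  nb3 <- neighbors(net, x[3])

  internal <- c(nb1[x[2]], nb1[x[3]], nb2[x[3]])
  internal <- internal[!is.na(internal)]
  f1 <- max(internal)
  f2 <- min(internal)

  e1 <- nb1[!(names(nb1) %in% x)]
  e2 <- nb2[!(names(nb2) %in% x)]
  e3 <- nb3[!(names(nb3) %in% x)]
  ext <- c(e1, e2, e3)
  if (length(ext) == 0L) {
    f3 <- 0; f4 <- 0; f5 <- 0
  } else {
    f3 <- max(ext)
    f4 <- min(ext)
    # F5: per external protein seen from >=2 distinct members, the best
    # member pair gives min of its two largest weights = second largest
    counts <- table(names(ext))
    shared <- names(counts)[counts >= 2L]
    if (length(shared) == 0L) {
      f5 <- 0
    } else {
      f5 <- max(vapply(shared, function(r) {
        sort(ext[names(ext) == r], decreasing = TRUE)[2]
      }, 0))
    }
  }
  dc <- c(domain_count(dom, x[1]), domain_count(dom, x[2]),
          domain_count(dom, x[3]))
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5,
    F6 = max(dc), F7 = min(dc))
}

#' Phase-1 feature matrix for a set of triplets
#'
#' @param net a [ppi_network]
#' @param dom a [domain_annotation]
#' @param keys character vector of canonical triplet keys
#' @return numeric matrix, one row per triplet (rownames = keys), columns
#'   F1..F7
#' @export
phase1_matrix <- function(net, dom, keys) {
  members <- triplet_members(keys)
  out <- matrix(0, nrow = length(keys), ncol = 7,
                dimnames = list(keys, paste0("F", 1:7)))
  for (i in seq_along(keys)) {
    out[i, ] <- phase1_features(net, dom, members[[i]])
  }
  out
}
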