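#' Weighted protein-protein interaction network
#'
#' Constructs an undirected, weighted PPI network from an edge table. Edges
#' are stored once in canonical orientation (first endpoint lexicographically
#' smaller). Self-interactions are dropped; duplicate pairs are resolved by
#' keeping the maximum weight, preserving the "reliability score" semantics of
#' WI-PHI-style weights (a warning is emitted when duplicates collapse).
#'
#' @param edges data.frame with columns `a`, `b` (protein IDs, character) and
#'   `weight` (strictly positive numeric).
#' @return An object of class `ppi_network` with fields `edges` (canonical
#'   edge data.frame), `proteins` (sorted character vector) and `adj`
#'   (adjacency map: protein -> named numeric vector of neighbor weights).
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    edges <- data.frame(a = character(), b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  names(edges)[1:3] <- c("a", "b", "weight")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) {
    stop("non-numeric interaction weight in edge table")
  }
  if (any(edges$weight <= 0)) {
    stop("interaction weights must be strictly positive")
  }
  # drop self-interactions, canonicalise orientation
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  flip <- edges$a > edges$b
  tmp <- edges$a[flip]
  edges$a[flip] <- edges$b[flip]
  edges$b[flip] <- tmp
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate interaction pairs collapsed (maximum weight kept)")
    w <- tapply(edges$weight, key, max)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$a, edges$b, sep = "\r")])
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  proteins <- sort(unique(c(edges$a, edges$b)))
  adj <- new.env(parent = emptyenv())
  for (p in proteins) assign(p, numeric(0), envir = adj)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]; w <- edges$weight[i]
    va <- get(a, envir = adj); va[b] <- w; assign(a, va, envir = adj)
    vb <- get(b, envir = adj); vb[a] <- w; assign(b, vb, envir = adj)
  }
  structure(list(edges = edges, proteins = proteins, adj = adj),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("Weighted PPI network: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a protein
#'
#' @param net a `ppi_network`
#' @param p protein ID
#' @return Named numeric vector of interaction weights, names = neighboring
#'   protein IDs. Empty for proteins absent from the network.
#' @export
neighbors <- function(net, p) {
  if (exists(p, envir = net$adj, inherits = FALSE)) {
    get(p, envir = net$adj)
  } else {
    numeric(0)
  }
}

#' Weight of an interaction edge
#'
#' @inheritParams neighbors
#' @param q second protein ID
#' @return The edge weight, or `NA` if the edge is absent.
#' @export
edge_weight <- function(net, p, q) {
  v <- neighbors(net, p)
  if (q %in% names(v)) unname(v[[q]]) else NA_real_
}

#' Read a weighted interaction table
#'
#' Parses a WI-PHI-style tab-separated table of interacting protein pairs:
#' columns proteinA, proteinB, weight. A header line is auto-detected (first
#' row whose weight column does not parse as a number). Self-interactions are
#' dropped and duplicate pairs keep the maximum weight.
#'
#' @param path file path
#' @param sep field separator (default tab; any whitespace run when `sep` is
#'   `""`)
#' @param columns integer vector of length 3 giving the positions of the
#'   proteinA, proteinB and weight columns (dialect option; default `1:3`)
#' @return a [ppi_network]
#' @export
read_interaction_table <- function(path, sep = "\t", columns = 1:3) {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(ppi_network(data.frame(a = character(), b = character(),
                                  weight = numeric())))
  }
  split_one <- function(l) {
    if (identical(sep, "")) strsplit(trimws(l), "[ \t]+")[[1]]
    else strsplit(l, sep, fixed = TRUE)[[1]]
  }
  parts <- lapply(lines, split_one)
  first <- parts[[1]]
  start <- 1L
  if (length(first) >= max(columns) &&
      is.na(suppressWarnings(as.numeric(first[columns[3]])))) {
    start <- 2L  # header row
  }
  rows <- parts[seq.int(start, length(parts))]
  if (length(rows) == 0L) {
    return(ppi_network(data.frame(a = character(), b = character(),
                                  weight = numeric())))
  }
  bad <- which(vapply(rows, length, 1L) < max(columns))
  if (length(bad) > 0L) {
    stop(sprintf("malformed interaction row at line %d: expected %d fields",
                 bad[1] + start - 1L, max(columns)))
  }
  a <- vapply(rows, `[`, "", columns[1])
  b <- vapply(rows, `[`, "", columns[2])
  w <- suppressWarnings(as.numeric(vapply(rows, `[`, "", columns[3])))
  if (anyNA(w)) {
    stop(sprintf("malformed weight at line %d",
                 which(is.na(w))[1] + start - 1L))
  }
  if (any(w <= 0)) {
    stop(sprintf("non-positive weight at line %d",
                 which(w <= 0)[1] + start - 1L))
  }
  ppi_network(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
}

#' Write a weighted interaction table
#'
#' Writes the canonical edge list as a 3-column TSV (proteinA, proteinB,
#' weight) readable by [read_interaction_table()]. Reading the result back
#' round-trips the edge set and weights exactly.
#'
#' @param net a [ppi_network]
#' @param path output file path
#' @export
write_interaction_table <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
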