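#' Domain-composition signature of a triplet
#'
#' Canonical form deciding composition equivalence between triplets: two
#' triplets are equivalent when some permutation matches their proteins so
#' that matched proteins carry identical domain compositions (multisets of
#' domain IDs). Sorting the three per-protein compositions realises the
#' existential permutation test without iterating the symmetric group.
#'
#' @param dom a [domain_annotation]
#' @param x triplet (character vector of 3 protein IDs)
#' @return single string: the canonical signature
#' @export
triplet_signature <- function(dom, x) {
  comps <- vapply(as.character(x), function(p) {
    paste(protein_domains(dom, p), collapse = "\x1f")
  }, "")
  paste(sort(comps), collapse = "\x1e")
}

#' Signatures for a set of triplets
#'
#' @param dom a [domain_annotation]
#' @param keys canonical triplet keys
#' @return character vector of signatures, names = keys
#' @export
triplet_signatures <- function(dom, keys) {
  members <- triplet_members(keys)
  sig <- vapply(members, function(m) triplet_signature(dom, m), "")
  names(sig) <- keys
  sig
}

#' Domain composition kernel
#'
#' 0/1 kernel: 1 iff the two triplets are composition-equivalent (their
#' canonical signatures coincide), else 0.
#'
#' @param si,sj triplet signatures from [triplet_signature()]
#' @return 0 or 1
#' @export
domain_composition_kernel <- function(si, sj) as.numeric(si == sj)

#' Combined Gram matrix: inner product plus weighted domain kernel
#'
#' Element (i, j) is `<f_i, f_j> + alpha * Kc(s_i, s_j)`. With equal row and
#' column inputs this is the (symmetric, positive semidefinite for
#' `alpha >= 0`) training Gram; with distinct inputs it is the cross-Gram
#' used at prediction time (rows = test, columns = train).
#'
#' @param features numeric matrix of feature vectors (rows = examples)
#' @param signatures character vector of triplet signatures, one per row of
#'   `features`
#' @param alpha nonnegative mixing constant for the domain kernel
#' @param features2,signatures2 optional second set (columns); defaults to
#'   the first set
#' @return numeric matrix
#' @export
combined_gram <- function(features, signatures, alpha,
                          features2 = NULL, signatures2 = NULL) {
  stopifnot(alpha >= 0)
  features <- as.matrix(features)
  if (nrow(features) != length(signatures)) {
    stop("features and signatures differ in length")
  }
  if (is.null(features2)) {
    features2 <- features
    signatures2 <- signatures
  }
  features2 <- as.matrix(features2)
  if (nrow(features2) != length(signatures2)) {
    stop("features2 and signatures2 differ in length")
  }
  if (ncol(features) != ncol(features2)) {
    stop("feature dimensionality mismatch")
  }
  g <- features %*% t(features2)
  if (alpha > 0) {
    g <- g + alpha * outer(signatures, signatures2, `==`)
  }
  unname(g)
}
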