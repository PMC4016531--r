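#' Protein domain annotation
#'
#' A total map from protein ID to a multiset of domain identifiers. Proteins
#' absent from the map have the empty multiset; lookups never fail. Domains
#' are kept as multisets: a protein annotated twice with the same domain
#' counts both occurrences, consistent with the "number of domains" features
#' and the composition equivalence used by the domain kernel.
#'
#' @param x named list: protein ID -> character vector of domain IDs
#'   (repeats allowed)
#' @return an object of class `domain_annotation`
#' @export
domain_annotation <- function(x = list()) {
  env <- new.env(parent = emptyenv())
  for (p in names(x)) {
    cur <- if (exists(p, envir = env, inherits = FALSE))
      get(p, envir = env) else character(0)
    assign(p, sort(c(cur, as.character(x[[p]]))), envir = env)
  }
  structure(list(map = env), class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("Domain annotation: %d annotated proteins\n",
              length(ls(x$map))))
  invisible(x)
}

#' Domain composition of a protein
#'
#' @param dom a [domain_annotation]
#' @param p protein ID
#' @return Sorted character vector of domain IDs (the multiset composition);
#'   `character(0)` for unannotated proteins.
#' @export
protein_domains <- function(dom, p) {
  if (exists(p, envir = dom$map, inherits = FALSE)) {
    get(p, envir = dom$map)
  } else {
    character(0)
  }
}

#' Number of domains of a protein (multiset cardinality)
#'
#' @inheritParams protein_domains
#' @return nonnegative integer count
#' @export
domain_count <- function(dom, p) length(protein_domains(dom, p))

#' Read a protein-domain annotation table
#'
#' TSV rows: protein ID followed by zero or more domain IDs. Repeated rows
#' for the same protein merge their multisets.
#'
#' @param path file path
#' @return a [domain_annotation]
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (l in lines) {
    f <- strsplit(trimws(l), "[ \t]+")[[1]]
    p <- f[1]
    doms <- if (length(f) > 1L) f[-1] else character(0)
    out[[length(out) + 1L]] <- doms
    names(out)[length(out)] <- p
  }
  domain_annotation(out)
}

#' Write a protein-domain annotation table
#'
#' @param dom a [domain_annotation]
#' @param path output file path
#' @export
write_domain_table <- function(dom, path) {
  ps <- sort(ls(dom$map))
  lines <- vapply(ps, function(p) {
    paste(c(p, protein_domains(dom, p)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
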