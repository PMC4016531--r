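#' Protein complex catalogue
#'
#' A CYC2008-style list of curated complexes, each an unordered set of at
#' least two distinct proteins. Size-3 complexes (heterotrimers) are the
#' positive-example source; complexes of size greater than three supply the
#' negative pool.
#'
#' @param complexes list of character vectors (member protein IDs)
#' @return an object of class `complex_catalogue`
#' @export
complex_catalogue <- function(complexes) {
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  sizes <- vapply(complexes, length, 1L)
  if (any(sizes < 2L)) {
    stop("complex with fewer than 2 distinct members at entry ",
         which(sizes < 2L)[1])
  }
  structure(list(complexes = complexes, sizes = sizes),
            class = "complex_catalogue")
}

#' @export
print.complex_catalogue <- function(x, ...) {
  cat(sprintf("Complex catalogue: %d complexes (sizes %d-%d)\n",
              length(x$complexes), min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' @export
length.complex_catalogue <- function(x) length(x$complexes)

#' Subset a catalogue by complex size
#'
#' @param cat a [complex_catalogue]
#' @param size exact size to keep, or `NULL`
#' @param min_size keep complexes of at least this size (ignored when `size`
#'   given)
#' @return a [complex_catalogue] with the matching complexes
#' @export
catalogue_by_size <- function(cat, size = NULL, min_size = NULL) {
  keep <- if (!is.null(size)) cat$sizes == size
  else if (!is.null(min_size)) cat$sizes >= min_size
  else rep(TRUE, length(cat$sizes))
  if (!any(keep)) {
    return(structure(list(complexes = list(), sizes = integer()),
                     class = "complex_catalogue"))
  }
  complex_catalogue(cat$complexes[keep])
}

#' Fraction of complexes of a given size
#'
#' E.g. the heterodimeric or heterotrimeric share of a curated catalogue,
#' as a percentage of all catalogued complexes.
#'
#' @param cat a [complex_catalogue]
#' @param size complex size of interest
#' @return percentage in [0, 100]
#' @export
catalogue_size_percent <- function(cat, size) {
  100 * sum(cat$sizes == size) / length(cat$complexes)
}

#' Read a complex catalogue
#'
#' One complex per line, member protein IDs separated by whitespace or tabs
#' (CYC2008-style flat export).
#'
#' @param path file path
#' @return a [complex_catalogue]
#' @export
read_complex_catalogue <- function(path) {
  if (!file.exists(path)) stop("complex catalogue not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  members <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  bad <- which(vapply(members, function(m) length(unique(m)), 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("complex with fewer than 2 distinct members at line %d",
                 bad[1]))
  }
  complex_catalogue(members)
}

#' Write a complex catalogue
#'
#' @param cat a [complex_catalogue]
#' @param path output file path
#' @export
write_complex_catalogue <- function(cat, path) {
  writeLines(vapply(cat$complexes, paste, "", collapse = "\t"), path)
  invisible(path)
}
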