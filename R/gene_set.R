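#' Gene sets
#'
#' A `gene_set` is the currency of every stage of the workflow: a named,
#' deduplicated, ordered collection of uppercase gene symbols. Symbols are
#' normalized on construction (whitespace trimmed, upper-cased) and
#' deduplicated preserving first occurrence. Two gene sets are considered
#' equal when they contain the same symbols regardless of order.
#'
#' @param genes character vector of gene symbols.
#' @param name short label for the set (e.g. a cohort or module name).
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `genes`.
#' @examples
#' gene_set(c("icam1", "ICAM1", "Ccl2"), name = "toy")
#' @export
gene_set <- function(genes, name = "gene_set") {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- normalize_symbols(genes)
  if (anyNA(genes)) stop("gene symbols must not be NA")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Normalize gene symbols
#'
#' Trims surrounding whitespace, upper-cases, drops empty strings and
#' deduplicates preserving first occurrence. No alias resolution is
#' attempted.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  x <- trimws(as.character(x))
  x <- toupper(x[nzchar(x)])
  x[!duplicated(x)]
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' with %d genes\n", x$name, length(x$genes)))
  shown <- utils::head(x$genes, 10L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Coerce to a plain symbol vector
#'
#' Accepts a `gene_set` or a character vector; always returns normalized
#' symbols. Used throughout so that every operation takes either form.
#'
#' @param x gene_set or character vector.
#' @return character vector of normalized symbols.
#' @export
as_symbols <- function(x) {
  if (inherits(x, "gene_set")) return(x$genes)
  normalize_symbols(x)
}

#' Set operations on gene sets
#'
#' Order-preserving intersection/union/difference on normalized symbols
#' (first argument's order wins).
#'
#' @param x,y gene_set or character.
#' @param name label for the result.
#' @return gene_set.
#' @export
gs_intersect <- function(x, y, name = "intersection") {
  a <- as_symbols(x); b <- as_symbols(y)
  gene_set(a[a %in% b], name = name)
}

#' @rdname gs_intersect
#' @export
gs_union <- function(x, y, name = "union") {
  gene_set(c(as_symbols(x), as_symbols(y)), name = name)
}

#' @rdname gs_intersect
#' @export
gs_setdiff <- function(x, y, name = "difference") {
  a <- as_symbols(x); b <- as_symbols(y)
  gene_set(a[!(a %in% b)], name = name)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path path to a plain text file, one symbol per line. An optional
#'   single header line can be skipped with `header = TRUE`.
#' @param name label for the resulting set; defaults to the file base name.
#' @param header logical; skip the first line.
#' @return gene_set.
#' @export
read_gene_list <- function(path, name = NULL, header = FALSE) {
  if (!file.exists(path)) stop("cannot read gene list: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1L]
  genes <- normalize_symbols(lines)
  if (length(genes) == 0L) stop("empty gene list: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(genes, name = name)
}

#' Write a gene list, one symbol per line
#'
#' @param x gene_set or character.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_symbols(x), path)
  invisible(path)
}

#' Gene set collections (GMT)
#'
#' A `gene_set_collection` is a named list of `gene_set`s with unique term
#' names and optional term descriptions, as read from a standard GMT file
#' (term name, description, then tab-separated member symbols).
#'
#' @param sets named list of gene_set or character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("all terms must be named")
  if (anyDuplicated(nm)) stop("term names must be unique")
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s else gene_set(s, name = nm[i])
  })
  names(sets) <- nm
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets, descriptions = stats::setNames(descriptions, nm)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d terms (median size %s)\n",
              length(x$sets),
              stats::median(vapply(x$sets, length, 1L))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT file
#'
#' @param path GMT path; each line must have at least three tab-separated
#'   fields (name, description, members...).
#' @return gene_set_collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) {
    stop("GMT format error: line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  }
  nms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(seq_along(fields), function(i) {
    gene_set(fields[[i]][-(1:2)], name = nms[i])
  })
  names(sets) <- nms
  gene_set_collection(sets, descriptions = desc)
}

#' Write a GMT file
#'
#' @param collection gene_set_collection.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
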