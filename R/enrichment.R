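# Hypergeometric over-representation analysis of a query gene/protein set
# against a GMT collection, BH-corrected.  One-sided upper tail: standard
# GO ORA semantics.

#' Construct a gene-set collection
#'
#' @param sets Named list; each element is a list with fields
#'   `description` (character) and `genes` (character vector).
#' @param universe Character vector of background gene ids.  Set members
#'   outside the universe are dropped at construction.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe) {
  .check(is.list(sets) && !is.null(names(sets)) && !anyDuplicated(names(sets)),
         "sets must be a named list with unique set ids")
  universe <- unique(as.character(universe))
  .check(length(universe) > 0L, "universe must be non-empty")
  sets <- lapply(sets, function(s) {
    .check(is.list(s) && !is.null(s$genes), "each set needs a 'genes' field")
    list(description = as.character(s$description %||% ""),
         genes = intersect(unique(as.character(s$genes)), universe))
  })
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation of a query against a collection
#'
#' The query and every set are restricted to the collection's universe;
#' sets with restricted size outside `[min_set, max_set]` are excluded.
#' Per set, the upper-tail hypergeometric p-value of the observed overlap
#' is computed ([hypergeom_tail()]) and BH-adjusted across the tested sets.
#'
#' @param query Character vector of query gene ids.
#' @param collection A [gene_set_collection()].
#' @param min_set,max_set Set-size filters after universe restriction
#'   (defaults 5 and 500).
#' @return A data.frame with one row per tested set: `set_id`,
#'   `description`, `k` (overlap), `K` (set size), `n` (query size),
#'   `N` (universe size), `fold_enrichment`, `p_value`, `p_adj`; sorted by
#'   p-value, ties broken by set id.
#' @export
enrich <- function(query, collection, min_set = 5, max_set = 500) {
  .check(inherits(collection, "gene_set_collection"),
         "collection must be a gene_set_collection")
  query <- intersect(unique(as.character(query)), collection$universe)
  .check(length(query) > 0L, "query has no gene in the universe")
  N <- length(collection$universe)
  n <- length(query)
  sizes <- vapply(collection$sets, function(s) length(s$genes), integer(1))
  keep <- sizes >= min_set & sizes <= max_set
  .check(any(keep), "no set within [min_set, max_set] after restriction")
  ids <- names(collection$sets)[keep]
  rows <- lapply(ids, function(id) {
    s <- collection$sets[[id]]
    K <- length(s$genes)
    k <- length(intersect(query, s$genes))
    data.frame(set_id = id, description = s$description,
               k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: id, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @param universe Background gene ids; defaults to the union of all set
#'   members in the file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .check(length(lines) > 0L, "empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    .check(length(f) >= 3L, "malformed GMT line (need id, description, genes)")
    sets[[f[1]]] <- list(description = f[2], genes = f[-(1:2)])
  }
  if (is.null(universe))
    universe <- unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  .check(inherits(collection, "gene_set_collection"),
         "collection must be a gene_set_collection")
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
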