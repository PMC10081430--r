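#' Read an HPO-style ontology from an OBO file
#'
#' Minimal OBO 1.2 reader covering the stanza fields this pipeline needs:
#' `[Term]` blocks with `id`, `name` and `is_a` lines (obsolete terms are
#' skipped). Works with the full Human Phenotype Ontology as well as the
#' miniature ontologies emitted by [simulate_cohort()].
#'
#' @param path path to the `.obo` file.
#' @return An object of class `hpo_ontology`: term ids, names, parent lists
#'   and the depth of each term (shortest is_a path to a root, root = 0).
#' @export
read_hpo_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanzas found in ", path)
  ends <- c(term_starts[-1] - 1L, length(lines))
  ids <- character(0); nms <- character(0); parents <- list()
  for (k in seq_along(term_starts)) {
    blk <- lines[term_starts[k]:ends[k]]
    if (any(grepl("^is_obsolete: *true", blk))) next
    id <- sub("^id: *", "", grep("^id: ", blk, value = TRUE)[1])
    if (is.na(id)) next
    nm <- sub("^name: *", "", grep("^name: ", blk, value = TRUE)[1])
    pa <- sub("^is_a: *([^ !]+).*$", "\\1", grep("^is_a: ", blk, value = TRUE))
    ids <- c(ids, id); nms <- c(nms, if (is.na(nm)) id else nm)
    parents[[id]] <- pa
  }
  names(nms) <- ids
  ## depth by breadth-first traversal from the roots
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[vapply(parents[ids], length, integer(1)) == 0L]
  depth[roots] <- 0L
  frontier <- roots
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- ids[is.na(depth) &
                 vapply(parents[ids], function(p) any(p %in% frontier), logical(1))]
    depth[nxt] <- d
    frontier <- nxt
  }
  structure(list(ids = ids, names = nms, parents = parents, depth = depth,
                 roots = roots),
            class = "hpo_ontology")
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(sprintf("<hpo_ontology> %d terms, max depth %d, root(s): %s\n",
              length(x$ids), max(x$depth, na.rm = TRUE),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

hpo_ancestors <- function(term, ontology) {
  out <- character(0)
  frontier <- ontology$parents[[term]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(ontology$parents[frontier]))
  }
  out
}

#' Ancestor closure of an HPO term set
#'
#' Expands each term to itself plus all its is_a ancestors, then removes the
#' ontology root(s) and any term of depth < 2: near-root terms are too
#' unspecific to count as shared phenotype. Terms absent from the ontology
#' are dropped with a warning.
#'
#' @param terms character vector of HPO IDs.
#' @param ontology an `hpo_ontology`.
#' @return Character vector of closure terms (depth >= 2 only).
#' @export
hpo_closure <- function(terms, ontology) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  unknown <- setdiff(terms, ontology$ids)
  if (length(unknown) > 0L) {
    warning("HPO term(s) not in ontology, ignored: ",
            paste(unknown, collapse = ", "))
    terms <- intersect(terms, ontology$ids)
  }
  cl <- unique(c(terms, unlist(lapply(terms, hpo_ancestors, ontology = ontology))))
  cl[!is.na(ontology$depth[cl]) & ontology$depth[cl] >= 2L]
}
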