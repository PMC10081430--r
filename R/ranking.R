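#' Rank all individuals for one gene
#'
#' Individuals are ranked by descending GenePy score with competition
#' ("1224") ranks: tied scores share the minimal rank and the next distinct
#' score's rank equals 1 + the count of strictly higher scores. Within a
#' tie, rows are ordered lexicographically by sample id for reproducible
#' output; rank values themselves are order-independent.
#'
#' @param x a `genepy_matrix`.
#' @param gene_id gene to rank.
#' @return data.frame (class `gene_ranking`) with columns `gene_id`,
#'   `sample_id`, `score`, `rank`, covering all samples.
#' @export
rank_gene <- function(x, gene_id) {
  stopifnot(inherits(x, "genepy_matrix"))
  if (!gene_id %in% colnames(x$scores)) stop("unknown gene: ", gene_id)
  s <- stats::setNames(x$scores[, gene_id], rownames(x$scores))
  r <- rank(-s, ties.method = "min")
  ord <- order(-s, names(s))
  out <- data.frame(gene_id = gene_id, sample_id = names(s)[ord],
                    score = unname(s[ord]), rank = as.integer(unname(r[ord])),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Rank every gene of a GenePy matrix
#'
#' @param x a `genepy_matrix`.
#' @return data.frame of stacked [rank_gene()] results.
#' @export
rank_all <- function(x) {
  out <- do.call(rbind, lapply(colnames(x$scores), function(g) rank_gene(x, g)))
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Tie-retaining top-k selection
#'
#' Keeps every individual whose competition rank is `<= k`. When several
#' individuals tie at a retained rank, all of them are kept, so the set may
#' exceed k members. Ties at score zero are retained like any other tie.
#'
#' @param ranking a `gene_ranking` from [rank_gene()] (or [rank_all()]; the
#'   rule is applied per gene either way).
#' @param k retain ranks up to k (default 5).
#' @return data.frame (class `top_set`) with the same columns as the
#'   ranking.
#' @export
top_k <- function(ranking, k = 5) {
  stopifnot(k >= 1)
  out <- ranking[ranking$rank <= k, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("top_set", "data.frame")
  out
}

#' Top-k sets for every gene of a matrix
#'
#' @param x a `genepy_matrix`.
#' @param k retain ranks up to k (default 5).
#' @return data.frame (class `top_set`) of all genes' retained entries.
#' @export
top_sets <- function(x, k = 5) {
  top_k(rank_all(x), k = k)
}

#' Invert per-gene top sets into per-sample gene lists
#'
#' @param topsets a `top_set` data.frame.
#' @param samples optional full sample vector; samples appearing in no top
#'   set map to an empty gene list.
#' @return Named list: for each sample, the character vector of genes where
#'   it is top-ranked.
#' @export
invert_topsets <- function(topsets, samples = NULL) {
  sp <- split(topsets$gene_id, topsets$sample_id)
  sp <- lapply(sp, function(g) sort(unique(g)))
  if (!is.null(samples)) {
    out <- stats::setNames(rep(list(character(0)), length(samples)), samples)
    out[names(sp)] <- sp
    out
  } else sp
}
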