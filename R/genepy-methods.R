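#' @export
print.genepy_matrix <- function(x, ...) {
  cat(sprintf("GenePy score matrix: %d samples x %d genes (%d scored variants)\n",
              nrow(x$scores), ncol(x$scores), x$n_variants))
  cat(sprintf("  deleteriousness: %s (scale %g); frequency floor: %g\n",
              x$model$mode, x$model$scale, x$policy$floor))
  nz <- x$scores[x$scores > 0]
  if (length(nz) > 0) {
    cat(sprintf("  nonzero cells: %d (%.1f%%), score range %.4g-%.4g\n",
                length(nz), 100 * length(nz) / length(x$scores),
                min(nz), max(nz)))
  } else cat("  all scores zero\n")
  invisible(x)
}

#' @export
summary.genepy_matrix <- function(object, ...) {
  s <- object$scores
  per_gene <- t(apply(s, 2, function(col)
    c(max = max(col), mean = mean(col), nonzero = sum(col > 0))))
  out <- list(n_samples = nrow(s), n_genes = ncol(s), per_gene = per_gene)
  class(out) <- "summary.genepy_matrix"
  out
}

#' @export
print.summary.genepy_matrix <- function(x, ...) {
  cat(sprintf("GenePy matrix summary: %d samples x %d genes\n",
              x$n_samples, x$n_genes))
  top <- x$per_gene[order(-x$per_gene[, "max"]), , drop = FALSE]
  utils::head(top, 10)
  print(utils::head(top, 10))
  invisible(x)
}

#' @export
as.matrix.genepy_matrix <- function(x, ...) x$scores

#' @export
dim.genepy_matrix <- function(x) dim(x$scores)

#' Heatmap of a GenePy score matrix
#'
#' Rows (samples) and columns (genes) are ordered by their total score so
#' that high-burden individuals and genes cluster in one corner; useful for
#' eyeballing outliers before ranking.
#'
#' @param x a `genepy_matrix`.
#' @param max_samples,max_genes cap on rows/columns drawn (highest totals
#'   kept).
#' @param ... passed to [graphics::image()].
#' @export
plot.genepy_matrix <- function(x, max_samples = 100, max_genes = 50, ...) {
  s <- x$scores
  rs <- order(-rowSums(s))[seq_len(min(nrow(s), max_samples))]
  cs <- order(-colSums(s))[seq_len(min(ncol(s), max_genes))]
  s <- s[rev(rs), cs, drop = FALSE]
  graphics::image(x = seq_len(ncol(s)), y = seq_len(nrow(s)), z = t(s),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "genes (by total score)",
                  ylab = "samples (by total score)",
                  main = "GenePy scores", ...)
  invisible(x)
}

#' Write a GenePy matrix to TSV
#'
#' @param x a `genepy_matrix`.
#' @param path output file.
#' @param format `"wide"` (first column sample_id, one column per gene) or
#'   `"long"` (sample_id, gene_id, score).
#' @param digits significant digits to print (default 15, full double
#'   precision).
#' @export
write_genepy_matrix <- function(x, path, format = c("wide", "long"),
                                digits = 15) {
  format <- match.arg(format)
  s <- x$scores
  fmt <- function(z) formatC(z, digits = digits, format = "g")
  if (format == "wide") {
    d <- data.frame(sample_id = rownames(s), stringsAsFactors = FALSE)
    for (g in colnames(s)) d[[g]] <- fmt(s[, g])
  } else {
    d <- data.frame(sample_id = rep(rownames(s), times = ncol(s)),
                    gene_id = rep(colnames(s), each = nrow(s)),
                    score = fmt(as.vector(s)), stringsAsFactors = FALSE)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GenePy matrix written by [write_genepy_matrix()] (wide format)
#'
#' @param path TSV file with a `sample_id` column followed by gene columns.
#' @return A `genepy_matrix` (model/policy metadata not recoverable from
#'   TSV; defaults recorded).
#' @export
read_genepy_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "sample_id") stop("expected first column sample_id in ", path)
  s <- as.matrix(d[, -1, drop = FALSE])
  mode(s) <- "numeric"
  rownames(s) <- d$sample_id
  structure(list(scores = s, model = deleteriousness_model(),
                 policy = frequency_policy(), n_variants = NA_integer_),
            class = "genepy_matrix")
}
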