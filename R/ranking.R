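#' Pearson product-moment correlation with a degenerate-input flag
#'
#' Standard Pearson correlation, except that a zero-variance input yields
#' `NA` (flagged degenerate) instead of an error or a division by zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is constant.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: length(x) = ", length(x), ", length(y) = ", length(y))
  }
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Rank genes by correlation between expression and age
#'
#' Computes the Pearson correlation of each gene's log2 expression with donor
#' age and orders genes best-first. The default ordering key is `|r|`, so
#' genes whose expression decreases with age rank alongside increasing ones;
#' `signed = TRUE` ranks by `r` descending instead. Constant (zero-variance)
#' genes have no defined correlation and are excluded; their count is
#' recorded in the result. Ties are broken lexicographically by gene
#' identifier for cross-platform determinism.
#'
#' @param matrix an [expression_matrix()] with `scale = "log2"`.
#' @param ages numeric vector of donor ages aligned with the matrix columns.
#' @param signed rank by signed `r` instead of `|r|`.
#' @return A `GeneRanking`: data frame (`gene_id`, `r`) ordered best-first,
#'   with attributes `n_samples_used` and `n_degenerate`.
#' @export
rank_genes <- function(matrix, ages, signed = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "log2") stop("rank_genes expects a log2-scale matrix")
  if (length(ages) != ncol(matrix$values)) {
    stop("ages (", length(ages), ") must align with matrix columns (",
         ncol(matrix$values), ")")
  }
  if (length(ages) < 3L) stop("need at least 3 samples to rank genes")
  r <- correlate_with_age(t(matrix$values), ages)
  degenerate <- is.na(r)
  out <- data.frame(gene_id = rownames(matrix$values)[!degenerate],
                    r = r[!degenerate], stringsAsFactors = FALSE)
  key <- if (signed) -out$r else -abs(out$r)
  out <- out[order(key, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples_used") <- length(ages)
  attr(out, "n_degenerate") <- sum(degenerate)
  class(out) <- c("GeneRanking", "data.frame")
  out
}

# Vectorized per-column Pearson correlation of a samples x genes matrix with
# a response; zero-variance columns (or a constant response) give NA.
correlate_with_age <- function(x, y) {
  n <- nrow(x)
  xc <- x - rep(colMeans(x), each = n)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  r <- as.vector(crossprod(xc, yc)) / sqrt(sxx * syy)
  r[sxx == 0 | syy == 0] <- NA_real_
  r
}

#' Take the top N genes of a ranking
#'
#' @param ranking a `GeneRanking` from [rank_genes()].
#' @param n positive number of genes; when `n` exceeds the ranking size the
#'   whole ranking is returned with a warning.
#' @return Character vector of gene identifiers in ranking order.
#' @export
top_n_genes <- function(ranking, n) {
  stopifnot(inherits(ranking, "GeneRanking"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be a positive integer")
  n <- as.integer(n)
  if (n > nrow(ranking)) {
    warning("requested ", n, " genes but the ranking has only ", nrow(ranking))
    n <- nrow(ranking)
  }
  ranking$gene_id[seq_len(n)]
}

#' Default preselection sizes
#'
#' The standard grid of top-gene counts used for model selection: 50 to 6400
#' by near-doublings.
#'
#' @return Integer vector `c(50, 100, 200, 400, 600, 800, 1600, 3200, 6400)`.
#' @export
default_n_grid <- function() c(50L, 100L, 200L, 400L, 600L, 800L, 1600L, 3200L, 6400L)

#' Export a gene ranking as TSV
#'
#' @param ranking a `GeneRanking`.
#' @param path output file; columns `gene_id`, `r`, `rank`.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "GeneRanking"))
  df <- data.frame(gene_id = ranking$gene_id,
                   r = formatC(ranking$r, digits = 7, format = "g"),
                   rank = seq_len(nrow(ranking)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
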