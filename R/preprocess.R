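#' Quantile normalization across samples
#'
#' Forces every sample (column) to share one reference distribution: the
#' vector of row means of the column-sorted matrix. Each column's values are
#' replaced by the reference values at their within-column ranks; tied values
#' receive the mean of the reference values at their tied ranks, so columns
#' that are permutations of each other become identical and the operation is
#' idempotent.
#'
#' @param matrix an [expression_matrix()] with `scale = "raw"` and at least
#'   two samples.
#' @return A quantile-normalized [expression_matrix()], still `scale = "raw"`.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw") stop("quantile normalization expects a raw-scale matrix")
  x <- matrix$values
  if (ncol(x) < 2L) stop("quantile normalization is undefined for a single sample")
  if (nrow(x) < 1L) stop("empty matrix")
  if (anyNA(x)) stop("expression values contain NA/NaN")
  reference <- rowMeans(apply(x, 2L, sort, method = "radix"))
  out <- apply(x, 2L, function(col) {
    # mean of reference values over tied ranks, via per-tie-group averaging
    r <- rank(col, ties.method = "min")
    runs <- rank(col, ties.method = "max")
    ref_cum <- cumsum(reference)
    (ref_cum[runs] - c(0, ref_cum)[r]) / (runs - r + 1)
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, scale = "raw", tissue = matrix$tissue)
}

#' Log2 transformation with pseudocount
#'
#' Replaces every value by `log2(value + pseudocount)` and flips the scale
#' flag to `"log2"`, the scale on which the age model and the gene-age
#' correlations are defined.
#'
#' @param matrix an [expression_matrix()] with `scale = "raw"`.
#' @param pseudocount non-negative offset added before taking logs; the
#'   default 1 maps zero expression to zero.
#' @return An [expression_matrix()] with `scale = "log2"`.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw") stop("matrix is already on the log2 scale")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("'pseudocount' must be a single non-negative number")
  }
  x <- matrix$values + pseudocount
  if (any(x <= 0)) {
    idx <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "log2 undefined for gene '%s', sample '%s' (value + pseudocount <= 0)",
      rownames(matrix$values)[idx[1L]], colnames(matrix$values)[idx[2L]]))
  }
  out <- log2(x)
  expression_matrix(out, scale = "log2", tissue = matrix$tissue)
}
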