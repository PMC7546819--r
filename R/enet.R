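#' Fit the elastic-net age regression
#'
#' Minimizes the unscaled penalized residual sum of squares
#' \deqn{\sum_i (Age_i - \omega_0 - \sum_j x_{ij}\omega_j)^2 +
#'       \lambda\big(\alpha\sum_j|\omega_j| +
#'       \tfrac{1-\alpha}{2}\sum_j\omega_j^2\big),}
#' with an unpenalized intercept, by cyclic coordinate descent. Note the
#' residual term carries no `1/(2M)` factor, so `lambda` here is on the
#' same scale as the grid \eqn{2^{-10} \ldots 2^{10}}; `alpha = 1` is the
#' lasso, `alpha = 0` ridge regression.
#'
#' `standardize = TRUE` rescales features internally for numerical
#' conditioning only: the per-coordinate penalty weights are rescaled in
#' step, so the optimized objective — and hence the returned raw-scale
#' coefficients — is identical to the unstandardized fit up to solver
#' tolerance.
#'
#' @param x numeric matrix, samples in rows, features (log2 expression) in
#'   columns; column names are gene identifiers.
#' @param ages numeric response vector aligned with the rows of `x`.
#' @param alpha lasso/ridge mixing parameter in `[0, 1]`.
#' @param lambda penalty strength, > 0 (use a tiny value for a near-OLS fit).
#' @param tissue optional per-feature tissue-of-origin tags (recycled if
#'   length 1); used by paired-tissue models.
#' @param standardize internally rescale features (see above).
#' @param tol relative objective-change convergence tolerance.
#' @param maxit maximum coordinate-descent sweeps; non-convergence warns.
#' @return An `AgeModel`: list with `intercept`, `coefficients` (data frame
#'   `gene_id`, `tissue`, `weight`, raw log2-expression scale), `alpha`,
#'   `lambda`, `n_features_requested`, and solver diagnostics.
#' @export
fit_elastic_net <- function(x, ages, alpha, lambda, tissue = NULL,
                            standardize = TRUE, tol = 1e-7, maxit = 1e5) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix (samples x features)")
  if (nrow(x) != length(ages)) stop("rows of 'x' must align with 'ages'")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(ages)) stop("NA values are not supported")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single number in [0, 1]")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("'lambda' must be a single number > 0")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("feature", seq_len(ncol(x)))
  if (is.null(tissue)) tissue <- NA_character_
  tissue <- rep_len(as.character(tissue), ncol(x))

  p <- ncol(x)
  xm <- colMeans(x)
  ym <- mean(ages)
  xc <- sweep(x, 2L, xm, "-")
  yc <- ages - ym

  scale_j <- rep(1, p)
  if (standardize) {
    s <- sqrt(colMeans(xc^2))
    scale_j[s > 0] <- s[s > 0]
    xc <- sweep(xc, 2L, scale_j, "/")
  }
  # penalty on the RAW-scale coefficient w_j = theta_j / scale_j
  l1 <- rep(lambda * alpha, p) / scale_j
  q <- rep(lambda * (1 - alpha), p) / scale_j^2

  fit <- enet_cd(xc, yc, l1, q, tol, as.integer(maxit), numeric(p))
  if (!fit$converged) {
    warning("coordinate descent did not converge in ", maxit, " sweeps")
  }
  w <- as.numeric(fit$coefficients) / scale_j
  intercept <- ym - sum(xm * w)

  structure(
    list(intercept = intercept,
         coefficients = data.frame(gene_id = colnames(x), tissue = tissue,
                                   weight = w, stringsAsFactors = FALSE),
         alpha = alpha, lambda = lambda,
         n_features_requested = p,
         converged = fit$converged, iterations = fit$iterations),
    class = "AgeModel")
}

#' @export
print.AgeModel <- function(x, ...) {
  nz <- sum(x$coefficients$weight != 0)
  cat(sprintf(
    "AgeModel: intercept %.4g years, %d features (%d non-zero), alpha = %s, lambda = %s\n",
    x$intercept, nrow(x$coefficients), nz,
    format(x$alpha), format(x$lambda)))
  invisible(x)
}

# Value of the penalized objective for a coefficient vector; used by
# optimality checks.
enet_objective <- function(x, ages, intercept, weights, alpha, lambda) {
  resid <- ages - intercept - as.vector(x %*% weights)
  sum(resid^2) + lambda * (alpha * sum(abs(weights)) +
                           (1 - alpha) / 2 * sum(weights^2))
}

#' Predict age from an expression profile
#'
#' Evaluates `Age = w0 + sum_j y_j w_j` for one or more samples. Every gene
#' carried by the model must be present in the input; missing genes are an
#' error (listing them), never silently treated as zero. The one exception
#' is `all_zero = TRUE`, a diagnostic mode that evaluates the equation on an
#' all-zero expression vector and so returns the intercept.
#'
#' @param model an `AgeModel` (fitted or read with [read_age_model()]).
#' @param expression named numeric vector (one sample), a genes-by-samples
#'   numeric matrix with gene rownames, or a log2-scale
#'   [expression_matrix()]. Ignored when `all_zero = TRUE`.
#' @param all_zero evaluate at zero expression for every model gene.
#' @return Named numeric vector of predicted ages (years), one per sample.
#' @export
predict_age <- function(model, expression = NULL, all_zero = FALSE) {
  stopifnot(inherits(model, "AgeModel"))
  if (all_zero) return(c(zero_profile = model$intercept))
  if (is.null(expression)) stop("'expression' is required unless all_zero = TRUE")
  if (inherits(expression, "ExpressionMatrix")) {
    if (expression$scale != "log2") stop("expression must be on the log2 scale")
    expression <- expression$values
  }
  if (is.numeric(expression) && is.null(dim(expression))) {
    expression <- matrix(expression, ncol = 1L,
                         dimnames = list(names(expression), "sample1"))
  }
  genes <- model$coefficients$gene_id
  missing_genes <- setdiff(genes, rownames(expression))
  if (length(missing_genes)) {
    stop("expression is missing ", length(missing_genes), " model gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  preds <- model$intercept +
    as.vector(crossprod(expression[genes, , drop = FALSE],
                        model$coefficients$weight))
  names(preds) <- colnames(expression)
  preds
}

#' Root-mean-square error
#'
#' `sqrt(mean((truth - predicted)^2))`; zero exactly when the two vectors
#' coincide.
#'
#' @param truth,predicted numeric vectors of equal length >= 1.
#' @return RMSE in the units of the inputs (years for ages).
#' @export
rmse <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("length mismatch: ", length(truth), " vs ", length(predicted))
  }
  if (length(truth) < 1L) stop("need at least one pair")
  sqrt(mean((truth - predicted)^2))
}

#' Pearson correlation between true and predicted age
#'
#' Delegates to [pearson_correlation()] (degenerate inputs yield `NA`).
#'
#' @param truth,predicted numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]` or `NA` if either vector is constant.
#' @export
pcc <- function(truth, predicted) pearson_correlation(truth, predicted)

#' Write an age model in the coefficient-table layout
#'
#' First data row `Intercept<TAB><value>`, then one row per gene
#' (`gene_id`, coefficient, tissue) ordered by decreasing `|coefficient|`,
#' 7 significant digits. With `drop_zero = TRUE` (default) zero
#' coefficients are omitted. A sidecar `<path>.meta` key=value file records
#' alpha, lambda and the requested feature count.
#'
#' @param model an `AgeModel`.
#' @param path output TSV.
#' @param drop_zero omit zero-weight genes.
#' @param metadata also write the sidecar file.
#' @export
write_age_model <- function(model, path, drop_zero = TRUE, metadata = TRUE) {
  stopifnot(inherits(model, "AgeModel"))
  co <- model$coefficients
  if (drop_zero) co <- co[co$weight != 0, , drop = FALSE]
  co <- co[order(-abs(co$weight), co$gene_id, method = "radix"), , drop = FALSE]
  lines <- c("Gene_symbol\tCoefficient\tTissue",
             paste0("Intercept\t", formatC(model$intercept, digits = 7, format = "g")),
             paste(co$gene_id,
                   formatC(co$weight, digits = 7, format = "g"),
                   ifelse(is.na(co$tissue), "", co$tissue),
                   sep = "\t"))
  writeLines(lines, path, useBytes = FALSE)
  if (metadata) {
    writeLines(c(paste0("alpha=", format(model$alpha)),
                 paste0("lambda=", format(model$lambda)),
                 paste0("n_features_requested=", model$n_features_requested)),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read an age model from the coefficient-table layout
#'
#' Accepts the layout written by [write_age_model()]: an optional header, an
#' `Intercept` row, then gene rows with coefficient and optional tissue tag.
#' Unicode minus signs are tolerated. If a `<path>.meta` sidecar exists its
#' alpha/lambda are attached.
#'
#' @param path model TSV.
#' @return An `AgeModel`.
#' @export
read_age_model <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("−", "-", lines)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(parts[[1L]][1L]))
  if (first %in% c("gene_symbol", "gene symbol", "gene_id")) parts <- parts[-1L]
  term <- vapply(parts, function(p) trimws(p[1L]), character(1))
  coef <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2L]), numeric(1)))
  tiss <- vapply(parts, function(p) if (length(p) >= 3L) trimws(p[3L]) else "", character(1))
  if (anyNA(coef)) {
    stop("non-numeric coefficient for: ", paste(term[is.na(coef)], collapse = ", "))
  }
  is_int <- tolower(term) == "intercept"
  if (sum(is_int) != 1L) stop("model file must contain exactly one Intercept row")
  genes <- term[!is_int]
  if (anyDuplicated(genes)) {
    stop("duplicate gene rows: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  tiss <- tiss[!is_int]
  tiss[!nzchar(tiss)] <- NA_character_
  meta <- paste0(path, ".meta")
  alpha <- lambda <- NA_real_
  if (file.exists(meta)) {
    kv <- read_keyvalue(meta)
    alpha <- suppressWarnings(as.numeric(kv[["alpha"]]))
    lambda <- suppressWarnings(as.numeric(kv[["lambda"]]))
  }
  structure(
    list(intercept = coef[is_int],
         coefficients = data.frame(gene_id = genes, tissue = tiss,
                                   weight = coef[!is_int],
                                   stringsAsFactors = FALSE),
         alpha = alpha, lambda = lambda,
         n_features_requested = length(genes),
         converged = NA, iterations = NA_integer_),
    class = "AgeModel")
}

# Parse a flat key=value text file into a named list of strings.
read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}
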