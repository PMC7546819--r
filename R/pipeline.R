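#' Fit and select a single-tissue age model
#'
#' The full single-tissue pipeline: subset to the tissue, quantile-normalize
#' across its samples (the default; normalization precedes any CV split),
#' log2-transform, then grid-search (N, alpha, lambda) by repeated 10-fold
#' cross-validation with fold-internal gene reranking, and refit the winning
#' model on all samples.
#'
#' @param matrix raw-scale [expression_matrix()] (any mix of tissues).
#' @param table matching [sample_table()].
#' @param tissue tissue to model.
#' @param grid a [param_grid()]; defaults to the full reference lattice.
#' @param k,repeats,base_seed cross-validation protocol (see [cv_evaluate()]).
#' @param normalize quantile-normalize the tissue matrix first (default TRUE).
#' @param pseudocount offset for [log2_transform()].
#' @param refine_alpha see [grid_search()].
#' @return A `CVResult` whose `final_model` carries the tissue tag.
#' @export
fit_single_tissue <- function(matrix, table, tissue, grid = param_grid(),
                              k = 10, repeats = 100, base_seed = 1,
                              normalize = TRUE, pseudocount = 1,
                              refine_alpha = FALSE) {
  sub <- subset_by_tissue(matrix, table, tissue)
  m <- sub$matrix
  if (normalize) m <- quantile_normalize(m)
  m <- log2_transform(m, pseudocount = pseudocount)
  x <- t(m$values)
  res <- grid_search(x, sub$table$age, grid, k = k, repeats = repeats,
                     base_seed = base_seed, refine_alpha = refine_alpha)
  res$final_model$coefficients$tissue <- tissue
  res$tissue <- tissue
  res
}

#' Fit and select a two-tissue age model
#'
#' Builds the shared-donor candidate matrix for the pair (each tissue
#' normalized and log2-transformed on its own samples), then grid-searches
#' per-tissue feature budgets and penalty parameters by repeated k-fold
#' cross-validation over donors, with fold-internal per-tissue reranking on
#' the shared donors.
#'
#' @param matrix raw-scale [expression_matrix()] covering both tissues (or a
#'   list of two single-tissue matrices).
#' @param table matching [sample_table()].
#' @param tissue_a,tissue_b the pair to combine.
#' @param budgets list of per-tissue budget pairs, each a length-2 integer
#'   vector ordered (tissue_a, tissue_b); default the reference
#'   600 + \{50, 100, 200, 400\} configuration.
#' @param alpha,lambda penalty grids.
#' @param min_overlap refuse pairs sharing fewer donors than this
#'   (default 70).
#' @param k,repeats,base_seed cross-validation protocol.
#' @param normalize,pseudocount preprocessing switches.
#' @return A `CVResult`; the final model's coefficients are tissue-tagged.
#' @export
fit_tissue_pair <- function(matrix, table, tissue_a, tissue_b,
                            budgets = list(c(600L, 50L), c(600L, 100L),
                                           c(600L, 200L), c(600L, 400L)),
                            alpha = seq(0, 1, by = 0.01),
                            lambda = 2^seq(-10, 10),
                            min_overlap = 70, k = 10, repeats = 100,
                            base_seed = 1, normalize = TRUE, pseudocount = 1) {
  prep <- function(tissue) {
    sub <- if (is.list(matrix) && !inherits(matrix, "ExpressionMatrix")) {
      pick <- which(vapply(matrix, function(m) identical(m$tissue, tissue), logical(1)))
      if (!length(pick)) stop("no matrix provided for tissue '", tissue, "'")
      subset_by_tissue(matrix[[pick[1L]]], table, tissue)
    } else {
      subset_by_tissue(matrix, table, tissue)
    }
    m <- sub$matrix
    if (normalize) m <- quantile_normalize(m)
    list(matrix = log2_transform(m, pseudocount = pseudocount), table = sub$table)
  }
  a <- prep(tissue_a)
  b <- prep(tissue_b)
  n_shared <- length(donor_overlap(a$table, b$table))
  if (n_shared < min_overlap) {
    stop("only ", n_shared, " donors shared between '", tissue_a, "' and '",
         tissue_b, "' (minimum ", min_overlap,
         "); lower 'min_overlap' to proceed anyway")
  }
  cand <- paired_candidate_matrix(a$matrix, a$table, b$matrix, b$table)
  # budgets are given in (tissue_a, tissue_b) order; the engine consumes
  # them in factor-level (alphabetical) order
  reorder <- match(cand$tissues, c(tissue_a, tissue_b))
  budgets <- lapply(budgets, function(bd) {
    if (length(bd) != 2L) stop("each budget must be a length-2 vector")
    as.integer(bd)[reorder]
  })
  grid <- param_grid(n_top = budgets, alpha = alpha, lambda = lambda)
  res <- grid_search(cand$x, cand$ages, grid, k = k, repeats = repeats,
                     base_seed = base_seed, groups = cand$groups)
  # untag coefficient gene ids, keep the tissue column informative
  co <- res$final_model$coefficients
  parts <- strsplit(co$gene_id, "|", fixed = TRUE)
  co$gene_id <- vapply(parts, `[`, character(1), 1L)
  co$tissue <- vapply(parts, `[`, character(1), 2L)
  res$final_model$coefficients <- co
  res$tissues <- c(tissue_a, tissue_b)
  res$n_shared_donors <- n_shared
  res
}

#' Export the gene list of a model for functional-annotation tools
#'
#' Writes the distinct gene symbols carried by a model (intercept excluded,
#' zero-weight genes dropped), one per line — the plain-list format
#' enrichment services such as DAVID accept.
#'
#' @param model an `AgeModel`.
#' @param path output file; when `NULL` the list is returned only.
#' @return Invisibly, the character vector of gene symbols.
#' @export
export_genelist <- function(model, path = NULL) {
  stopifnot(inherits(model, "AgeModel"))
  genes <- unique(model$coefficients$gene_id[model$coefficients$weight != 0])
  if (!length(genes)) warning("model has no non-zero coefficients; empty gene list")
  if (!is.null(path)) writeLines(genes, path)
  invisible(genes)
}
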