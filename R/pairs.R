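#' Donors shared between two tissues
#'
#' @param table_a,table_b single-tissue [sample_table()] views.
#' @return Sorted character vector of donor identifiers present in both.
#' @export
donor_overlap <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "SampleTable"), inherits(table_b, "SampleTable"))
  sort(intersect(unique(table_a$donor_id), unique(table_b$donor_id)))
}

#' Enumerate tissue pairs with sufficient donor overlap
#'
#' Considers every unordered pair of tissues in the table and keeps those
#' sharing at least `min_overlap` donors — the usual threshold below which a
#' paired model is not worth fitting is 70 donors.
#'
#' @param table a [sample_table()] covering two or more tissues (or a list
#'   of single-tissue tables).
#' @param min_overlap minimum shared-donor count (default 70).
#' @return Data frame (`tissue_a`, `tissue_b`, `overlap`) sorted by
#'   decreasing overlap, then lexicographically; zero rows when no pair
#'   qualifies.
#' @export
enumerate_pairs <- function(table, min_overlap = 70) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- sample_table(do.call(rbind, lapply(table, as.data.frame)))
  }
  stopifnot(inherits(table, "SampleTable"))
  tissues <- sort(unique(table$tissue))
  donors <- lapply(tissues, function(t) unique(table$donor_id[table$tissue == t]))
  names(donors) <- tissues
  out <- data.frame(tissue_a = character(), tissue_b = character(),
                    overlap = integer(), stringsAsFactors = FALSE)
  if (length(tissues) >= 2L) {
    combs <- utils::combn(tissues, 2L)
    ov <- apply(combs, 2L, function(pr) {
      length(intersect(donors[[pr[1L]]], donors[[pr[2L]]]))
    })
    out <- data.frame(tissue_a = combs[1L, ], tissue_b = combs[2L, ],
                      overlap = as.integer(ov), stringsAsFactors = FALSE)
    out <- out[out$overlap >= min_overlap, , drop = FALSE]
    out <- out[order(-out$overlap, out$tissue_a, out$tissue_b,
                     method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Assemble the full candidate feature matrix for a tissue pair: one row per
# shared donor (sorted donor_ids), all genes of both tissues as tagged
# columns ("gene|tissue"). This is the input the CV engine reranks
# fold-internally; budgets are applied per tissue group.
paired_candidate_matrix <- function(mat_a, table_a, mat_b, table_b) {
  stopifnot(inherits(mat_a, "ExpressionMatrix"), inherits(mat_b, "ExpressionMatrix"))
  if (mat_a$scale != "log2" || mat_b$scale != "log2") {
    stop("both matrices must be normalized and log2-scaled")
  }
  tis_a <- unique(table_a$tissue)
  tis_b <- unique(table_b$tissue)
  if (length(tis_a) != 1L || length(tis_b) != 1L) {
    stop("each table must be a single-tissue view")
  }
  if (identical(tis_a, tis_b)) stop("the two tissues must differ")
  donors <- donor_overlap(table_a, table_b)
  if (!length(donors)) {
    stop("empty cohort: no donors shared between '", tis_a, "' and '", tis_b, "'")
  }
  row_a <- table_a[match(donors, table_a$donor_id), , drop = FALSE]
  row_b <- table_b[match(donors, table_b$donor_id), , drop = FALSE]
  keep <- row_a$sample_id %in% colnames(mat_a$values) &
    row_b$sample_id %in% colnames(mat_b$values)
  if (!all(keep)) {
    message(sum(!keep), " shared donor(s) missing expression in one tissue were dropped")
    donors <- donors[keep]
    row_a <- row_a[keep, , drop = FALSE]
    row_b <- row_b[keep, , drop = FALSE]
  }
  if (!length(donors)) stop("empty cohort: no shared donors with expression in both tissues")
  xa <- t(mat_a$values[, row_a$sample_id, drop = FALSE])
  xb <- t(mat_b$values[, row_b$sample_id, drop = FALSE])
  colnames(xa) <- paste(rownames(mat_a$values), tis_a, sep = "|")
  colnames(xb) <- paste(rownames(mat_b$values), tis_b, sep = "|")
  x <- cbind(xa, xb)
  rownames(x) <- donors
  groups <- factor(rep(c(tis_a, tis_b), c(ncol(xa), ncol(xb))),
                   levels = sort(c(tis_a, tis_b)))
  # budgets in grid cells follow factor level order; report the mapping
  list(x = x, ages = row_a$age, donor_ids = donors, groups = groups,
       tissues = levels(groups))
}

#' Build a two-tissue dataset over shared donors
#'
#' Restricts both tissues to their shared donors, ranks genes within each
#' tissue on those donors (fold-free; inside cross-validation the engine
#' reranks fold-internally instead), and concatenates the top `n_a` features
#' of tissue A with the top `n_b` of tissue B. Features are tagged
#' `gene|tissue`, so a gene measured in both tissues contributes two
#' distinct features. With `rank_on = "full"` the ranking uses each
#' tissue's full cohort instead of the shared donors only.
#'
#' @param mat_a,mat_b normalized, log2-scale [expression_matrix()] objects.
#' @param table_a,table_b the matching single-tissue [sample_table()] views.
#' @param n_a,n_b per-tissue feature budgets (both >= 0, not both 0).
#' @param rank_on `"shared"` (default) or `"full"` cohort ranking.
#' @return A `PairedDataset`: list with `x` (donors x features), `ages`,
#'   `donor_ids`, `features` (data frame `gene_id`, `tissue`), `budgets`.
#' @export
build_paired_dataset <- function(mat_a, table_a, mat_b, table_b, n_a, n_b,
                                 rank_on = c("shared", "full")) {
  rank_on <- match.arg(rank_on)
  if (n_a < 0 || n_b < 0 || n_a + n_b == 0) {
    stop("per-tissue budgets must be non-negative and not both zero")
  }
  cand <- paired_candidate_matrix(mat_a, table_a, mat_b, table_b)
  pick <- function(mat, tab, n_top, tissue) {
    if (n_top == 0L) return(character())
    if (rank_on == "shared") {
      cols <- tab$sample_id[match(cand$donor_ids, tab$donor_id)]
      sub <- expression_matrix(mat$values[, cols, drop = FALSE],
                               scale = "log2", tissue = tissue)
      rk <- rank_genes(sub, cand$ages)
    } else {
      ord_tab <- tab[tab$sample_id %in% colnames(mat$values), , drop = FALSE]
      sub <- expression_matrix(mat$values[, ord_tab$sample_id, drop = FALSE],
                               scale = "log2", tissue = tissue)
      rk <- rank_genes(sub, ord_tab$age)
    }
    if (n_top > nrow(rk)) {
      warning("tissue '", tissue, "': requested ", n_top, " genes but only ",
              nrow(rk), " are rankable")
      n_top <- nrow(rk)
    }
    rk$gene_id[seq_len(n_top)]
  }
  tis_a <- unique(table_a$tissue)
  tis_b <- unique(table_b$tissue)
  genes_a <- pick(mat_a, table_a, as.integer(n_a), tis_a)
  genes_b <- pick(mat_b, table_b, as.integer(n_b), tis_b)
  tags <- c(paste(genes_a, tis_a, sep = "|"), paste(genes_b, tis_b, sep = "|"))
  x <- cand$x[, tags, drop = FALSE]
  structure(
    list(x = x, ages = cand$ages, donor_ids = cand$donor_ids,
         features = data.frame(gene_id = c(genes_a, genes_b),
                               tissue = rep(c(tis_a, tis_b),
                                            c(length(genes_a), length(genes_b))),
                               stringsAsFactors = FALSE),
         budgets = c(a = as.integer(n_a), b = as.integer(n_b)),
         tissues = c(tis_a, tis_b)),
    class = "PairedDataset")
}

#' @export
print.PairedDataset <- function(x, ...) {
  cat(sprintf("PairedDataset: %d donors, %d features (%s: %d, %s: %d)\n",
              length(x$donor_ids), ncol(x$x),
              x$tissues[1L], sum(x$features$tissue == x$tissues[1L]),
              x$tissues[2L], sum(x$features$tissue == x$tissues[2L])))
  invisible(x)
}
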