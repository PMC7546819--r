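#' Sample attribute table
#'
#' A `SampleTable` is a validated data frame with one row per sample and
#' columns `sample_id`, `donor_id`, `tissue`, `age` (years, > 0) and `sex`
#' (`"male"`, `"female"` or `"unknown"`). It links expression matrices across
#' tissues through the donor identifier; within a tissue each donor
#' contributes at most one sample.
#'
#' @param df data frame with at least `sample_id`, `donor_id`, `tissue`,
#'   `age`; `sex` is optional and unrecognized tokens map to `"unknown"`.
#' @return A data frame of class `SampleTable`.
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "donor_id", "tissue", "age")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("sample table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    donor_id = as.character(df$donor_id),
    tissue = trimws(as.character(df$tissue)),
    age = suppressWarnings(as.numeric(df$age)),
    sex = if ("sex" %in% names(df)) tolower(as.character(df$sex)) else "unknown",
    stringsAsFactors = FALSE
  )
  out$sex[!out$sex %in% c("male", "female")] <- "unknown"
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  if (anyNA(out$age) || any(!is.finite(out$age)) || any(out$age <= 0)) {
    bad <- out$sample_id[is.na(out$age) | !is.finite(out$age) | out$age <= 0]
    stop("age must be a finite number > 0; offending samples: ",
         paste(bad, collapse = ", "))
  }
  key <- paste(out$donor_id, out$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    stop("each (donor_id, tissue) pair may appear at most once; duplicated: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(out) <- c("SampleTable", "data.frame")
  out
}

#' Read a sample attribute table from TSV
#'
#' @param path tab-separated file with a header containing at least
#'   `sample_id`, `donor_id`, `tissue`, `age`; `sex` optional.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_table(df)
}

#' Write a sample attribute table to TSV
#'
#' @param table a [sample_table()].
#' @param path output file.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "SampleTable"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict an expression matrix and sample table to one tissue
#'
#' Keeps the samples of `tissue` that are present in both the matrix and the
#' table, in table order, so ages align positionally with matrix columns.
#' Samples listed in the table but absent from the matrix are dropped with a
#' message.
#'
#' @param matrix an [expression_matrix()].
#' @param table a [sample_table()].
#' @param tissue tissue label, matched case-sensitively after trimming.
#' @return A list with elements `matrix` (columns restricted and reordered)
#'   and `table` (rows restricted, aligned with the matrix columns).
#' @export
subset_by_tissue <- function(matrix, table, tissue) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(table, "SampleTable"))
  tissue <- trimws(tissue)
  tab <- table[table$tissue == tissue, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("empty cohort: no samples for tissue '", tissue, "' in the sample table")
  }
  keep <- tab$sample_id %in% colnames(matrix$values)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) of tissue '", tissue,
            "' absent from the expression matrix were dropped: ",
            paste(tab$sample_id[!keep], collapse = ", "))
  }
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("empty cohort: no '", tissue,
         "' samples shared between matrix and sample table")
  }
  values <- matrix$values[, tab$sample_id, drop = FALSE]
  out_mat <- expression_matrix(values, scale = matrix$scale, tissue = tissue)
  class(tab) <- c("SampleTable", "data.frame")
  rownames(tab) <- NULL
  list(matrix = out_mat, table = tab)
}

#' Per-tissue cohort summary
#'
#' Reproduces the usual cohort-description table from per-sample records:
#' sample count, minimum / maximum / median / mean age, male and female
#' counts, and the male:female ratio (rounded to 3 decimals; `NA` when there
#' are no female samples).
#'
#' @param table a [sample_table()].
#' @return A data frame with one row per tissue, columns `Tissue`, `Number`,
#'   `Minimum`, `Maximum`, `Median`, `Mean`, `NumMen`, `NumWomen`,
#'   `Proportion`.
#' @export
summarize_cohort <- function(table) {
  stopifnot(inherits(table, "SampleTable"))
  if (nrow(table) == 0L) stop("empty sample table")
  tissues <- sort(unique(table$tissue))
  rows <- lapply(tissues, function(t) {
    sub <- table[table$tissue == t, , drop = FALSE]
    n_m <- sum(sub$sex == "male")
    n_f <- sum(sub$sex == "female")
    data.frame(
      Tissue = t,
      Number = nrow(sub),
      Minimum = min(sub$age),
      Maximum = max(sub$age),
      Median = stats::median(sub$age),
      Mean = mean(sub$age),
      NumMen = n_m,
      NumWomen = n_f,
      Proportion = if (n_f == 0L) NA_real_ else round(n_m / n_f, 3L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
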