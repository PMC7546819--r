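#' Expression matrix container
#'
#' An `ExpressionMatrix` is a genes-by-samples numeric matrix together with a
#' scale flag (`"raw"` for non-negative expression-level values such as RPKM,
#' `"log2"` after [log2_transform()]) and an optional tissue label for
#' single-tissue matrices. Gene and sample identifiers live in the dimnames
#' and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Rownames
#'   are gene identifiers, colnames are sample identifiers.
#' @param scale `"raw"` or `"log2"`. Raw matrices must be non-negative.
#' @param tissue optional single tissue label.
#' @return An object of class `ExpressionMatrix`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:2))))
#' dim(m$values)
#' @export
expression_matrix <- function(values, scale = c("raw", "log2"), tissue = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("'values' must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values)) stop("expression values contain NA/NaN; missing values are not supported")
  if (scale == "raw" && any(values < 0)) {
    stop("raw-scale expression values must be non-negative")
  }
  structure(
    list(values = values, scale = scale,
         tissue = if (is.null(tissue)) NA_character_ else as.character(tissue)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.na(x$tissue)) "" else paste0(", tissue = ", x$tissue)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from GCT 1.2 or plain TSV
#'
#' GCT 1.2 files start with a `#1.2` version line and a
#' `<ngenes><TAB><nsamples>` dimensions line, followed by a table with
#' `Name` and `Description` columns before the samples; the `Description`
#' column is discarded. Plain TSV has gene identifiers in the first column
#' and sample identifiers in the header row.
#'
#' @param path file to read.
#' @param format `"gct"` or `"tsv"`; by default guessed from the file
#'   extension (`.gct` means GCT, everything else TSV).
#' @param tissue optional tissue label attached to the result.
#' @return An [expression_matrix()] with `scale = "raw"`.
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv"), tissue = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[1L]) != "#1.2") {
      stop("malformed GCT header: expected version line '#1.2', got '",
           if (length(header)) header[1L] else "", "'")
    }
    dims <- strsplit(trimws(header[2L]), "\t", fixed = TRUE)[[1L]]
    dims <- suppressWarnings(as.integer(dims))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT dimensions line: '", header[2L], "'")
    }
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L || tolower(names(tab)[1L]) != "name") {
      stop("malformed GCT table header: expected columns Name, Description, <samples>")
    }
    values <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(values) <- as.character(tab[[1L]])
    if (nrow(values) != dims[1L] || ncol(values) != dims[2L]) {
      stop(sprintf(
        "GCT dimension mismatch: dims line says %d x %d but table is %d x %d",
        dims[1L], dims[2L], nrow(values), ncol(values)))
    }
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed TSV: need a gene column plus >= 1 sample column")
    values <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(values) <- as.character(tab[[1L]])
  }
  storage.mode(values) <- "double"
  expression_matrix(values, scale = "raw", tissue = tissue)
}

#' Write an expression matrix to GCT 1.2 or plain TSV
#'
#' Values are written with full precision (up to 15 significant digits) so a
#' TSV round trip reproduces them bit-exactly for values representable at
#' that precision.
#'
#' @param x an [expression_matrix()].
#' @param path output file.
#' @param format `"gct"` or `"tsv"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  body <- apply(x$values, 2L, fmt)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x$values))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(x$values), ncol(x$values), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(x$values)), collapse = "\t"), con)
    writeLines(paste(gene_ids(x), "na",
                     apply(body, 1L, paste, collapse = "\t"), sep = "\t"), con)
  } else {
    writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
    writeLines(paste(gene_ids(x), apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}
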