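#' Expression matrices, clinical tables, and normalization
#'
#' The analysis consumes a genes-by-samples matrix either of raw positive
#' probe intensities or of log2 median-centered ratios (per-sample
#' `log2(intensity / sample median)`). The polarization likelihood is scored
#' on per-gene cohort z-scores of the log ratios.
#'
#' @name expression-io
NULL

#' Construct an expression matrix object
#'
#' @param values numeric matrix, genes in rows, samples in columns
#' @param genes gene symbols (canonicalized); defaults to rownames
#' @param samples sample ids; defaults to colnames
#' @param scale `"raw"` (strictly positive intensities) or
#'   `"log2_median_ratio"`
#' @return an `expression_matrix` (a numeric matrix with dimnames and a
#'   `scale` attribute)
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values),
                              scale = c("raw", "log2_median_ratio")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (anyNA(values)) stop("missing values are not permitted", call. = FALSE)
  genes <- canonical_symbol(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (scale == "raw" && any(values <= 0)) {
    stop("raw intensities must be strictly positive", call. = FALSE)
  }
  dimnames(values) <- list(genes, samples)
  structure(values, scale = scale, class = c("expression_matrix", "matrix",
                                             "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x), " genes x ", ncol(x), " samples (",
      attr(x, "scale"), ")\n", sep = "")
  invisible(x)
}

expr_scale <- function(m) attr(m, "scale")

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene symbols
#' (or the transpose, with `layout = "samples_by_genes"`). Delimiter is
#' inferred from the file extension (`.csv` comma, otherwise tab).
#'
#' @param path file path
#' @param layout `"genes_by_samples"` (default) or `"samples_by_genes"`
#' @param scale value scale flag stored on the result
#' @return an [expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   layout = c("genes_by_samples",
                                              "samples_by_genes"),
                                   scale = c("raw", "log2_median_ratio")) {
  layout <- match.arg(layout)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, TRUE))
  if (length(bad)) {
    stop("non-numeric values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (layout == "samples_by_genes") m <- t(m)
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' @param m an [expression_matrix()]
#' @param path output path (`.csv` comma, otherwise tab)
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m),
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Required columns: `sample`, `pathology` (one of `ER+/PR+`, `HER2+`, `TN`,
#' `normal`, `unknown`), `os_months` (>= 0), `os_event` (0/1). Optional:
#' `group`.
#'
#' @param path delimited file path
#' @return data.frame, one row per sample
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample", "pathology", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in clinical table",
                                     call. = FALSE)
  ok_path <- c("ER+/PR+", "HER2+", "TN", "normal", "unknown")
  bad <- setdiff(unique(df$pathology), ok_path)
  if (length(bad)) {
    stop("unknown pathology label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$os_months < 0)) stop("negative survival time", call. = FALSE)
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1", call. = FALSE)
  df
}

#' Write a clinical table
#' @param clinical data.frame as returned by [read_clinical_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_clinical_table <- function(clinical, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(clinical, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log2 median-center raw intensities per sample
#'
#' Each column is divided by its median and log2-transformed, so a value
#' below zero means the gene is expressed below the sample median. The
#' output column medians are exactly zero, and the transform is invariant
#' to any positive rescaling of a column.
#'
#' @param m a raw-scale [expression_matrix()]
#' @return an [expression_matrix()] on the `log2_median_ratio` scale
#' @export
log2_median_center <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (expr_scale(m) != "raw") {
    stop("log2_median_center expects raw intensities", call. = FALSE)
  }
  med <- apply(unclass(m), 2L, stats::median)
  out <- log2(sweep(unclass(m), 2L, med, `/`))
  expression_matrix(out, scale = "log2_median_ratio")
}

#' Cohort z-scores of log2 median-centered expression
#'
#' Standardizes each gene across *all* samples passed in (tumor and normal
#' together): `z = (x - mean) / sd` with the sample standard deviation
#' (`n - 1` denominator by default). Zero-variance genes map to all-zero
#' rows with a warning. The z matrix is the data vector scored by the
#' polarization likelihood.
#'
#' @param m an [expression_matrix()] on the `log2_median_ratio` scale
#' @param denominator `"n-1"` (sample sd, default) or `"n"`
#' @return a `zscore_matrix`: numeric genes-by-samples matrix with
#'   attributes `center` and `scale` holding the per-gene mean and sd used
#' @export
zscore <- function(m, denominator = c("n-1", "n")) {
  stopifnot(inherits(m, "expression_matrix"))
  denominator <- match.arg(denominator)
  if (expr_scale(m) != "log2_median_ratio") {
    stop("zscore expects log2 median-centered ratios", call. = FALSE)
  }
  n <- ncol(m)
  if (n < 2L) stop("z-scoring needs >= 2 samples", call. = FALSE)
  x <- unclass(m)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (if (denominator == "n-1") n - 1L else n))
  degen <- sdv == 0
  if (any(degen)) {
    warning(sum(degen), " zero-variance gene(s) mapped to z = 0: ",
            paste(utils::head(rownames(x)[degen], 5L), collapse = ", "),
            call. = FALSE)
    sdv[degen] <- 1
  }
  z <- (x - mu) / sdv
  z[degen, ] <- 0
  structure(z, center = mu, scale = sdv,
            class = c("zscore_matrix", "matrix", "array"))
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("zscore_matrix: ", nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}
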