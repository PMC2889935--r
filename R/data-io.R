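#' Read a wide expression table
#'
#' Reads a delimited text file (CSV or TSV, chosen from the file extension or
#' the `sep` argument) with one header row and one id column into an
#' [expression_matrix]. The caller must state the orientation; it is never
#' guessed, because a silently transposed table is a classic data bug.
#'
#' @param path file path to a CSV/TSV table.
#' @param orientation `"samples_rows"` (rows are samples, columns genes) or
#'   `"genes_rows"` (the transpose).
#' @param scale scale tag to declare for the data; see [expression_matrix].
#' @param na_policy `"error"` (default): any missing cell is an error naming
#'   the sample and gene; `"drop_sample"`: samples with any missing value are
#'   removed (complete-case, since covariance estimation needs complete
#'   per-sample vectors).
#' @param sep field separator; default inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @return An [expression_matrix].
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_rows", "genes_rows"),
                                  scale = c("log_expression", "ct",
                                            "linear_expression"),
                                  na_policy = c("error", "drop_sample"),
                                  sep = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  na_policy <- match.arg(na_policy)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c())
  if (ncol(raw) < 2L) stop("table must have an id column and at least one data column")
  row_ids <- as.character(raw[[1L]])
  col_ids <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  is_na_token <- cells %in% c("NA", "NaN", "", "na")
  bad <- which(is.na(num) & !is_na_token, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "genes_rows") num <- t(num)
  # rows are now samples, columns genes
  miss <- which(is.na(num), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    if (na_policy == "error") {
      stop(sprintf("missing value for sample '%s', gene '%s'",
                   rownames(num)[miss[1L, 1L]], colnames(num)[miss[1L, 2L]]))
    }
    keep <- stats::complete.cases(num)
    if (!any(keep)) stop("all samples dropped by missing-value policy")
    num <- num[keep, , drop = FALSE]
  }
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' Writes samples as rows at full double precision (17 significant digits),
#' so that a read/write round trip is lossless.
#'
#' @param x an [expression_matrix].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @export
write_expression_table <- function(x, path) {
  assert_expression_matrix(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample = x$sample_ids,
                    apply(x$values, 2L, function(col) {
                      formatC(col, digits = 17, format = "g")
                    }),
                    check.names = FALSE)
  colnames(out) <- c("sample", x$gene_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format technical-replicate table
#'
#' Expects columns `sample`, `gene`, `replicate`, `value` (extra columns are
#' ignored; order does not matter as long as the names are present).
#'
#' @param path CSV/TSV path.
#' @param sep separator, inferred from extension if `NULL`.
#' @return data.frame with columns sample, gene, replicate, value.
#' @export
read_replicate_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("replicate table needs columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Average technical replicates
#'
#' Collapses a long-format replicate table to one value per (sample, gene)
#' by the arithmetic mean, the standard pre-processing step before any
#' reference-gene analysis. Every (sample, gene) pair must be present.
#'
#' @param table data.frame with columns sample, gene, replicate, value, as
#'   returned by [read_replicate_table()].
#' @param scale scale tag for the resulting matrix (replicate averaging does
#'   not change the scale; `"ct"` by default since replicates are almost
#'   always averaged on the Ct scale).
#' @return An [expression_matrix] of replicate means.
#' @export
average_replicates <- function(table, scale = "ct") {
  need <- c("sample", "gene", "value")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("replicate table needs columns: sample, gene, replicate, value")
  }
  if (!is.numeric(table$value)) stop("replicate values must be numeric")
  samples <- unique(as.character(table$sample))
  genes <- unique(as.character(table$gene))
  means <- tapply(table$value,
                  list(factor(as.character(table$sample), levels = samples),
                       factor(as.character(table$gene), levels = genes)),
                  mean)
  miss <- which(is.na(means), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    pairs <- apply(miss, 1L, function(ij) {
      paste0("(", samples[ij[1L]], ", ", genes[ij[2L]], ")")
    })
    stop("missing (sample, gene) pairs: ", paste(pairs, collapse = ", "))
  }
  expression_matrix(means, scale = scale,
                    sample_ids = samples, gene_ids = genes)
}

#' Transform Ct values to relative expression
#'
#' Converts threshold-cycle numbers to linear-scale relative expression per
#' gene: `Q_ij = 2^(anchor_j - Ct_ij)`, where the anchor is that gene's
#' minimum Ct (default, the gNorm convention). Values then lie in (0, 1]
#' with 1 at the sample with the smallest Ct (presumably the largest copy
#' number). The anchor may be switched to the per-gene maximum
#' (`Q = 2^(max Ct - Ct)`, values >= 1 with 1 at the largest Ct); the two
#' differ only by a per-gene multiplicative constant, which cancels in
#' every variance computation downstream.
#'
#' @param x an [expression_matrix] with `scale = "ct"`.
#' @param anchor `"min"` (default) or `"max"` per-gene Ct anchor.
#' @return An [expression_matrix] with `scale = "linear_expression"`.
#' @export
ct_to_relative_expression <- function(x, anchor = c("min", "max")) {
  assert_expression_matrix(x)
  anchor <- match.arg(anchor)
  if (x$scale != "ct") {
    stop("ct_to_relative_expression requires scale = 'ct'; got '", x$scale, "'")
  }
  v <- x$values
  a <- apply(v, 2L, if (anchor == "min") min else max)
  q <- 2^sweep(-v, 2L, a, "+")    # 2^(anchorCt - Ct)
  expression_matrix(q, scale = "linear_expression",
                    sample_ids = x$sample_ids, gene_ids = x$gene_ids,
                    covariates = x$covariates)
}

#' Log-transform linear expression levels
#'
#' @param x an [expression_matrix] with `scale = "linear_expression"` and
#'   strictly positive values.
#' @param base `"e"` (natural log, default) or `"2"`.
#' @return An [expression_matrix] with `scale = "log_expression"`.
#' @export
log_transform <- function(x, base = c("e", "2")) {
  assert_expression_matrix(x)
  base <- match.arg(base)
  if (x$scale != "linear_expression") {
    stop("log_transform requires scale = 'linear_expression'; got '",
         x$scale, "'")
  }
  if (any(x$values <= 0)) {
    bad <- which(x$values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive value at sample '%s', gene '%s'",
                 x$sample_ids[bad[1L]], x$gene_ids[bad[2L]]))
  }
  lv <- if (base == "e") log(x$values) else log2(x$values)
  expression_matrix(lv, scale = "log_expression",
                    sample_ids = x$sample_ids, gene_ids = x$gene_ids,
                    covariates = x$covariates)
}
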