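#' Expression matrix container
#'
#' An `expression_matrix` holds an N samples x J genes matrix of qRT-PCR
#' measurements together with a scale tag that records what the numbers are:
#' raw threshold cycles (`"ct"`), linear-scale relative expression levels
#' (`"linear_expression"`), or log-transformed expression (`"log_expression"`).
#' The scale tag gates which transformations are legal: only linear
#' expression may be log-transformed, and only Ct matrices may be converted
#' to relative expression. Optional per-sample covariates (tissue type etc.)
#' travel with the matrix for use in the mean model of the covariance fit.
#'
#' @param values numeric N x J matrix; rows are samples, columns genes.
#' @param scale one of `"log_expression"`, `"ct"`, `"linear_expression"`.
#' @param sample_ids,gene_ids optional character vectors; default to the
#'   dimnames of `values` or generated labels.
#' @param covariates optional data.frame with N rows of per-sample factors.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale, sample_ids = NULL,
                              gene_ids = NULL, covariates = NULL) {
  scale <- match.arg(scale, c("log_expression", "ct", "linear_expression"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least 1 sample and 1 gene")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', gene '%s'",
                 sample_ids[bad[1L]], gene_ids[bad[2L]]))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values)) {
      stop("covariates must have one row per sample")
    }
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, scale = scale, sample_ids = sample_ids,
         gene_ids = gene_ids, covariates = covariates),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("genes:", paste(x$gene_ids, collapse = ", "), "\n")
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

n_samples <- function(x) nrow(x$values)
n_genes <- function(x) ncol(x$values)

assert_expression_matrix <- function(x) {
  if (!inherits(x, "expression_matrix")) {
    stop("expected an expression_matrix; got ", class(x)[1L])
  }
  invisible(x)
}
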