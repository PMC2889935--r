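#' Design specification for the mean model
#'
#' Builds the per-sample design matrix A for the linear mean model of the
#' multivariate fit. By default the mean model is intercept-only (one common
#' mean per gene); covariate columns (tissue type etc.) may be added through
#' a formula evaluated against the matrix's covariates.
#'
#' @param x an [expression_matrix].
#' @param formula mean-model formula, default `~ 1`; terms are looked up in
#'   `x$covariates`.
#' @return list with the N x p design matrix `A` (first column intercept)
#'   and its column labels, of class `design_spec`.
#' @export
design_spec <- function(x, formula = ~1) {
  assert_expression_matrix(x)
  env <- x$covariates
  if (is.null(env)) env <- data.frame(row.names = seq_len(n_samples(x)))
  A <- stats::model.matrix(formula, data = env)
  if (nrow(A) != n_samples(x)) {
    stop("design matrix rows do not match sample count (missing covariates?)")
  }
  if (colnames(A)[1L] != "(Intercept)") {
    stop("mean model must include an intercept")
  }
  if (qr(A)$rank < ncol(A)) stop("design matrix is rank deficient")
  structure(list(A = A, labels = colnames(A)), class = "design_spec")
}

#' Estimate the unstructured total covariance matrix
#'
#' Fits the J-variate normal model for the log-scale expression vectors: each
#' gene column is regressed on the shared design matrix A by ordinary least
#' squares, and the total covariance V of the genes is estimated from the
#' residual cross-products with the unbiased divisor N - p. Because the mean
#' model is identical across genes and V is left unstructured, this closed
#' form coincides with the mixed-model (REML) solution; no iteration is
#' needed. With an intercept-only design this is exactly the textbook sample
#' covariance matrix (divisor N - 1) and the per-gene means.
#'
#' No attempt is made to split V into a shared sample-effect component and
#' a gene-effect component: those parts are not separately identifiable
#' without structural constraints, and all downstream subset-variance
#' computations need only the total V.
#'
#' @param data an [expression_matrix] on the log-expression or Ct scale.
#' @param design optional [design_spec]; `NULL` means intercept-only.
#' @return object of class `covariance_estimate`: list with `V` (J x J),
#'   `beta` (p x J fixed-effect estimates; the gene means when
#'   intercept-only), `n_samples`, `df` (N - p), `gene_ids`.
#' @export
estimate_covariance <- function(data, design = NULL) {
  assert_expression_matrix(data)
  if (data$scale == "linear_expression") {
    stop("covariance must be estimated on the log or Ct scale; ",
         "apply log_transform() first")
  }
  if (is.null(design)) design <- design_spec(data)
  A <- design$A
  N <- n_samples(data)
  J <- n_genes(data)
  p <- ncol(A)
  if (N <= p) stop(sprintf("need more samples than mean parameters (N=%d, p=%d)", N, p))
  if (N <= (J + 3) / 2) {
    warning(sprintf(
      "N = %d does not exceed (J+3)/2 = %.1f; the unstructured covariance is weakly identified",
      N, (J + 3) / 2))
  }
  qrA <- qr(A)
  if (qrA$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrA, data$values)
  E <- qr.resid(qrA, data$values)
  V <- crossprod(E) / (N - p)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(data$gene_ids, data$gene_ids)
  structure(
    list(V = V, beta = beta, n_samples = N, df = N - p,
         gene_ids = data$gene_ids, design_labels = design$labels),
    class = "covariance_estimate"
  )
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("covariance_estimate: %d genes, N = %d, df = %d\n",
              length(x$gene_ids), x$n_samples, x$df))
  print(round(x$V, 4))
  invisible(x)
}

#' Write a covariance estimate to CSV / JSON
#'
#' @param x a `covariance_estimate`.
#' @param path output path; `.json` writes a JSON object (matrix, means,
#'   df), anything else a CSV of the V matrix with gene ids.
#' @export
write_covariance <- function(x, path) {
  if (!inherits(x, "covariance_estimate")) stop("not a covariance_estimate")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(gene_ids = x$gene_ids, V = x$V, beta = x$beta,
           n_samples = x$n_samples, df = x$df),
      path, digits = NA, matrix = "rowmajor"
    )
  } else {
    utils::write.csv(data.frame(gene = x$gene_ids, x$V, check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Residuals after fixed per-sample effects
#'
#' Removes the per-gene mean and a fixed (not random) per-sample effect by
#' the unweighted two-way additive fit: r_ji = y_ji - ghat_j - shat_i, with
#' ghat_j the gene column mean and shat_i the row mean of the gene-centered
#' values. Because the sample effect absorbs everything shared across genes
#' within a sample (loading, RNA amount, RT efficiency), these residuals
#' carry only the innate between-individual variation of each gene, which is
#' what correlations between candidate reference genes should be judged on.
#'
#' @param data an [expression_matrix] with at least two genes.
#' @return N x J residual matrix; every row and column mean is ~0.
#' @export
residuals_fixed_sample_effects <- function(data) {
  assert_expression_matrix(data)
  if (n_genes(data) < 2L) {
    stop("need at least 2 genes to separate the sample effect")
  }
  y <- data$values
  g <- colMeans(y)
  yc <- sweep(y, 2L, g)
  s <- rowMeans(yc)
  r <- yc - s
  dimnames(r) <- dimnames(y)
  r
}

#' Pairwise Pearson correlations of residuals
#'
#' Correlation matrix of innate-variation residuals with two-sided p-values
#' from the t distribution on N - 2 degrees of freedom (the plain Pearson
#' test; this slightly understates the df spent on estimating the sample
#' effects, see the methods vignette). A zero-variance column makes its
#' correlations undefined: they are returned as NA with a warning, never
#' silently zeroed.
#'
#' @param residuals N x J numeric matrix (N >= 3).
#' @return list with `r` (J x J, unit diagonal), `p` (J x J, NA diagonal),
#'   and `n`.
#' @export
residual_correlations <- function(residuals) {
  residuals <- as.matrix(residuals)
  N <- nrow(residuals)
  if (N < 3L) stop("need at least 3 samples for correlation p-values")
  sds <- apply(residuals, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance residual column(s): ",
            paste(colnames(residuals)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  }
  r <- suppressWarnings(stats::cor(residuals))
  diag(r) <- 1
  tstat <- r * sqrt((N - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = N - 2)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  list(r = r, p = p, n = N)
}
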