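#' Enumerate all nonempty gene subsets
#'
#' Returns the full collection of 2^J - 1 nonempty subsets of J genes as a
#' 0/1 indicator matrix, in a fixed deterministic order: by subset size,
#' then lexicographically by the included gene indices. The fixed order
#' makes ranks and report rows reproducible across runs.
#'
#' @param J number of candidate genes.
#' @param max_J guard against combinatorial blowup (default 20); raise it
#'   explicitly if you really want more than ~10^6 subsets.
#' @return integer matrix with 2^J - 1 rows and J columns of 0/1 indicators;
#'   row names are indicator strings like `"110010"`.
#' @export
enumerate_subsets <- function(J, max_J = 20L) {
  if (!is.numeric(J) || length(J) != 1L || J < 1L || J != round(J)) {
    stop("J must be a positive integer")
  }
  if (J > max_J) {
    stop(sprintf("J = %d exceeds the subset-enumeration cap (%d); raise max_J to override",
                 J, max_J))
  }
  J <- as.integer(J)
  rows <- vector("list", J)
  for (L in seq_len(J)) {
    cmb <- utils::combn(J, L)
    m <- matrix(0L, nrow = ncol(cmb), ncol = J)
    for (i in seq_len(ncol(cmb))) m[i, cmb[, i]] <- 1L
    rows[[L]] <- m
  }
  S <- do.call(rbind, rows)
  rownames(S) <- apply(S, 1L, paste, collapse = "")
  S
}

subset_sizes <- function(subsets) as.integer(rowSums(subsets))

as_indicator <- function(subset, J) {
  if (is.character(subset) && length(subset) == 1L) {
    subset <- as.integer(strsplit(subset, "")[[1L]])
  }
  subset <- as.numeric(subset)
  if (length(subset) != J || !all(subset %in% c(0, 1))) {
    stop("subset must be a length-", J, " 0/1 indicator vector")
  }
  if (sum(subset) < 1) stop("subset must contain at least one gene")
  subset
}

#' Log geometric mean (log normalizing factor) of a gene subset
#'
#' For log-scale data the log of the geometric mean of the subset's linear
#' expressions is simply the arithmetic mean of the log values:
#' `F_i = (1/L) * sum_{j in subset} y_ij`. This is the (log) normalizing
#' factor that a target gene would be normalized by.
#'
#' @param data an [expression_matrix] on the log-expression or Ct scale.
#' @param subset length-J 0/1 indicator vector (or indicator string).
#' @return length-N numeric vector F.
#' @export
log_geometric_mean <- function(data, subset) {
  assert_expression_matrix(data)
  if (data$scale == "linear_expression") {
    stop("log_geometric_mean needs log-scale (or Ct) data")
  }
  C <- as_indicator(subset, n_genes(data))
  rowMeans(data$values[, C == 1, drop = FALSE])
}

check_symmetric <- function(V, tol = 1e-8) {
  V <- as.matrix(V)
  if (nrow(V) != ncol(V)) stop("V must be square")
  scale <- max(abs(V), 1)
  if (max(abs(V - t(V))) > tol * scale) stop("V is not symmetric")
  V
}

#' Variance of the log normalizing factor of one subset
#'
#' The quadratic form `C' V C / L^2`: the variance of the mean of the
#' selected genes' log expressions under covariance V. When V decomposes as
#' `sigma^2 * 11' + R` (shared sample effect plus gene effects), this equals
#' `sigma^2 + C' R C / L^2`, so minimizing it over subsets is equivalent to
#' minimizing the gene-effect contribution alone.
#'
#' @param V symmetric J x J covariance matrix.
#' @param subset length-J 0/1 indicator (or indicator string).
#' @return scalar variance (squared log units).
#' @export
subset_variance <- function(V, subset) {
  V <- check_symmetric(V)
  C <- as_indicator(subset, nrow(V))
  L <- sum(C)
  as.numeric(C %*% V %*% C) / L^2
}

#' Variances of the log normalizing factor for many subsets at once
#'
#' Vectorized version of [subset_variance()] over the rows of an indicator
#' matrix (as produced by [enumerate_subsets()]).
#'
#' @param V symmetric J x J covariance matrix.
#' @param subsets indicator matrix, one subset per row.
#' @return numeric vector, one variance per subset row.
#' @export
subset_variances <- function(V, subsets) {
  V <- check_symmetric(V)
  S <- as.matrix(subsets)
  L <- rowSums(S)
  rowSums((S %*% V) * S) / L^2
}

#' Empirical variance of the log normalizing factor
#'
#' Unbiased sample variance (divisor N - 1) of the computed per-sample log
#' geometric means. With the intercept-only covariance estimate of the same
#' data this equals [subset_variance()] exactly (both are the same quadratic
#' form), which serves as the package's master self-check.
#'
#' @param data an [expression_matrix] on the log or Ct scale, N >= 2.
#' @param subset length-J 0/1 indicator.
#' @return scalar variance.
#' @export
empirical_loggm_variance <- function(data, subset) {
  assert_expression_matrix(data)
  if (n_samples(data) < 2L) stop("need at least 2 samples")
  stats::var(log_geometric_mean(data, subset))
}

#' Rank subset variances
#'
#' Rank 1 is the smallest variance; ties get the average of the tied rank
#' positions (exact ties are measure-zero for continuous data but do occur
#' among bootstrap replicates, and averaging keeps mean ranks unbiased).
#'
#' @param variances numeric vector.
#' @return numeric rank vector.
#' @export
rank_subsets <- function(variances) {
  rank(variances, ties.method = "average")
}

#' Full subset-variance table
#'
#' Computes the normalizing-factor variance for every nonempty subset under
#' a covariance matrix and ranks them, giving one row per subset.
#'
#' @param V symmetric J x J covariance matrix (e.g. `$V` from
#'   [estimate_covariance()]).
#' @param gene_ids optional gene labels (defaults to V's dimnames).
#' @param max_J passed to [enumerate_subsets()].
#' @return data.frame with columns `subset` (indicator string), `genes`
#'   (comma-joined ids), `size`, `variance`, `sd`, `rank`.
#' @export
subset_variance_table <- function(V, gene_ids = NULL, max_J = 20L) {
  V <- check_symmetric(V)
  J <- nrow(V)
  if (is.null(gene_ids)) gene_ids <- rownames(V)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(J))
  S <- enumerate_subsets(J, max_J = max_J)
  v <- subset_variances(V, S)
  data.frame(
    subset = rownames(S),
    genes = apply(S, 1L, function(c) paste(gene_ids[c == 1], collapse = ",")),
    size = subset_sizes(S),
    variance = v,
    sd = sqrt(pmax(v, 0)),
    rank = rank_subsets(v),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
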