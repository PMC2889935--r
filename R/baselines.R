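#' geNorm pairwise variation of two genes
#'
#' The standard deviation across samples of the difference of the two
#' genes' log expressions (difference of logs = log expression ratio),
#' computed with the unbiased divisor N - 1. Two perfectly proportional
#' genes have pairwise variation 0.
#'
#' @param data an [expression_matrix] on the log scale.
#' @param j,k gene indices or ids; must differ.
#' @return scalar SD (log units).
#' @export
genorm_pairwise_variation <- function(data, j, k) {
  assert_expression_matrix(data)
  j <- .gene_index(data, j)
  k <- .gene_index(data, k)
  if (j == k) stop("pairwise variation needs two distinct genes")
  if (n_samples(data) < 2L) stop("need at least 2 samples")
  stats::sd(data$values[, j] - data$values[, k])
}

.gene_index <- function(data, g) {
  if (is.character(g)) {
    i <- match(g, data$gene_ids)
    if (is.na(i)) stop("unknown gene id: ", g)
    return(i)
  }
  g <- as.integer(g)
  if (g < 1L || g > n_genes(data)) stop("gene index out of range: ", g)
  g
}

.pairwise_variation_matrix <- function(values) {
  J <- ncol(values)
  V <- matrix(NA_real_, J, J, dimnames = list(colnames(values), colnames(values)))
  for (j in seq_len(J - 1L)) {
    for (k in (j + 1L):J) {
      V[j, k] <- V[k, j] <- stats::sd(values[, j] - values[, k])
    }
  }
  V
}

#' geNorm stability ranking by backward elimination
#'
#' Re-implementation of the geNorm algorithm: each gene's stability M is its
#' average pairwise variation with all other genes still in play; the gene
#' with the largest M (least stable) is removed and M recomputed, until two
#' genes remain. Those two are the "seed pair" with the highest expression
#' agreement — the pair the forward description of the algorithm starts
#' from — and are reported as tied-best. The ranking is the elimination
#' order reversed.
#'
#' Because M is an average of SDs of log ratios, changing the log base
#' rescales every M by the same constant and leaves the ranking unchanged.
#'
#' @param data an [expression_matrix] on the log scale with J >= 3 genes.
#' @return object of class `genorm_result`: `ranking` (gene ids, most to
#'   least stable; the first two tied), `elimination_order` (first removed
#'   first), `rounds` (data.frame of gene, round, M, eliminated flag), and
#'   `pairwise` (J x J pairwise-variation matrix).
#' @export
genorm_rank <- function(data) {
  assert_expression_matrix(data)
  if (data$scale == "linear_expression") {
    stop("genorm_rank needs log-scale data; apply log_transform() first")
  }
  J <- n_genes(data)
  if (J < 3L) stop("geNorm ranking needs at least 3 genes")
  PV <- .pairwise_variation_matrix(data$values)
  remaining <- seq_len(J)
  eliminated <- integer(0)
  rounds <- list()
  r <- 0L
  while (length(remaining) > 2L) {
    r <- r + 1L
    M <- vapply(remaining, function(j) {
      mean(PV[j, setdiff(remaining, j)])
    }, numeric(1))
    worst <- remaining[which.max(M)]
    rounds[[r]] <- data.frame(round = r, gene = data$gene_ids[remaining],
                              M = M, eliminated = remaining == worst,
                              stringsAsFactors = FALSE)
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  # final pair: report its (equal) M values for completeness
  Mfin <- rep(PV[remaining[1L], remaining[2L]], 2L)
  rounds[[r + 1L]] <- data.frame(round = r + 1L,
                                 gene = data$gene_ids[remaining],
                                 M = Mfin, eliminated = FALSE,
                                 stringsAsFactors = FALSE)
  structure(
    list(ranking = data$gene_ids[c(remaining, rev(eliminated))],
         seed_pair = data$gene_ids[remaining],
         elimination_order = data$gene_ids[eliminated],
         rounds = do.call(rbind, rounds),
         pairwise = PV),
    class = "genorm_result"
  )
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm ranking (most to least stable):\n ",
      paste(x$ranking, collapse = " > "), "\n")
  cat("seed pair (tied best):", paste(x$seed_pair, collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene variances under the independence assumption
#'
#' The quantity the diagonal-covariance comparator ranks genes by, in one
#' of three modes:
#'
#' * `"total"` (default): each gene's plain sample variance — the diagonal
#'   of the intercept-only covariance estimate, shared sample component
#'   included.
#' * `"innate"`: remove fixed per-sample effects by the unweighted two-way
#'   fit ([residuals_fixed_sample_effects()]) and take the column variances
#'   of the residuals (divisor N - 1). Simple, but the unweighted sample
#'   effect mixes high-variance genes into every residual, compressing and
#'   distorting the per-gene differences.
#' * `"innate_weighted"`: the heteroscedastic fixed-sample-effect model
#'   fitted properly — per-gene error variances with the sample effects
#'   estimated as precision-weighted means, iterated to convergence with a
#'   REML-style degrees-of-freedom correction. This is what mixed-model
#'   software fits for the "model 1a" comparator, and is the mode the
#'   sensitivity experiment uses for the independence-assuming method.
#'
#' @param data an [expression_matrix] on the log or Ct scale, N >= 2
#'   (modes other than `"total"` need J >= 2).
#' @param mode `"total"`, `"innate"` or `"innate_weighted"`.
#' @return named numeric vector of length J with attribute `mode`.
#' @export
estimate_diagonal_variances <- function(data,
                                        mode = c("total", "innate",
                                                 "innate_weighted")) {
  assert_expression_matrix(data)
  mode <- match.arg(mode)
  if (n_samples(data) < 2L) stop("need at least 2 samples")
  v <- switch(mode,
    total = apply(data$values, 2L, stats::var),
    innate = apply(residuals_fixed_sample_effects(data), 2L, stats::var),
    innate_weighted = .weighted_innate_variances(data$values)
  )
  names(v) <- data$gene_ids
  attr(v, "mode") <- mode
  v
}

# Heteroscedastic two-way fixed-effects fit:
#   y_ij = mu + s_i + g_j + e_ij,  Var(e_ij) = tau_j^2.
# Given tau^2 the GLS sample effect is the precision-weighted mean across
# genes; tau_j^2 is then updated from gene j's residual sum of squares with
# the REML df  N - 1 - N * w_j / sum(w)  (each gene loses one df to its own
# mean and its precision share of each sample effect). Iterated to a fixed
# point. The df correction is what keeps the fit away from the tau -> 0
# collapse that plain ML exhibits with N incidental sample effects.
.weighted_innate_variances <- function(X, max_iter = 200L, tol = 1e-9) {
  N <- nrow(X)
  J <- ncol(X)
  if (J < 2L) stop("need at least 2 genes to separate the sample effect")
  tau2 <- pmax(apply(X, 2L, stats::var), 1e-12)
  g <- colMeans(X)
  for (it in seq_len(max_iter)) {
    w <- 1 / tau2
    s <- rep(0, N)
    for (k in seq_len(100L)) {
      s_new <- as.vector(sweep(X, 2L, g) %*% w) / sum(w)
      s_new <- s_new - mean(s_new)   # identifiability: sample effects sum to 0
      g_new <- colMeans(X - s_new)
      done <- max(abs(s_new - s), abs(g_new - g)) < 1e-12
      s <- s_new
      g <- g_new
      if (done) break
    }
    E <- X - outer(s, rep(1, J)) - outer(rep(1, N), g)
    df <- N - 1 - N * w / sum(w)
    tau2_new <- pmax(colSums(E^2) / df, 1e-12)
    delta <- max(abs(tau2_new - tau2) / pmax(tau2, 1e-8))
    tau2 <- tau2_new
    if (delta < tol) break
  }
  tau2
}

#' Independence-assuming (diagonal-covariance) subset comparator
#'
#' Under a diagonal covariance model the variance of the log normalizing
#' factor of a size-L subset is (sum of the per-gene variances) / L^2, so
#' the best size-L subset is simply the L genes with the smallest variances.
#' This computes that best subset and score for every size and the overall
#' argmin across sizes (ties prefer the smaller size).
#'
#' @param variances length-J nonnegative vector of per-gene variances, e.g.
#'   from [estimate_diagonal_variances()].
#' @param gene_ids optional labels (default from names).
#' @return object of class `uncorrelated_result`: `table` (size, subset
#'   indicator, genes, score), `best_size`, `best_subset` (indicator
#'   string), `variances`.
#' @export
uncorrelated_subset_table <- function(variances, gene_ids = NULL) {
  v <- as.numeric(variances)
  if (any(v < 0)) stop("variances must be nonnegative")
  J <- length(v)
  if (is.null(gene_ids)) gene_ids <- names(variances)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(J))
  ord <- order(v, seq_len(J))
  rows <- lapply(seq_len(J), function(L) {
    pick <- sort(ord[seq_len(L)])
    ind <- rep(0L, J)
    ind[pick] <- 1L
    data.frame(size = L,
               subset = paste(ind, collapse = ""),
               genes = paste(gene_ids[pick], collapse = ","),
               score = sum(v[pick]) / L^2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$score)   # first minimum = smallest size on ties
  structure(
    list(table = tab, best_size = tab$size[best],
         best_subset = tab$subset[best], best_genes = tab$genes[best],
         variances = stats::setNames(v, gene_ids),
         mode = attr(variances, "mode")),
    class = "uncorrelated_result"
  )
}

#' @export
print.uncorrelated_result <- function(x, ...) {
  cat("independence-assuming comparator",
      if (!is.null(x$mode)) sprintf("(mode: %s)", x$mode), "\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("overall best: size %d, {%s}\n", x$best_size, x$best_genes))
  invisible(x)
}
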