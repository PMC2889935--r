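#' Bootstrap the normalizing-factor variances of all gene subsets
#'
#' The robust selection engine. Samples are resampled with replacement B
#' times as whole rows (complete per-sample gene vectors, so all cross-gene
#' correlation is preserved). For each bootstrap replicate the unstructured
#' covariance V is re-estimated, the variance of the log normalizing factor
#' is computed for every one of the 2^J - 1 subsets, and the subsets are
#' ranked. The summary holds, per subset, the 95th percentile of its
#' variance across replicates (the bootstrap 95% upper confidence limit),
#' the same limit on the SD scale, and the mean rank across replicates.
#'
#' For the intercept-only mean model the whole computation is vectorized:
#' a row resample is equivalent to a vector of multinomial row counts, so
#' all B covariance estimates reduce to two matrix products, and all subset
#' variances to one more (the quadratic form is linear in the covariance
#' entries). A general design matrix falls back to an explicit loop;
#' replicates whose resampled design is rank deficient are redrawn (counted
#' and reported with a warning).
#'
#' Percentiles use the standard empirical quantile with linear interpolation
#' between order statistics (R type 7). Results are bit-reproducible given
#' the same data, B and seed.
#'
#' @param data an [expression_matrix] on the log-expression or Ct scale,
#'   N >= 3.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed; mandatory, recorded in the summary.
#' @param design optional [design_spec]; `NULL` means intercept-only.
#' @param max_J subset-enumeration cap, see [enumerate_subsets()].
#' @return object of class `bootstrap_summary`: list with `table` (one row
#'   per subset: subset, genes, size, point_variance, ucl95_variance,
#'   ucl95_sd, mean_rank), `B`, `seed`, `n_samples`, `gene_ids`, `subsets`
#'   (indicator matrix), and `redraws`.
#' @export
bootstrap_selection <- function(data, B = 1000L, seed, design = NULL,
                                max_J = 20L) {
  assert_expression_matrix(data)
  if (missing(seed)) stop("an explicit RNG seed is required for provenance")
  N <- n_samples(data)
  J <- n_genes(data)
  if (N < 3L) stop("need at least 3 samples to bootstrap")
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")

  S <- enumerate_subsets(J, max_J = max_J)
  L <- subset_sizes(S)
  point_est <- estimate_covariance(data, design)
  point_var <- subset_variances(point_est$V, S)

  intercept_only <- is.null(design) || ncol(design$A) == 1L
  redraws <- 0L
  set.seed(seed)

  if (intercept_only) {
    VarMat <- .boot_variances_vectorized(data$values, B, S, L)
  } else {
    A <- design$A
    p <- ncol(A)
    VarMat <- matrix(NA_real_, nrow = B, ncol = nrow(S))
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(N, N, replace = TRUE)
        Ab <- A[idx, , drop = FALSE]
        qrb <- qr(Ab)
        if (qrb$rank == p) break
        redraws <- redraws + 1L
      }
      Eb <- qr.resid(qrb, data$values[idx, , drop = FALSE])
      Vb <- crossprod(Eb) / (N - p)
      VarMat[b, ] <- rowSums((S %*% Vb) * S) / L^2
    }
    if (redraws > 0L) {
      warning(redraws, " bootstrap replicate(s) redrawn due to rank-deficient design")
    }
  }

  RankMat <- t(apply(VarMat, 1L, rank, ties.method = "average"))
  if (nrow(S) == 1L) RankMat <- matrix(1, nrow = B, ncol = 1L)
  ucl <- apply(VarMat, 2L, stats::quantile, probs = 0.95, type = 7,
               names = FALSE)

  tab <- data.frame(
    subset = rownames(S),
    genes = apply(S, 1L, function(c) {
      paste(data$gene_ids[c == 1], collapse = ",")
    }),
    size = L,
    point_variance = point_var,
    ucl95_variance = ucl,
    ucl95_sd = sqrt(pmax(ucl, 0)),
    mean_rank = colMeans(RankMat),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, B = B, seed = seed, n_samples = N,
         gene_ids = data$gene_ids, subsets = S, redraws = redraws),
    class = "bootstrap_summary"
  )
}

# All-B bootstrap covariances and subset variances in a few matrix products.
# A row resample is a multinomial count vector over the N rows; for counts q,
#   mean_j   = (q %*% X)_j / N
#   (N-1)V_jk = q %*% (X_j * X_k) - N * mean_j * mean_k
# and each subset variance is a fixed linear combination of the V entries.
.boot_variances_vectorized <- function(X, B, S, L) {
  N <- nrow(X)
  J <- ncol(X)
  Q <- t(stats::rmultinom(B, size = N, prob = rep(1 / N, N)))  # B x N
  storage.mode(Q) <- "double"
  pp <- which(upper.tri(diag(J), diag = TRUE), arr.ind = TRUE) # M pairs
  Z <- X[, pp[, 1], drop = FALSE] * X[, pp[, 2], drop = FALSE] # N x M
  M1 <- (Q %*% X) / N                                          # B x J means
  SS <- Q %*% Z                                                # B x M
  Vvec <- (SS - N * M1[, pp[, 1], drop = FALSE] *
                 M1[, pp[, 2], drop = FALSE]) / (N - 1)        # B x M
  W <- S[, pp[, 1], drop = FALSE] * S[, pp[, 2], drop = FALSE] # nsub x M
  mult <- ifelse(pp[, 1] == pp[, 2], 1, 2)
  Wm <- sweep(W, 2L, mult, "*") / L^2                          # nsub x M
  Vvec %*% t(Wm)                                               # B x nsub
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary: %d subsets of %d genes, N = %d, B = %d, seed = %s\n",
              nrow(x$table), length(x$gene_ids), x$n_samples, x$B,
              format(x$seed)))
  best <- x$table[order(x$table$ucl95_variance, x$table$size), ][1L, ]
  cat(sprintf("smallest 95%% UCL Var(logGM): %.4g for {%s}\n",
              best$ucl95_variance, best$genes))
  invisible(x)
}

.selection_result <- function(criterion, row, summary, threshold = NULL,
                              status = "ok") {
  structure(
    list(criterion = criterion,
         subset = if (is.null(row)) character(0) else row$subset,
         genes = if (is.null(row)) character(0) else row$genes,
         size = if (is.null(row)) NA_integer_ else row$size,
         metrics = if (is.null(row)) list() else
           list(ucl95_variance = row$ucl95_variance,
                ucl95_sd = row$ucl95_sd,
                mean_rank = row$mean_rank,
                point_variance = row$point_variance),
         threshold = threshold,
         status = status,
         B = summary$B, seed = summary$seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("criterion %s: no subset qualifies (%s)\n", x$criterion, x$status))
    return(invisible(x))
  }
  cat(sprintf("criterion %s: subset {%s} (size %d)\n", x$criterion, x$genes, x$size))
  cat(sprintf("  95%% UCL Var(logGM) = %.4g (SD %.4g), mean rank = %.2f\n",
              x$metrics$ucl95_variance, x$metrics$ucl95_sd, x$metrics$mean_rank))
  invisible(x)
}

# rows of summary$table in tie-broken preference order for a metric:
# smaller metric first, then smaller subset size, then enumeration order
# (which is size-major, then lexicographic -- so ties resolve reproducibly).
.order_by <- function(tab, metric) {
  order(tab[[metric]], tab$size, seq_len(nrow(tab)))
}

#' Criterion A: minimize the bootstrap 95% UCL of the variance
#'
#' Chooses the subset with the smallest bootstrap 95% upper confidence limit
#' on the variance of the log normalizing factor, regardless of how many
#' genes it needs. Ties prefer the smaller subset, then enumeration order.
#'
#' @param summary a [bootstrap_selection()] result.
#' @return a `selection_result`.
#' @export
select_criterion_A <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  row <- summary$table[.order_by(summary$table, "ucl95_variance")[1L], ]
  .selection_result("A", row, summary)
}

#' Criterion B: fewest genes under an acceptable variability limit
#'
#' Among subsets whose 95% UCL on the SD scale is at or below the given
#' threshold, chooses the smallest subset; within that size, the smallest
#' UCL. If no subset qualifies an empty result with an explanatory status is
#' returned (not an error).
#'
#' @param summary a [bootstrap_selection()] result.
#' @param sd_threshold acceptable upper limit on the SD (log units) of the
#'   normalizing factor; must be positive.
#' @return a `selection_result` (status `"none_below_threshold"` if empty).
#' @export
select_criterion_B <- function(summary, sd_threshold) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    stop("sd_threshold must be a positive number (log units)")
  }
  tab <- summary$table
  ok <- tab$ucl95_sd <= sd_threshold
  if (!any(ok)) {
    return(.selection_result("B", NULL, summary, threshold = sd_threshold,
                             status = "none_below_threshold"))
  }
  cand <- tab[ok, , drop = FALSE]
  cand <- cand[order(cand$size, cand$ucl95_sd), , drop = FALSE]
  .selection_result("B", cand[1L, ], summary, threshold = sd_threshold)
}

#' Criterion C: minimize the mean bootstrap rank
#'
#' Chooses the subset whose variance had the smallest average rank across
#' bootstrap replicates. Ties prefer the smaller subset, then enumeration
#' order.
#'
#' @param summary a [bootstrap_selection()] result.
#' @return a `selection_result`.
#' @export
select_criterion_C <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  row <- summary$table[.order_by(summary$table, "mean_rank")[1L], ]
  .selection_result("C", row, summary)
}

#' Coordinates for the UCL-vs-mean-rank scatter
#'
#' Criteria A and C can be weighed jointly by plotting each subset's 95% UCL
#' (SD scale) against its mean bootstrap rank; a subset near the lower-left
#' corner is good on both. This returns the plot coordinates plus a
#' normalized distance to that corner: both axes are min-max scaled to
#' [0, 1] and the Euclidean distance taken, so the two criteria get equal
#' weight regardless of their units. Rows are sorted by that distance.
#'
#' @param summary a [bootstrap_selection()] result.
#' @param rank_cutoff optional: keep only subsets with mean rank below this
#'   (useful when 2^J - 1 is large); scaling still uses all subsets.
#' @return data.frame with subset, genes, size, mean_rank, ucl95_sd,
#'   normalized_distance, sorted ascending by distance.
#' @export
ucl_vs_rank_plotdata <- function(summary, rank_cutoff = NULL) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  tab <- summary$table
  mm <- function(z) {
    rng <- range(z)
    if (rng[1L] == rng[2L]) rep(0, length(z)) else (z - rng[1L]) / diff(rng)
  }
  d <- sqrt(mm(tab$mean_rank)^2 + mm(tab$ucl95_sd)^2)
  out <- data.frame(subset = tab$subset, genes = tab$genes, size = tab$size,
                    mean_rank = tab$mean_rank, ucl95_sd = tab$ucl95_sd,
                    normalized_distance = d, stringsAsFactors = FALSE)
  if (!is.null(rank_cutoff)) out <- out[out$mean_rank < rank_cutoff, , drop = FALSE]
  out <- out[order(out$normalized_distance, out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best subset of each size by 95% UCL
#'
#' The "top ranked by set size" report: for each subset size the subset with
#' the smallest bootstrap 95% UCL of the normalizing-factor variance.
#'
#' @param summary a [bootstrap_selection()] result.
#' @return data.frame, one row per size.
#' @export
top_subsets_by_size <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  tab <- summary$table
  picks <- lapply(split(tab, tab$size), function(g) {
    g[order(g$ucl95_variance), ][1L, ]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out[order(out$size), ]
}

#' Top subsets by mean bootstrap rank
#'
#' The "top 10 overall" report: subsets with the smallest mean rank of the
#' normalizing-factor variance across bootstrap replicates, any size.
#'
#' @param summary a [bootstrap_selection()] result.
#' @param n how many rows (default 10).
#' @return data.frame sorted by mean rank.
#' @export
top_by_mean_rank <- function(summary, n = 10L) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  tab <- summary$table[.order_by(summary$table, "mean_rank"), ]
  out <- utils::head(tab, n)
  rownames(out) <- NULL
  out
}
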