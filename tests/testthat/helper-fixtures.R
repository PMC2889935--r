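# in-code fixtures shared across test files

# random log-expression matrix with mild cross-gene correlation
rand_logexpr <- function(N = 20, J = 5, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(J * J, sd = 0.4), J, J)
  V <- crossprod(A) + diag(0.2, J)
  X <- matrix(rnorm(N * J), N, J) %*% chol(V)
  expression_matrix(X, scale = "log_expression")
}

write_wide_tsv <- function(values, ids, genes, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample = ids, values, check.names = FALSE)
  colnames(df) <- c("sample", genes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# printed per-size minima of the simulation-design table (3 dp, half-up)
TRUE_MINIMA <- list(
  s1_uncorrelated = c(0.250, 0.213, 0.255, 0.264, 0.267),
  s2_pos02        = c(0.380, 0.275, 0.239, 0.275, 0.301),
  s3_mixed02      = c(0.276, 0.176, 0.141, 0.166, 0.175),
  s4_mixed04      = c(0.250, 0.199, 0.217, 0.223, 0.244),
  s5_pos04        = c(0.260, 0.243, 0.274, 0.302, 0.331)
)
# printed independence-assuming comparator scores (diagonal of V), excluding
# the fourth scenario whose printed column is internally inconsistent
UNCORR_MINIMA <- list(
  s1_uncorrelated = c(0.250, 0.133, 0.148, 0.144, 0.139),
  s2_pos02        = c(0.380, 0.223, 0.164, 0.169, 0.167),
  s3_mixed02      = c(0.276, 0.145, 0.101, 0.086, 0.073),
  s5_pos04        = c(0.260, 0.153, 0.133, 0.121, 0.114)
)
# printed values are rounded half-up to 3 dp, so half a printed ulp plus
# binary-representation slack
PRINT_TOL <- 5.1e-4

# independent brute-force geNorm oracle: recompute every stability value
# from scratch each round with plain loops
genorm_oracle <- function(values, gene_ids) {
  J <- ncol(values)
  pv <- function(a, b) sd(values[, a] - values[, b])
  remaining <- seq_len(J)
  elim <- integer(0)
  while (length(remaining) > 2L) {
    M <- sapply(remaining, function(j) {
      others <- setdiff(remaining, j)
      mean(sapply(others, function(k) pv(j, k)))
    })
    worst <- remaining[which.max(M)]
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  gene_ids[c(remaining, rev(elim))]
}
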