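# construct a summary object with chosen per-subset metrics, for testing the
# selection criteria in isolation
mock_summary <- function(sizes, ucl_sd = NULL, mean_rank = NULL,
                         genes = NULL) {
  n <- length(sizes)
  if (is.null(ucl_sd)) ucl_sd <- rep(1, n)
  if (is.null(mean_rank)) mean_rank <- seq_len(n)
  if (is.null(genes)) genes <- paste0("set", seq_len(n))
  tab <- data.frame(
    subset = sprintf("m%02d", seq_len(n)), genes = genes, size = sizes,
    point_variance = ucl_sd^2, ucl95_variance = ucl_sd^2, ucl95_sd = ucl_sd,
    mean_rank = mean_rank, stringsAsFactors = FALSE
  )
  structure(list(table = tab, B = 1000L, seed = 1L, n_samples = 40L,
                 gene_ids = letters[1:5],
                 subsets = matrix(1L, n, 1L), redraws = 0L),
            class = "bootstrap_summary")
}

test_that("bootstrap summary is reproducible and matches a loop oracle", {
  x <- rand_logexpr(12, 4, seed = 21)
  b1 <- bootstrap_selection(x, B = 60, seed = 99)
  b2 <- bootstrap_selection(x, B = 60, seed = 99)
  expect_identical(b1, b2)
  expect_false(identical(b1$table$ucl95_variance,
                         bootstrap_selection(x, B = 60, seed = 100)$table$ucl95_variance))

  # oracle: explicit per-replicate resampling loop fed the same multinomial
  # counts, direct cov() + quadratic form + rank + type-7 quantile
  N <- 12
  set.seed(99)
  Q <- t(rmultinom(60, N, rep(1 / N, N)))
  S <- enumerate_subsets(4)
  L <- rowSums(S)
  vm <- matrix(NA_real_, 60, nrow(S))
  for (b in 1:60) {
    idx <- rep(seq_len(N), Q[b, ])
    Vb <- cov(x$values[idx, ])
    vm[b, ] <- apply(S, 1, function(C) (C %*% Vb %*% C) / sum(C)^2)
  }
  expect_equal(b1$table$ucl95_variance,
               apply(vm, 2, quantile, 0.95, names = FALSE),
               tolerance = 1e-12)
  expect_equal(b1$table$mean_rank,
               colMeans(t(apply(vm, 1, rank))), tolerance = 1e-12)
  expect_equal(b1$table$point_variance,
               subset_variances(cov(x$values), S), ignore_attr = TRUE)
  # the 95th percentile dominates the 5th for every subset
  expect_true(all(b1$table$ucl95_variance >=
                  apply(vm, 2, quantile, 0.05, names = FALSE)))
})

test_that("degenerate and single-replicate cases behave as defined", {
  # identical samples: all variances zero, every rank tied at the midpoint
  xz <- expression_matrix(matrix(1.5, 6, 3), scale = "log_expression")
  bz <- bootstrap_selection(xz, B = 25, seed = 3)
  expect_equal(bz$table$ucl95_variance, rep(0, 7))
  expect_equal(bz$table$mean_rank, rep(4, 7))

  # B = 1: the UCL is that single replicate's variance
  x <- rand_logexpr(10, 3, seed = 4)
  b1 <- bootstrap_selection(x, B = 1, seed = 17)
  set.seed(17)
  q <- rmultinom(1, 10, rep(0.1, 10))[, 1]
  Vb <- cov(x$values[rep(1:10, q), ])
  expect_equal(b1$table$ucl95_variance,
               subset_variances(Vb, enumerate_subsets(3)),
               ignore_attr = TRUE)

  expect_error(bootstrap_selection(x, B = 0, seed = 1), "B must be")
  expect_error(bootstrap_selection(x, B = 10), "seed")
})

test_that("general designs bootstrap by explicit resampling", {
  x <- rand_logexpr(16, 3, seed = 5)
  x$covariates <- data.frame(tissue = rep(c("a", "b"), each = 8))
  ds <- design_spec(x, ~tissue)
  b <- bootstrap_selection(x, B = 40, seed = 11, design = ds)
  expect_identical(b, bootstrap_selection(x, B = 40, seed = 11, design = ds))
  expect_true(all(b$table$ucl95_variance >= 0))
  expect_equal(b$table$point_variance,
               subset_variances(estimate_covariance(x, ds)$V,
                                enumerate_subsets(3)), ignore_attr = TRUE)
})

test_that("criterion A minimizes the UCL with size tie-breaking", {
  s <- mock_summary(sizes = c(1, 2, 3, 4),
                    ucl_sd = sqrt(c(0.407, 0.349, 0.356, 0.398)))
  a <- select_criterion_A(s)
  expect_equal(a$size, 2)
  expect_equal(a$metrics$ucl95_variance, 0.349)

  # exact UCL tie: the smaller subset wins
  st <- mock_summary(sizes = c(3, 2), ucl_sd = c(0.5, 0.5))
  expect_equal(select_criterion_A(st)$size, 2)

  s1 <- mock_summary(sizes = 1, ucl_sd = 0.3)
  expect_equal(select_criterion_A(s1)$subset, "m01")
})

test_that("criterion B picks the smallest qualifying subset", {
  # per-size UCL-SD profile shaped like a real 10-gene run: sizes 1..10
  sds <- c(0.677, 0.583, 0.583, 0.550, 0.547, 0.546, 0.550, 0.563, 0.578,
           0.594)
  s <- mock_summary(sizes = 1:10, ucl_sd = sds)
  b <- select_criterion_B(s, sd_threshold = 0.55)
  expect_equal(b$size, 4)   # smallest size with UCL-SD <= 0.55
  expect_equal(b$metrics$ucl95_sd, 0.550)

  # threshold below every UCL: empty result with status, not an error
  none <- select_criterion_B(s, sd_threshold = 0.1)
  expect_equal(none$status, "none_below_threshold")
  expect_length(none$subset, 0)

  # threshold above every UCL: size minimality forces the single gene
  all_ok <- select_criterion_B(s, sd_threshold = 10)
  expect_equal(all_ok$size, 1)
  expect_error(select_criterion_B(s, sd_threshold = -1), "positive")
})

test_that("criterion C minimizes mean rank with argmin oracle", {
  s <- mock_summary(sizes = c(2, 3, 2, 1), mean_rank = c(1.2, 2.0, 3.2, 6.4))
  expect_equal(select_criterion_C(s)$subset, "m01")

  set.seed(12)
  for (rep in 1:5) {
    mr <- runif(8, 1, 31)
    s2 <- mock_summary(sizes = rep(2, 8), mean_rank = mr)
    expect_equal(select_criterion_C(s2)$subset,
                 s2$table$subset[which.min(mr)])
  }

  # full tie: smallest size, then enumeration (lexicographic) order
  s3 <- mock_summary(sizes = c(3, 2, 2), mean_rank = c(5, 5, 5))
  expect_equal(select_criterion_C(s3)$subset, "m02")
})

test_that("UCL-vs-rank plot data measures distance to the ideal corner", {
  # a subset that is argmin of both axes has distance 0 and sorts first
  s <- mock_summary(sizes = c(2, 3, 4), ucl_sd = c(0.5, 0.7, 0.9),
                    mean_rank = c(1.5, 4, 9))
  pd <- ucl_vs_rank_plotdata(s)
  expect_equal(pd$normalized_distance[1], 0)
  expect_equal(pd$subset[1], "m01")

  # two subsets: hand min-max scaling puts both at the corners
  s2 <- mock_summary(sizes = c(2, 3), ucl_sd = c(0.4, 0.8),
                     mean_rank = c(2, 1))
  pd2 <- ucl_vs_rank_plotdata(s2)
  expect_equal(sort(pd2$normalized_distance), c(1, 1))

  # real run: row count is 2^J - 1, and the rank cutoff filters
  x <- rand_logexpr(14, 4, seed = 30)
  bs <- bootstrap_selection(x, B = 50, seed = 2)
  pd3 <- ucl_vs_rank_plotdata(bs)
  expect_equal(nrow(pd3), 15L)
  pd4 <- ucl_vs_rank_plotdata(bs, rank_cutoff = 8)
  expect_true(all(pd4$mean_rank < 8))
})

test_that("criterion A's choice is its size's best in the per-size report", {
  x <- rand_logexpr(20, 5, seed = 41)
  bs <- bootstrap_selection(x, B = 100, seed = 7)
  a <- select_criterion_A(bs)
  tops <- top_subsets_by_size(bs)
  expect_equal(tops$subset[tops$size == a$size], a$subset)
  expect_equal(nrow(tops), 5L)
  # top-by-rank report is sorted and bounded
  t10 <- top_by_mean_rank(bs, 10)
  expect_equal(nrow(t10), 10L)
  expect_true(!is.unsorted(t10$mean_rank))
})

test_that("a dominating low-variance pair is selected by all criteria", {
  # strongly anticorrelated low-variance pair: Var(logGM of genes 1-2) is
  # ~12x below every other subset, so the pair truly dominates
  corr <- diag(5)
  corr[1, 2] <- corr[2, 1] <- -0.9
  spec <- scenario_spec(0.01, c(0.5, 0.5, 2, 2, 2), corr,
                        n_samples = 200, seed = 50)
  wins <- c(A = 0L, C = 0L)
  for (r in 1:5) {
    x <- simulate_dataset(spec, seed = 100 + r)
    bs <- bootstrap_selection(x, B = 100, seed = 200 + r)
    if (select_criterion_A(bs)$subset == "11000") wins["A"] <- wins["A"] + 1L
    if (select_criterion_C(bs)$subset == "11000") wins["C"] <- wins["C"] + 1L
  }
  expect_equal(unname(wins), c(5L, 5L))
})
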