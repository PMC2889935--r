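test_that("wide tables parse in either orientation and errors name the cell", {
  v <- matrix(c(20, 21, 23, 25, 26, 27), nrow = 3)
  p <- write_wide_tsv(v, c("s1", "s2", "s3"), c("gA", "gB"))
  x <- read_expression_table(p, orientation = "samples_rows", scale = "ct")
  expect_s3_class(x, "expression_matrix")
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(x$scale, "ct")
  expect_equal(unname(x$values[, 1]), c(20, 21, 23))

  # the transposed file with orientation=genes_rows gives the identical matrix
  pt <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = c("gA", "gB"), t(v), check.names = FALSE)
  colnames(df) <- c("gene", "s1", "s2", "s3")
  write.table(df, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  xt <- read_expression_table(pt, orientation = "genes_rows", scale = "ct")
  expect_equal(xt$values, x$values)

  # missing cell: default policy errors naming sample and gene
  vna <- v
  vna[2, 2] <- NA
  pna <- write_wide_tsv(vna, c("s1", "s2", "s3"), c("gA", "gB"))
  expect_error(read_expression_table(pna, scale = "ct"), "s2.*gB")
  # drop-sample policy removes the offending sample only
  xd <- read_expression_table(pna, scale = "ct", na_policy = "drop_sample")
  expect_equal(x$sample_ids[c(1, 3)], xd$sample_ids)

  # non-numeric garbage is a parse error naming the cell
  vtx <- matrix(c("20", "oops", "23", "25", "26", "27"), nrow = 3)
  ptx <- write_wide_tsv(vtx, c("s1", "s2", "s3"), c("gA", "gB"))
  expect_error(read_expression_table(ptx, scale = "ct"), "oops")

  # duplicate gene ids rejected
  pdup <- write_wide_tsv(v, c("s1", "s2", "s3"), c("gA", "gA"))
  expect_error(read_expression_table(pdup, scale = "ct"), "duplicated")
})

test_that("write/read round trip is lossless at full precision", {
  x <- rand_logexpr(7, 3, seed = 42)
  p <- tempfile(fileext = ".csv")
  write_expression_table(x, p)
  y <- read_expression_table(p, scale = "log_expression")
  expect_identical(y$values, x$values)
})

test_that("replicate averaging takes per-(sample,gene) means and checks the grid", {
  tab <- data.frame(
    sample = c("s1", "s1", "s1", "s1", "s1", "s2", "s2"),
    gene = c("g1", "g1", "g2", "g2", "g2", "g1", "g2"),
    replicate = c(1, 2, 1, 2, 3, 1, 1),
    value = c(20, 22, 20, 21, 25, 30, 31)
  )
  x <- average_replicates(tab)
  expect_equal(x$values["s1", "g1"], 21.0)
  expect_equal(x$values["s1", "g2"], 22.0)  # mean of 20, 21, 25
  expect_equal(x$values["s2", "g1"], 30)

  # K = 1 everywhere: identity, hence idempotent
  tab1 <- tab[tab$replicate == 1, ]
  x1 <- average_replicates(tab1)
  expect_equal(unname(x1$values),
               matrix(c(20, 30, 20, 31), nrow = 2))

  # a missing (sample, gene) pair is an error listing the pair
  expect_error(average_replicates(tab[-(6), ]), "\\(s2, g1\\)")
})

test_that("Ct -> relative expression anchors at the per-gene minimum Ct", {
  x <- expression_matrix(cbind(c(20, 21, 23), c(30, 28, 29)), scale = "ct")
  q <- ct_to_relative_expression(x)
  expect_equal(q$scale, "linear_expression")
  expect_equal(unname(q$values[, 1]), c(1, 0.5, 0.125))
  expect_equal(unname(q$values[, 2]), c(0.25, 1, 0.5))

  # constant Ct column maps to all ones
  xc <- expression_matrix(cbind(c(25, 25)), scale = "ct")
  expect_equal(unname(ct_to_relative_expression(xc)$values[, 1]), c(1, 1))

  # only legal on Ct data
  expect_error(ct_to_relative_expression(rand_logexpr(4, 2)), "scale")

  # min and max anchors differ by a per-gene constant on the log scale
  qmax <- ct_to_relative_expression(x, anchor = "max")
  rat <- q$values / qmax$values
  expect_equal(rat[1, 1], rat[2, 1])
  expect_equal(rat[1, 2], rat[3, 2])
})

test_that("log transform respects base and domain", {
  x <- expression_matrix(cbind(c(1, exp(1), exp(2))), scale = "linear_expression")
  expect_equal(unname(log_transform(x)$values[, 1]), c(0, 1, 2))
  x2 <- expression_matrix(cbind(c(1, 0.5)), scale = "linear_expression")
  expect_equal(unname(log_transform(x2, base = "2")$values[, 1]), c(0, -1))
  x0 <- expression_matrix(cbind(c(1, 1e-12)), scale = "linear_expression")
  x0$values[2, 1] <- 0
  expect_error(log_transform(x0), "nonpositive")
  expect_error(log_transform(rand_logexpr(3, 2)), "scale")
})

test_that("Ct transform invariants hold on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    ct <- expression_matrix(matrix(runif(24, 18, 34), 8, 3), scale = "ct")
    q <- ct_to_relative_expression(ct)
    # per-gene maximum of relative expression is exactly 1
    expect_equal(unname(apply(q$values, 2, max)), rep(1, 3))
    # log2 of the transform recovers minCt - Ct exactly
    l2 <- log_transform(q, base = "2")
    mins <- apply(ct$values, 2, min)
    expect_equal(l2$values, sweep(-ct$values, 2, mins, "+"),
                 tolerance = 1e-12)
  }
})
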