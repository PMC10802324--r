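# The 1-D worked example used throughout: samples 0,1 in group A and 3,4 in
# group B. Hand computation with explicit 1x1 scatter matrices:
#   group means 0.5 / 3.5, global mean 2
#   Db^2 = (2*(0.5-2)^2 + 2*(3.5-2)^2)/4 = 2.25 -> Db = 1.5
#   Dw^2 = (0.25*4)/4 = 0.25              -> Dw = 0.5, DSC = 3
micro_data <- matrix(c(0, 1, 3, 4), ncol = 1)
micro_labels <- c("A", "A", "B", "B")

test_that("worked 1-D example gives Db=1.5, Dw=0.5, DSC=3 in both forms", {
  for (f in list(dsc_fast, dsc_naive)) {
    r <- f(micro_data, micro_labels)
    expect_equal(r$db, 1.5)
    expect_equal(r$dw, 0.5)
    expect_equal(r$dsc, 3)
    expect_equal(r$n_samples, 4L)
    expect_equal(r$n_groups, 2L)
  }
})

test_that("trace form and explicit scatter form agree on random instances", {
  set.seed(31)
  for (i in 1:100) {
    inst <- random_dsc_instance(n_samples = sample(6:50, 1),
                                n_dims = sample(1:200, 1),
                                n_groups = sample(2:6, 1))
    a <- dsc_fast(inst$data, inst$labels)
    b <- dsc_naive(inst$data, inst$labels)
    expect_equal(a$db, b$db, tolerance = 1e-10)
    expect_equal(a$dw, b$dw, tolerance = 1e-10)
    expect_equal(a$dsc, b$dsc, tolerance = 1e-10)
  }
})

test_that("between and within dispersion decompose the total scatter", {
  set.seed(32)
  for (i in 1:20) {
    inst <- random_dsc_instance(sample(6:40, 1), sample(1:50, 1),
                                sample(2:5, 1))
    r <- dsc_fast(inst$data, inst$labels)
    total <- sum(sweep(inst$data, 2, colMeans(inst$data))^2) /
      nrow(inst$data)
    expect_equal(r$db^2 + r$dw^2, total, tolerance = 1e-9)
  }
})

test_that("DSC is invariant to translation, scaling and rotation", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_dsc_instance(sample(8:30, 1), sample(2:20, 1),
                                sample(2:4, 1))
    base <- dsc_fast(inst$data, inst$labels)$dsc
    shifted <- sweep(inst$data, 2, rnorm(ncol(inst$data), sd = 50), "+")
    expect_equal(dsc_fast(shifted, inst$labels)$dsc, base,
                 tolerance = 1e-9)
    c_pos <- runif(1, 0.1, 40)
    expect_equal(dsc_fast(inst$data * c_pos, inst$labels)$dsc, base,
                 tolerance = 1e-9)
    d <- ncol(inst$data)
    Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
    expect_equal(dsc_fast(inst$data %*% Q, inst$labels)$dsc, base,
                 tolerance = 1e-9)
  }
})

test_that("identical group distributions give DSC 0; degenerate cases error", {
  # both groups hold the values {0, 1}: group means equal the global mean
  x <- matrix(c(0, 1, 0, 1), ncol = 1)
  r <- dsc_fast(x, c("A", "A", "B", "B"))
  expect_equal(r$db, 0)
  expect_equal(r$dsc, 0)
  # duplicating one group into two equal-mean groups: db = 0 (naive form)
  y <- matrix(rnorm(16), ncol = 2)
  y2 <- rbind(y, y)
  rn <- dsc_naive(y2, rep(c("g1", "g2"), each = 8))
  expect_equal(rn$db, 0, tolerance = 1e-12)
  # dw = 0 with distinct means is undefined
  z <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_error(dsc_fast(z, c("A", "A", "B", "B")),
               "zero within-group dispersion")
  # dw = 0 and db = 0: DSC defined as 0 with a warning
  w <- matrix(rep(2, 4), ncol = 1)
  expect_warning(r0 <- dsc_fast(w, c("A", "A", "B", "B")), "degenerate")
  expect_equal(r0$dsc, 0)
  # fewer than 2 groups is a parameter error
  expect_error(dsc_fast(y, rep("A", 8)), "at least 2 groups")
  # size-1 groups trip the outlier caveat warning
  expect_warning(dsc_fast(y, c("A", rep("B", 7))), "size 1")
})

test_that("DSC scales with group separation (monotone in delta)", {
  set.seed(34)
  deltas <- c(0, 0.5, 1, 2, 4)
  mean_dsc <- vapply(deltas, function(delta) {
    mean(replicate(30, {
      d <- 5
      g1 <- matrix(rnorm(20 * d), 20, d)
      g2 <- matrix(rnorm(20 * d, mean = delta / sqrt(d)), 20, d)
      dsc_fast(rbind(g1, g2), rep(c("a", "b"), each = 20))$dsc
    }))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) > 0))
})

test_that("interpretation thresholds: <0.3 low, [0.3,0.6] moderate, >0.6 strong", {
  expect_identical(interpret_dsc(0.2), "low")
  expect_identical(interpret_dsc(0.45), "moderate")
  expect_identical(interpret_dsc(0.7), "strong")
  # closed-interval boundary handling
  expect_identical(interpret_dsc(c(0, 0.3, 0.6, 0.601)),
                   c("low", "moderate", "moderate", "strong"))
  expect_error(interpret_dsc(-0.1), "non-negative")
})

test_that("permutation null on the worked example matches exhaustive enumeration", {
  # independent oracle: enumerate all 6 balanced assignments of 2+2 labels
  idx_a <- combn(4, 2)
  exhaustive <- apply(idx_a, 2, function(ia) {
    lab <- rep("B", 4); lab[ia] <- "A"
    dsc_naive(micro_data, lab)$dsc
  })
  expect_equal(sort(exhaustive), sort(c(3, 3, 1/3, 1/3, 0, 0)),
               tolerance = 1e-12)
  p_exact <- mean(exhaustive >= 3)
  expect_equal(p_exact, 1/3, tolerance = 1e-12)
  # the sampled permutation test converges to the exhaustive p-value
  pt <- permutation_test(micro_data, micro_labels, n_perm = 4000, seed = 35)
  expect_equal(pt$observed_dsc, 3)
  expect_true(all(pt$null_dsc %in% exhaustive |
                    abs(pt$null_dsc - 1/3) < 1e-12))
  expect_lt(abs(pt$p_value - p_exact), 0.03)
})

test_that("permutation test is reproducible, size-preserving, tie-inclusive", {
  set.seed(36)
  inst <- random_dsc_instance(18, 6, 3)
  p1 <- permutation_test(inst$data, inst$labels, n_perm = 50, seed = 99)
  p2 <- permutation_test(inst$data, inst$labels, n_perm = 50, seed = 99)
  expect_identical(p1$null_dsc, p2$null_dsc)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$p_value,
               sum(p1$null_dsc >= p1$observed_dsc) / 50)
  # observed DSC of 0 (identical groups): every permuted value >= 0, p = 1
  x <- matrix(c(0, 1, 0, 1), ncol = 1)
  p0 <- permutation_test(x, c("A", "A", "B", "B"), n_perm = 25, seed = 1)
  expect_equal(p0$observed_dsc, 0)
  expect_equal(p0$p_value, 1)
  # smoothing option
  ps <- permutation_test(x, c("A", "A", "B", "B"), n_perm = 25, seed = 1,
                         smooth = TRUE)
  expect_equal(ps$p_value, 1)
})

test_that("p-values under an exchangeable null are roughly uniform", {
  set.seed(37)
  pvals <- replicate(80, {
    inst <- random_dsc_instance(15, 4, 3)
    permutation_test(inst$data, inst$labels, n_perm = 60)$p_value
  })
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  # sub-uniformity at the 0.1 level, with Monte Carlo slack
  expect_lt(mean(pvals <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 80))
})

test_that("dsc_report pairs overall and PCA-space DSC consistently", {
  set.seed(38)
  # group structure living entirely in the first principal axis
  d <- 30
  shift <- c(rep(6, 1), rep(0, d - 1))
  g1 <- matrix(rnorm(15 * d), 15, d)
  g2 <- sweep(matrix(rnorm(15 * d), 15, d), 2, shift, "+")
  m <- t(rbind(g1, g2))
  dimnames(m) <- list(sprintf("f%02d", 1:d), sprintf("s%02d", 1:30))
  ann <- labels_annotation(colnames(m), rep(c("b1", "b2"), each = 15))
  pca <- compute_pca(m, 2)
  rep1 <- dsc_report(m, pca, ann, "batch", n_perm = 200, seed = 40)
  expect_identical(rep1$table$space, c("overall", "pca-2"))
  # PC1 captures the shift, so score-space DSC >= full-space DSC
  expect_gte(rep1$table$DSC[2], rep1$table$DSC[1])
  expect_lt(rep1$table$p_value[1], 0.05)
  # determinism with a shared seed
  rep2 <- dsc_report(m, pca, ann, "batch", n_perm = 200, seed = 40)
  expect_identical(rep1$table, rep2$table)
  # random labels: both spaces non-significant and near the null
  ann_null <- labels_annotation(colnames(m),
                                rep_len(c("b1", "b2", "b1", "b2"), 30))
  shuffled <- withr::with_seed(41, sample(rep(c("b1", "b2"), 15)))
  ann_null <- labels_annotation(colnames(m), shuffled)
  rep_null <- dsc_report(m, pca, ann_null, "batch", n_perm = 200, seed = 42)
  expect_true(all(rep_null$table$p_value > 0.05))
  # report writer emits a readable TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dsc_report(rep1, path)
  tab <- read.delim(path)
  expect_identical(names(tab),
                   c("variable", "space", "n_samples", "n_groups", "Db",
                     "Dw", "DSC", "p_value", "n_perm", "interpretation"))
})
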