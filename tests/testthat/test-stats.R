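test_that("K2 omnibus matches the reference implementation (frozen oracle)", {
  # expected values computed once with an independent implementation of the
  # D'Agostino-Pearson omnibus (scipy.stats.normaltest) on these exact draws
  set.seed(5); x <- round(rnorm(20, 10, 2), 6)
  nc <- normality_check(x)
  expect_equal(nc$statistic, 1.8450399310, tolerance = 1e-8)
  expect_equal(nc$p_value, 0.3975160511, tolerance = 1e-8)
  set.seed(6); y <- round(exp(rnorm(50)), 6)
  ncy <- normality_check(y)
  expect_equal(ncy$statistic, 29.9013297365, tolerance = 1e-8)
  expect_lt(ncy$p_value, 0.05)
})

test_that("small or degenerate samples are flagged, not tested", {
  nc <- normality_check(rnorm(5))
  expect_true(nc$assumed)
  expect_false(nc$normal)
  expect_true(is.na(nc$statistic))
  expect_false(normality_check(rep(3, 20))$normal)
})

test_that("normality gate is calibrated and detects log-normality", {
  set.seed(8)
  rej <- mean(replicate(2000, normality_check(rnorm(30))$p_value < 0.05))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
  hit <- mean(replicate(200, normality_check(exp(rnorm(50)))$p_value < 0.05))
  expect_gte(hit, 0.95)
})

test_that("paired comparison selects the branch from the differences", {
  set.seed(12)
  a <- rnorm(12); b <- a + rnorm(12, 0.5, 0.3)
  rep1 <- paired_compare(a, b)
  expect_identical(rep1$test_name, "paired t-test")
  # a gross outlier in the differences selects Wilcoxon
  d <- c(0.4, -0.3, 0.2, -0.5, 0.1, 0.3, -0.2, 0.5, -0.1, 0.2, -0.4, 60)
  rep2 <- paired_compare(rep(10, 12), 10 + d)
  expect_identical(rep2$test_name, "Wilcoxon signed-rank")
  # identical values: t = 0, p = 1
  rep3 <- paired_compare(1:10 + 0.5, 1:10 + 0.5)
  expect_equal(rep3$statistic, 0)
  expect_equal(rep3$p_value, 1)
  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("paired t-test has reasonable power at delta = 1 sd (n = 10)", {
  set.seed(33)
  hits <- mean(replicate(400, {
    a <- rnorm(10); b <- a + rnorm(10) + 1
    paired_compare(b, a)$p_value < 0.05
  }))
  expect_gte(hits, 0.7)
})

test_that("Wilcoxon exact p equals full sign enumeration for n <= 10", {
  set.seed(44)
  for (n in c(6, 8, 10)) {
    for (rep_i in 1:5) {
      a <- round(rnorm(n, 1, 2), 3); b <- round(rcauchy(n), 3)
      d <- a - b
      got <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = TRUE))$p.value
      expect_equal(got, wilcoxon_enum_p(d), tolerance = 1e-10)
    }
  }
})

test_that("repeated-measures branch selection and degenerate inputs", {
  df <- expand.grid(unit_id = 1:8, condition = c("control", "drug", "wash"))
  df$value <- 5
  rep0 <- repeated_compare(df)
  expect_equal(rep0$p_value, 1)
  # missing a cell is a hard error naming it
  expect_error(repeated_compare(df[-5, ]), "missing cells")
  set.seed(3)
  df$value <- rnorm(24) + rep(c(0, 1, 0), each = 8)
  r1 <- repeated_compare(df)
  expect_identical(r1$test_name, "repeated-measures ANOVA")
  expect_lt(r1$p_value, 0.05)
  expect_true(all(c("p_adj", "diff") %in% names(r1$post_hoc)))
  expect_true(r1$gg_epsilon <= 1 && r1$gg_epsilon >= 0.5)
  df$value <- exp(rcauchy(24))
  r2 <- repeated_compare(df)
  expect_identical(r2$test_name, "Friedman")
})

test_that("Friedman Q matches the direct rank-sum formula on a fixed table", {
  m <- matrix(c(5.2, 5.9, 5.1,
                6.3, 6.7, 6.1,
                4.8, 5.5, 4.9,
                7.0, 7.4, 6.8,
                5.5, 6.2, 5.4,
                6.1, 6.0, 5.8), nrow = 6, byrow = TRUE,
              dimnames = list(1:6, c("control", "drug", "washout")))
  df <- data.frame(unit_id = rep(1:6, 3),
                   condition = rep(colnames(m), each = 6),
                   value = c(m))
  r <- repeated_compare(df)  # these values are wildly non-normal? force check
  got_Q <- unname(stats::friedman.test(m)$statistic)
  expect_equal(got_Q, friedman_Q_direct(m), tolerance = 1e-10)
  if (r$test_name == "Friedman") expect_equal(r$statistic, got_Q,
                                              tolerance = 1e-10)
})

test_that("unpaired branch gates on both groups", {
  set.seed(91)
  a <- rnorm(15); b <- rnorm(15, 1)
  r1 <- unpaired_compare(a, b)
  expect_identical(r1$test_name, "unpaired t-test")
  r2 <- unpaired_compare(a, exp(rnorm(30, 0, 2)))
  expect_identical(r2$test_name, "Mann-Whitney U")
})

test_that("p-values are invariant to unit relabeling and condition order", {
  set.seed(55)
  df <- expand.grid(unit_id = 1:9, condition = c("a", "b", "c"))
  df$value <- rnorm(27) + as.integer(df$condition == "b")
  p1 <- repeated_compare(df)$p_value
  perm <- sample(9)
  df2 <- df; df2$unit_id <- perm[df$unit_id]
  expect_equal(repeated_compare(df2)$p_value, p1, tolerance = 1e-9)
  df3 <- df[order(df$condition, decreasing = TRUE), ]
  expect_equal(repeated_compare(df3)$p_value, p1, tolerance = 1e-9)
})

test_that("null repeated-measures type-I error is near alpha (scaled run)", {
  set.seed(77)
  rej <- mean(replicate(500, {
    df <- expand.grid(unit_id = 1:14, condition = c("c", "d", "w"))
    df$value <- rnorm(42)
    repeated_compare(df)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
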