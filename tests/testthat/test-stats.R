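test_that("pearson matches hand computation and flags exact linearity", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$p_value, 0)
  res <- pearson(c(1, 2, 3), c(6, 4, 5))
  expect_equal(res$r, -0.5, tolerance = 1e-12)
  expect_equal(res$n, 3)
  expect_false(res$significant)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:3), "equal length")
})

test_that("pearson is symmetric and affine-invariant, matching the naive form", {
  withr::with_seed(14, {
    for (rep in 1:50) {
      n <- sample(4:30, 1)
      x <- rnorm(n); y <- rnorm(n)
      a <- pearson(x, y)
      naive <- naive_pearson(x, y)
      expect_equal(a$r, naive$r, tolerance = 1e-9)
      expect_equal(a$t_stat, naive$t, tolerance = 1e-9)
      expect_equal(a$p_value, naive$p, tolerance = 1e-9)
      expect_equal(pearson(y, x)$r, a$r, tolerance = 1e-12)
      expect_equal(pearson(2 + 3 * x, y)$r, a$r, tolerance = 1e-9)
      expect_equal(pearson(x, 10 * y - 1)$r, a$r, tolerance = 1e-9)
    }
  })
})

test_that("one-way ANOVA matches the hand decomposition", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  expect_equal(a$stars, "*")          # p ~ 0.0213

  same <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$stars, "")

  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(one_way_anova(list(a = c(2, 2), b = c(2, 2))), "identical")
})

test_that("ANOVA agrees with the naive formulas and with t-squared", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      k <- sample(2:4, 1)
      g <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = i))
      a <- one_way_anova(g)
      naive <- naive_anova(g)
      expect_equal(a$F, naive$F, tolerance = 1e-9)
      expect_equal(a$p_value, naive$p, tolerance = 1e-9)
      if (k == 2) {
        t2 <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)$statistic^2
        expect_equal(a$F, unname(t2), tolerance = 1e-9)
      }
    }
  })
})

test_that("stars are a pure strict-threshold function of p", {
  expect_equal(p_stars(c(0.05, 0.049, 0.01, 0.0099, 0.001, 0.0009, 0.5)),
               c("", "*", "*", "**", "**", "***", ""))
})

test_that("mean_sem summarizes replicates", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(mean_sem(c(5, 5, 5))$sem, 0)
  ms2 <- mean_sem(c(0, 0, 0, 4))
  expect_equal(ms2$mean, 1)
  expect_equal(ms2$sem, 1)
  expect_error(mean_sem(3), "at least 2")
})

test_that("correlation panels share sample labels and reduce to pearson", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("LTR", paste0("s", 1:6)))
  y <- matrix(c(2, 4, 5, 8, 10, 13), 1,
              dimnames = list("gene", paste0("s", 1:6)))
  panel <- correlation_panel(x, y)
  expect_equal(nrow(panel), 1L)
  ref <- pearson(x[1, ], y[1, ])
  expect_equal(panel$r, ref$r)
  expect_equal(panel$p_value, ref$p_value)

  colnames(y) <- paste0("t", 1:6)
  expect_error(correlation_panel(x, y), "sample-label mismatch")
  colnames(y) <- paste0("s", 1:6)
  expect_error(correlation_panel(x, y,
                                 pairs = data.frame(x = "LTR", y = "nope")),
               "not found")
})

test_that("a programmed near-perfect correlation is detected", {
  withr::with_seed(2, {
    te <- matrix(c(5, 1, 3, 3.5, 3.2, 3), 1,
                 dimnames = list("LTR", paste0("s", 1:6)))
    gene <- te + rnorm(6, sd = 0.01)   # programmed rho ~ 0.99+
    rownames(gene) <- "trim33"
  })
  panel <- correlation_panel(te, gene)
  expect_true(panel$significant)
  expect_gt(panel$r, 0.99)
})

test_that("the random-gene null control is seeded and calibrated", {
  withr::with_seed(5, {
    te <- matrix(rnorm(12), 2,
                 dimnames = list(c("LTR", "LINE"), paste0("s", 1:6)))
    genes <- matrix(rnorm(6 * 500), 500,
                    dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  })
  a <- null_correlation_control(te, genes, n_random = 50, seed = 123)
  b <- null_correlation_control(te, genes, n_random = 50, seed = 123)
  expect_identical(a$summary, b$summary)
  c2 <- null_correlation_control(te, genes, n_random = 50, seed = 124)
  expect_false(identical(a$summary$mean_r, c2$summary$mean_r))

  expect_error(null_correlation_control(te, genes, n_random = 0), "positive")
  expect_error(null_correlation_control(te, genes, n_random = 501),
               "insufficient")
  # target-set exclusion shrinks the pool
  expect_error(
    null_correlation_control(te, genes, n_random = 500,
                             exclude = "g1"), "insufficient")
})
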