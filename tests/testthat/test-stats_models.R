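toy_2x2 <- function() {
  # n = 3 per cell, integer responses, unbalanced-free reference design
  data.frame(
    treatment = rep(rep(c("T", "T+E2"), each = 3), 2),
    sex = rep(c("male", "female"), each = 6),
    y = c(5, 6, 7, 4, 6, 8, 2, 3, 4, 5, 5, 8))
}

test_that("two-way ANOVA matches an explicit Type III model-comparison oracle", {
  d <- toy_2x2()
  a <- two_way_anova(d, "y")
  oracle <- type3_oracle(d$y, d$treatment, d$sex)
  expect_equal(a$F, unname(oracle$F[c("A", "B", "A:B")]), tolerance = 1e-10)
  expect_equal(a$partial_eta_sq,
               unname(oracle$partial_eta_sq[c("A", "B", "A:B")]),
               tolerance = 1e-10)
  expect_equal(a$df_residual, rep(oracle$df_res, 3))
  # and on an unbalanced version of the same data
  du <- d[-c(1, 2, 7), ]
  au <- two_way_anova(du, "y")
  ou <- type3_oracle(du$y, du$treatment, du$sex)
  expect_equal(au$F, unname(ou$F[c("A", "B", "A:B")]), tolerance = 1e-10)
})

test_that("equal cell means give F = 0 for every term", {
  d <- expand.grid(treatment = c("T", "T+E2"), sex = c("male", "female"),
                   rep = 1:3)
  d$y <- 10 + rep(c(-1, 0, 1), each = 4)  # identical pattern in each cell
  a <- two_way_anova(d, "y")
  expect_equal(a$F, rep(0, 3), tolerance = 1e-12)
})

test_that("partial eta-squared is SS / (SS + SS_res) and 0.5 at equality", {
  d <- toy_2x2()
  oracle <- type3_oracle(d$y, d$treatment, d$sex)
  a <- two_way_anova(d, "y")
  expect_equal(a$partial_eta_sq,
               unname(oracle$ss[c("A", "B", "A:B")] /
                        (oracle$ss[c("A", "B", "A:B")] + oracle$rss)))
  # constructed case: sex half-effect a = within-cell deviation e makes
  # SS_sex = SS_res = 8, hence partial eta^2 exactly 0.5
  d2 <- data.frame(
    treatment = rep(c("T", "T+E2"), each = 2, times = 2),
    sex = rep(c("male", "female"), each = 4),
    y = c(2, 0, 2, 0, 0, -2, 0, -2))
  a2 <- two_way_anova(d2, "y")
  expect_equal(a2$partial_eta_sq[a2$term == "sex"], 0.5, tolerance = 1e-12)
})

test_that("partial eta-squared is invariant to affine rescaling of the response", {
  d <- toy_2x2()[-c(2, 5), ]           # make it unbalanced
  a1 <- two_way_anova(d, "y")
  d$y2 <- 100 * d$y - 42
  a2 <- two_way_anova(d, "y2")
  expect_equal(a1$partial_eta_sq, a2$partial_eta_sq, tolerance = 1e-10)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
})

test_that("balanced designs: Type III totals equal the sequential decomposition", {
  set.seed(61)
  d <- expand.grid(treatment = c("T", "T+E2"), sex = c("male", "female"),
                   rep = 1:5)
  d$y <- rnorm(nrow(d), mean = 2 * (d$sex == "male") + (d$treatment == "T"))
  a3 <- two_way_anova(d, "y")
  seq_tab <- anova(lm(y ~ treatment * sex, data = d))
  expect_equal(a3$F, seq_tab$`F value`[1:3], tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are signalled", {
  d <- toy_2x2()
  expect_error(two_way_anova(d[d$sex == "male" | d$treatment == "T", ], "y"),
               "empty design cell")
  d$z <- 5
  expect_warning(a <- two_way_anova(d, "z"), "constant response")
  expect_true(all(is.na(a$F)))
  # rows with missing response are dropped, shrinking the residual df
  d$y[1:2] <- NA
  a <- two_way_anova(d, "y")
  expect_equal(unique(a$df_residual), nrow(d) - 2 - 4)
})

test_that("Pearson correlation reproduces hand-computed values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1.0)
  expect_equal(pearson_correlation(x, -x), -1.0)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(x, rep(2, 4)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("PCA of two standardized variables has eigenvalues 1 +/- r", {
  set.seed(67)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40, sd = 0.8)
  r <- abs(cor(x, y))
  p <- pca_unrotated(data.frame(x, y))
  expect_equal(p$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(p$proportion_explained, c(1 + r, 1 - r) / 2, tolerance = 1e-10)
})

test_that("exactly uncorrelated variables share variance equally", {
  # Helmert contrast columns are zero-mean and mutually orthogonal, so their
  # sample correlations vanish identically.
  X <- stats::contr.helmert(13)[, 1:4]
  colnames(X) <- paste0("v", 1:4)
  p <- pca_unrotated(as.data.frame(X))
  expect_equal(p$proportion_explained, rep(0.25, 4), tolerance = 1e-10)
})

test_that("PCA eigenvalues sum to the variable count; scores are uncorrelated", {
  set.seed(73)
  X <- as.data.frame(matrix(rnorm(30 * 6), 30, 6) %*% matrix(runif(36), 6, 6))
  p <- pca_unrotated(X)
  expect_equal(sum(p$eigenvalues), ncol(X), tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$proportion_explained), 1, tolerance = 1e-12)
  sc <- cor(p$scores)
  expect_lt(max(abs(sc[upper.tri(sc)])), 1e-10)
  expect_equal(unname(apply(p$scores, 2, var)), unname(p$eigenvalues),
               tolerance = 1e-10)
  # sign convention: each component's dominant loading is positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("PCA rejects constant variables and logs dropped rows", {
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = 1)
  expect_error(pca_unrotated(X), "constant variable.*c")
  X2 <- data.frame(a = rnorm(10), b = rnorm(10))
  rownames(X2) <- paste0("r", 1:10)
  X2$a[3] <- NA
  p <- pca_unrotated(X2)
  expect_equal(p$dropped_rows, "r3")
  expect_equal(nrow(p$scores), 9)
})

test_that("OLS regression matches the normal-equations solution on a toy design", {
  d <- data.frame(y = c(3, 5, 4, 8, 9, 12),
                  x1 = c(1, 2, 2, 4, 5, 6),
                  x2 = c(0, 1, 0, 1, 0, 1))
  r <- ols_regression(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  est <- r$coefficients$estimate[match(c("(Intercept)", "x1", "x2"),
                                       r$coefficients$term)]
  expect_equal(est, as.numeric(beta), tolerance = 1e-10)
  resid <- d$y - X %*% beta
  expect_equal(r$r_squared,
               1 - sum(resid^2) / sum((d$y - mean(d$y))^2), tolerance = 1e-10)
})

test_that("OLS degenerate cases behave as specified", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6), x1 = c(1, 2, 3, 4, 5, 6))
  d$x2 <- 2 * d$x1                      # collinear
  expect_error(ols_regression(d, "y", c("x1", "x2")), "collinear.*x2")
  # exact linear fit (base lm warns about the perfect fit; expected here)
  r1 <- suppressWarnings(ols_regression(d, "y", "x1"))
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  r0 <- ols_regression(d, "y", character(0))
  expect_equal(r0$coefficients$estimate[r0$coefficients$term == "(Intercept)"],
               mean(d$y))
})

test_that("anova_table stacks one row-set per metric", {
  set.seed(79)
  d <- data.frame(treatment = rep(c("T", "T+E2"), 10),
                  sex = rep(c("male", "female"), each = 10),
                  m1 = rnorm(20), m2 = rnorm(20))
  tab <- anova_table(d, metrics = c("m1", "m2"))
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$metric), c("m1", "m2"))
  expect_setequal(unique(tab$term), c("treatment", "sex", "treatment:sex"))
})
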