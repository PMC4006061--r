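test_that("Rao's F degrees of freedom match frozen hand-checked values", {
  ## four-group x two-sex design, N = 153, 20 response PCs:
  ## full-interaction residual df = 153 - 8 = 145
  expect_equal(rao_f(0.5, 20, 3, 145)$df1, 60)
  expect_equal(rao_f(0.5, 20, 3, 145)$df2, 376.7496, tolerance = 1e-6)
  expect_equal(rao_f(0.5, 20, 1, 145)$df2, 126)
  ## covariate models (no interaction): females n = 79, males n = 74,
  ## residual df = n - 5
  expect_equal(rao_f(0.5, 20, 3, 74)$df2, 164.9244, tolerance = 1e-4)
  expect_equal(rao_f(0.5, 20, 3, 69)$df2, 150.0068, tolerance = 1e-4)
  ## separate-slopes models, residual df = n - 8
  expect_equal(rao_f(0.5, 20, 3, 71)$df2, 155.9741, tolerance = 1e-4)
  expect_equal(rao_f(0.5, 20, 1, 71)$df2, 52)
  expect_equal(rao_f(0.5, 20, 3, 66)$df2, 141.0571, tolerance = 1e-4)
  expect_equal(rao_f(0.5, 20, 1, 66)$df2, 47)
  ## one-way discriminant designs, residual df = n - 4
  expect_equal(rao_f(0.5, 20, 3, 75)$df2, 167.9082, tolerance = 1e-4)
  expect_equal(round(rao_f(0.5, 20, 3, 70)$df2), 153)
  expect_error(rao_f(0.5, 20, 3, 10), "singular")
})

test_that("Rao's F reduces to the univariate F when p = 1", {
  ## for one response, F = ((1 - L)/L) * df_res / q with dfs (q, df_res)
  lam <- 0.7
  rf <- rao_f(lam, 1, 3, 40)
  expect_equal(rf$df1, 3)
  expect_equal(rf$df2, 40)
  expect_equal(rf$F, (1 - lam) / lam * 40 / 3)
})

test_that("two-way Type III ANOVA matches car::Anova on unbalanced data", {
  set.seed(51)
  n <- c(12, 9, 14, 7, 11, 13, 8, 10)
  g <- factor(rep(rep(c("a", "b", "c", "d"), 2), n))
  s <- factor(rep(c("F", "M"), c(sum(n[1:4]), sum(n[5:8]))))
  y <- rnorm(sum(n)) + as.integer(g) * 0.5 + (s == "M") * 0.8
  tab <- two_way_anova(y, g, s, include_interaction = TRUE)
  ref <- car::Anova(stats::lm(y ~ g * s,
                              contrasts = list(g = "contr.sum",
                                               s = "contr.sum")),
                    type = 3)
  expect_equal(tab$SS[1:3], ref[c("g", "s", "g:s"), "Sum Sq"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(tab$F[1:3], ref[c("g", "s", "g:s"), "F value"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(tab$df, c(3, 1, 3, sum(n) - 8))
})

test_that("two-way ANOVA guards its design assumptions", {
  g <- factor(c("a", "a", "b", "b"))
  s <- factor(c("F", "F", "M", "M"))   # empty a:M and b:F cells
  expect_error(two_way_anova(rnorm(4), g, s, TRUE), "empty group x sex")
  expect_error(two_way_anova(rnorm(4), factor(rep("a", 4)), s),
               "at least two levels")
})

test_that("MANOVA with one response equals the univariate ANOVA", {
  set.seed(52)
  g <- factor(rep(c("a", "b", "c", "d"), c(8, 9, 7, 10)))
  s <- factor(sample(c("F", "M"), 34, replace = TRUE))
  y <- rnorm(34)
  mv <- manova_shape(matrix(y), g, s, include_interaction = TRUE)
  uv <- two_way_anova(y, g, s, include_interaction = TRUE)
  expect_equal(mv$F, uv$F[1:3], tolerance = 1e-10)
  expect_equal(mv$df1, uv$df[1:3])
})

test_that("MANOVA Wilks' lambda matches car::Manova type III", {
  set.seed(53)
  n <- 60
  g <- factor(rep(rep(c("a", "b", "c", "d"), 2), c(9, 8, 7, 6, 8, 9, 6, 7)))
  s <- factor(rep(c("F", "M"), c(30, 30)))
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[, 1] <- Y[, 1] + as.integer(g)
  mv <- manova_shape(Y, g, s, include_interaction = TRUE)
  fit <- stats::lm(Y ~ g * s, contrasts = list(g = "contr.sum",
                                               s = "contr.sum"))
  ref <- car::Manova(fit, type = 3, test.statistic = "Wilks")
  ref_l <- vapply(c("g", "s", "g:s"), function(t) {
    H <- ref$SSP[[t]]
    det(ref$SSPE) / det(ref$SSPE + H)
  }, 0)
  expect_equal(mv$wilks_lambda, unname(ref_l), tolerance = 1e-8)
})

test_that("eta squared follows the multivariate convention", {
  ## eta^2 = 1 - lambda^(1/s), s = min(p, q)
  set.seed(54)
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  s <- factor(rep(c("F", "M"), 20))
  Y <- matrix(rnorm(40 * 5), 40, 5)
  mv <- manova_shape(Y, g, s, include_interaction = FALSE)
  expect_equal(mv$eta_squared[1], 1 - mv$wilks_lambda[1]^(1 / 3))
  expect_equal(mv$eta_squared[2], 1 - mv$wilks_lambda[2]^(1 / 1))
})

test_that("MANCOVA models produce the expected residual dfs", {
  set.seed(55)
  mk <- function(n) list(
    Y = matrix(rnorm(n * 20), n, 20),
    g = factor(sample(c("a", "b", "c", "d"), n, replace = TRUE,
                      prob = c(0.28, 0.26, 0.25, 0.21))),
    cs = rnorm(n, 18, 1))
  f <- mk(79)
  main <- mancova_shape(f$Y, f$g, f$cs, include_interaction = FALSE)
  expect_equal(main$df2[main$effect == "group"], 164.9244,
               tolerance = 1e-4)
  inter <- mancova_shape(f$Y, f$g, f$cs, include_interaction = TRUE)
  expect_equal(inter$df2[inter$effect == "group"], 155.9741,
               tolerance = 1e-4)
  expect_equal(inter$df2[inter$effect == "cs"], 52)
  m <- mk(74)
  expect_equal(mancova_shape(m$Y, m$g, m$cs)$df2[1], 150.0068,
               tolerance = 1e-4)
  expect_error(mancova_shape(f$Y, f$g, rep(1, 79)), "constant covariate")
})

test_that("Holm adjustment matches the worked stepwise example", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.02)), c(0.03, 0.04, 0.04))
  p <- runif(6)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "p_values")
})

test_that("pairwise permutation percent explained matches a hand oracle", {
  ## two groups of two scalar values: between-SS / total-SS is exact
  x <- c(0, 2, 1, 3)
  lab <- factor(c("a", "a", "b", "b"))
  pt <- pairwise_permutation_tests(x, lab, "mean_difference",
                                   n_perm = 99, seed = 1)
  gm <- mean(x)
  ssb <- 2 * (mean(x[1:2]) - gm)^2 + 2 * (mean(x[3:4]) - gm)^2
  sst <- sum((x - gm)^2)
  expect_equal(pt$percent_explained, ssb / sst * 100)  # = 20
  expect_equal(pt$statistic, 1)
})

test_that("well-separated groups reach the minimal permutation p-value", {
  set.seed(56)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1), rnorm(10, 100, 0.1))
  lab <- factor(rep(c("a", "b", "c"), each = 10))
  pt <- pairwise_permutation_tests(x, lab, "mean_difference",
                                   n_perm = 199, seed = 2)
  expect_equal(pt$p_raw, rep(1 / 200, 3))
  expect_equal(pt$p_adjusted, rep(3 / 200, 3))
  expect_true(all(pt$significant))
  ## determinism under a fixed seed
  pt2 <- pairwise_permutation_tests(x, lab, "mean_difference",
                                    n_perm = 199, seed = 2)
  expect_identical(as.data.frame(pt), as.data.frame(pt2))
  expect_error(pairwise_permutation_tests(x[1:11], factor(c(rep("a", 10),
                                                            "b")),
                                          "mean_difference", 99),
               "size < 2")
})

test_that("pairwise matrix carries percents above and p-values below", {
  set.seed(57)
  x <- rnorm(30)
  lab <- factor(rep(c("a", "b", "c"), each = 10))
  pt <- pairwise_permutation_tests(x, lab, "mean_difference", 99, seed = 3)
  m <- pairwise_matrix(pt)
  expect_equal(m["a", "b"],
               pt$percent_explained[pt$group1 == "a" & pt$group2 == "b"])
  expect_equal(m["b", "a"],
               pt$p_adjusted[pt$group1 == "a" & pt$group2 == "b"])
  expect_true(all(is.na(diag(m))))
})

test_that("allometry regression is exact for a linear relationship", {
  set.seed(58)
  cs <- rnorm(30, 18, 1)
  b <- rnorm(10)
  Y <- outer(cs, b)                      # shape exactly linear in size
  ar <- allometry_regression(Y, cs, n_perm = 199, seed = 4)
  expect_equal(ar$percent_predicted, 100, tolerance = 1e-10)
  expect_equal(ar$p_permutation, 1 / 200)
  expect_equal(ar$coefficients, b, tolerance = 1e-10)
  ## pure noise: low percent, non-significant most of the time
  ar0 <- allometry_regression(matrix(rnorm(300), 30, 10), cs,
                              n_perm = 199, seed = 5)
  expect_lt(ar0$percent_predicted, 40)
  expect_error(allometry_regression(Y, rep(18, 30)), "constant")
})

test_that("size correction removes pooled allometry, keeps group offsets", {
  set.seed(59)
  n <- 60
  grp <- factor(rep(c("a", "b"), each = n / 2))
  cs <- rnorm(n, 18, 1)
  slope <- rnorm(8, 0, 0.5)
  offset <- c(rep(0, n / 2), rep(1, n / 2))
  Y <- outer(cs, slope) + outer(offset, rnorm(8, 2, 1)) +
    matrix(rnorm(n * 8, 0, 0.01), n, 8)
  corr <- size_correct(Y, cs, grp)
  ## within-group size dependence collapses from dominant to noise level
  for (g in levels(grp)) {
    i <- grp == g
    before <- allometry_regression(Y[i, ], cs[i], n_perm = 99, seed = 6)
    after <- allometry_regression(corr[i, ], cs[i], n_perm = 99, seed = 6)
    expect_gt(before$percent_predicted, 50)
    expect_lt(after$percent_predicted, 5)
  }
  ## the group mean difference survives the correction
  d <- colMeans(corr[grp == "b", ]) - colMeans(corr[grp == "a", ])
  expect_gt(sqrt(sum(d^2)), 1)
})

test_that("LOO discriminant analysis separates well-separated groups", {
  set.seed(60)
  centers <- matrix(rnorm(4 * 5, 0, 20), 4, 5)
  lab <- factor(rep(c("a", "b", "c", "d"), each = 15))
  X <- centers[as.integer(lab), ] + matrix(rnorm(60 * 5), 60, 5)
  res <- lda_crossval(X, lab)
  expect_equal(res$accuracy_loo, 1)
  expect_equal(res$accuracy_resub, 1)
  expect_identical(sum(res$confusion_loo), 60L)
  expect_lt(res$wilks$p, 1e-10)
  expect_equal(res$wilks$df1, 15)
  expect_error(lda_crossval(matrix(rnorm(60 * 57), 60, 57), lab),
               "singular pooled covariance")
})
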