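test_that("shape PCA reproduces tangent coordinates and their variance", {
  ds <- generate_study(small_generator(6L), seed = 17L)
  fit <- gpa(ds)
  sp <- shape_pca(fit)
  ## total variance is preserved by the rotation to PCs
  tot <- sum(apply(fit$tangent, 2, stats::var))
  expect_equal(sum(sp$eigenvalues), tot, tolerance = 1e-10)
  expect_equal(sum(sp$percent_variance), 100)
  ## reconstruction from all components is exact
  rec <- sweep(sp$scores %*% t(sp$eigenvectors), 2, sp$center, `+`)
  expect_equal(unname(rec), unname(fit$tangent), tolerance = 1e-10)
  ## no more than 47 non-degenerate components
  expect_lte(sum(sp$eigenvalues > max(sp$eigenvalues) * 1e-7), 47L)
})

test_that("a single injected direction dominates PC1", {
  set.seed(31)
  t0 <- molarmorph:::preshape(template_molar())
  v <- molarmorph:::tangent_vector(matrix(rnorm(54), 18, 3), t0, 0.05)
  coords <- array(NA_real_, c(18, 3, 40))
  amp <- seq(-1, 1, length.out = 40)
  for (i in 1:40) {
    m <- matrix(as.vector(t0) + amp[i] * v, 18, 3)
    coords[, , i] <- molarmorph:::preshape(m) * 18 +
      matrix(rnorm(54, 0, 0.002), 18, 3)
  }
  fit <- gpa(coords)
  sp <- shape_pca(fit)
  expect_gt(sp$percent_variance[1], 95)
})

test_that("distance-correlation profile matches a brute-force recomputation", {
  ds <- generate_study(small_generator(3L), seed = 23L)  # n = 24
  fit <- gpa(ds)
  sp <- shape_pca(fit)
  prof <- distance_correlation_profile(fit, sp)
  d_full <- as.vector(procrustes_dist_matrix(fit))
  for (m in c(1L, 3L, ncol(sp$scores))) {
    dm <- as.vector(stats::dist(sp$scores[, seq_len(m), drop = FALSE]))
    expect_equal(prof$r_values[m], stats::cor(dm, d_full),
                 tolerance = 1e-12)
  }
  ## with all components retained the correlation is essentially 1
  ## (tangent distances differ from Procrustes distances only through
  ## the curvature of shape space)
  expect_gt(prof$r_values[length(prof$r_values)], 1 - 1e-6)
  ## and it is non-decreasing in practice for nested distance sums
  expect_gt(min(diff(prof$r_values)), -0.02)
})

test_that("dimensionality selection honors threshold and plateau rules", {
  mk <- function(r) structure(list(r_values = r),
                              class = "distance_correlation_profile")
  sel <- select_dimensionality(mk(c(0.5, 0.9, 0.985, 0.9851, 0.9852,
                                    0.9853, 0.9853, 0.9854)),
                               threshold = 0.98)
  expect_identical(sel$m, 3L)
  expect_equal(sel$r, 0.985)
  ## plateau: first index gaining < 0.005 over the next five components
  expect_identical(sel$plateau, 3L)
  ## steady 0.005-per-step gains never plateau before the last component
  expect_identical(select_dimensionality(
    mk(c(0.5, 0.9, 0.985, 0.99, 0.995, 1)))$plateau, 6L)
  ## already above threshold at the first component
  expect_identical(select_dimensionality(mk(c(0.99, 0.995, 1)))$m, 1L)
  ## threshold never reached
  expect_error(select_dimensionality(mk(c(0.1, 0.2, 0.3))),
               "no component count reaches")
})

test_that("group mean shapes average the aligned configurations", {
  ds <- generate_study(small_generator(4L), seed = 29L)
  fit <- gpa(ds)
  g <- ds$records$group
  means <- group_mean_shapes(fit, g)
  expect_identical(dim(means), c(18L, 3L, 4L))
  i <- which(g == "severe")
  expect_equal(means[, , "severe"],
               apply(fit$aligned[, , i], c(1, 2), mean),
               ignore_attr = TRUE)
  expect_error(group_mean_shapes(fit, factor(g, levels = c(unique(g),
                                                           "ghost"))),
               "empty group")
  expect_error(group_mean_shapes(fit, g[-1]), "one label per specimen")
})

test_that("mean-shape PCA has at most g - 1 informative components", {
  ds <- generate_study(small_generator(5L), seed = 37L)
  fit <- gpa(ds)
  means <- group_mean_shapes(fit, ds$records$group)
  mp <- mean_shape_pca(means)
  ev <- mp$eigenvalues
  expect_lte(sum(ev > max(ev) * 1e-9), 3L)
  expect_error(mean_shape_pca(means[, , 1:2]), "at least 3")
})

test_that("TPS interpolates landmarks exactly and is affine-exact", {
  set.seed(41)
  ref <- template_molar()
  tgt <- ref + matrix(rnorm(54, 0, 0.4), 18, 3)
  w <- tps_warp(ref, tgt, grid_spec = NULL)
  expect_equal(tps_evaluate(w, ref), tgt, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_gte(w$bending_energy, 0)
  ## an affine target has zero bending energy and zero kernel weights
  Aff <- matrix(c(1.1, 0.05, 0, -0.02, 0.95, 0.01, 0, 0.03, 1.05), 3, 3)
  wa <- tps_warp(ref, ref %*% Aff + 2, grid_spec = NULL)
  expect_equal(wa$bending_energy, 0, tolerance = 1e-8)
  expect_lt(max(abs(wa$weights)), 1e-8)
  ## identity warp maps arbitrary points to themselves
  wi <- tps_warp(ref, ref, grid_spec = NULL)
  pts <- matrix(rnorm(30, 0, 5), 10, 3)
  expect_equal(tps_evaluate(wi, pts), pts, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("TPS solution satisfies the interpolation linear system", {
  set.seed(43)
  ref <- template_molar()
  tgt <- ref + matrix(rnorm(54, 0, 0.3), 18, 3)
  w <- tps_warp(ref, tgt, grid_spec = NULL)
  ## independent residual check: K W + P A = target, P' W = 0
  K <- as.matrix(stats::dist(ref))
  P <- cbind(1, ref)
  expect_equal(K %*% w$weights + P %*% t(w$affine), tgt,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(crossprod(P, w$weights), matrix(0, 4, 3),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("TPS grid covers three planes and rejects coplanar references", {
  ref <- template_molar()
  w <- tps_warp(ref, ref + 0.1, grid_spec = list(n = 5L, margin = 0.1))
  expect_named(w$grid, c("plane_x", "plane_y", "plane_z"))
  expect_identical(nrow(w$grid$plane_z$points), 36L)
  flat <- ref; flat[, 3] <- 0
  expect_error(tps_warp(flat, ref), "coplanar")
})
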