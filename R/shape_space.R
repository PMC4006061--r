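#' Principal component analysis of shape
#'
#' Covariance-based eigendecomposition of the tangent-space coordinates of
#' a Procrustes fit. Scores are centered; reconstruction from all
#' components reproduces the tangent coordinates exactly.
#'
#' @param fit a \code{procrustes_fit} with at least 3 specimens.
#' @return An object of class \code{shape_space} with elements
#'   \code{eigenvectors} (3k x d loadings), \code{eigenvalues} (descending
#'   variances), \code{scores} (n x d), \code{percent_variance} and
#'   \code{center}.
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  n <- nrow(fit$tangent)
  if (n < 3L) stop("shape PCA requires at least 3 specimens")
  pr <- stats::prcomp(fit$tangent, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  structure(list(eigenvectors = pr$rotation, eigenvalues = ev,
                 scores = pr$x,
                 percent_variance = ev / sum(ev) * 100,
                 center = pr$center,
                 consensus = fit$consensus, schema = fit$schema),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  nz <- sum(x$eigenvalues > max(x$eigenvalues) * 1e-7)
  cat("shape_space:", nrow(x$scores), "specimens,", nz,
      "non-degenerate components; PC1-PC2 explain",
      sprintf("%.1f%% + %.1f%%\n", x$percent_variance[1L],
              x$percent_variance[2L]))
  invisible(x)
}

#' Distance-correlation profile over retained components
#'
#' For every m from 1 to the number of components, the Pearson correlation
#' between inter-specimen Euclidean distances computed from the first m
#' PC scores and the full Procrustes shape distances. The profile is the
#' basis of the dimensionality-selection rule.
#'
#' @param fit a \code{procrustes_fit}.
#' @param space the \code{shape_space} from \code{\link{shape_pca}(fit)}.
#' @return An object of class \code{distance_correlation_profile} holding
#'   \code{r_values}.
#' @export
distance_correlation_profile <- function(fit, space) {
  stopifnot(inherits(fit, "procrustes_fit"), inherits(space, "shape_space"))
  n <- nrow(space$scores)
  if (n < 3L) stop("at least 3 specimens required for distance pairs")
  d_full <- as.vector(procrustes_dist_matrix(fit))
  d <- ncol(space$scores)
  D2 <- numeric(length(d_full))
  r <- numeric(d)
  for (m in seq_len(d)) {
    D2 <- D2 + as.vector(stats::dist(space$scores[, m]))^2
    r[m] <- stats::cor(sqrt(D2), d_full)
  }
  structure(list(r_values = r), class = "distance_correlation_profile")
}

#' Select shape-space dimensionality
#'
#' Smallest number of principal components m whose Euclidean
#' inter-specimen distances correlate with the full Procrustes distances
#' at r >= \code{threshold}. A plateau diagnostic is reported alongside:
#' the first m after which the correlation gains less than 0.005 over the
#' next five components.
#'
#' @param profile a \code{distance_correlation_profile}.
#' @param threshold correlation threshold (default 0.98).
#' @return A list with \code{m} (selected dimension), \code{r} (its
#'   correlation), \code{plateau} and \code{threshold}.
#' @export
select_dimensionality <- function(profile, threshold = 0.98) {
  stopifnot(inherits(profile, "distance_correlation_profile"))
  r <- profile$r_values
  hit <- which(r >= threshold)
  if (length(hit) == 0L)
    stop("no component count reaches r = ", threshold,
         "; use the full dimension (max r = ", sprintf("%.4f", max(r)), ")")
  m <- hit[1L]
  d <- length(r)
  plateau <- d
  for (i in seq_len(d)) {
    if (i == d) { plateau <- i; break }
    win <- r[(i + 1L):min(i + 5L, d)]
    if (max(win) - r[i] < 0.005) { plateau <- i; break }
  }
  list(m = m, r = r[m], plateau = plateau, threshold = threshold)
}

#' Group mean shapes
#'
#' Arithmetic mean of the aligned Procrustes coordinates within each
#' group.
#'
#' @param fit a \code{procrustes_fit}.
#' @param labels a grouping vector/factor, one entry per specimen.
#' @return A k x 3 x g array of mean configurations, one slice per group.
#' @export
group_mean_shapes <- function(fit, labels) {
  stopifnot(inherits(fit, "procrustes_fit"))
  labels <- as.factor(labels)
  if (length(labels) != dim(fit$aligned)[3L])
    stop("one label per specimen required")
  if (any(table(labels) == 0L))
    stop("empty group(s): ",
         paste(levels(labels)[table(labels) == 0L], collapse = ", "))
  k <- dim(fit$aligned)[1L]
  g <- nlevels(labels)
  out <- array(NA_real_, c(k, 3L, g),
               dimnames = list(dimnames(fit$aligned)[[1L]],
                               c("x", "y", "z"), levels(labels)))
  for (lv in levels(labels))
    out[, , lv] <- apply(fit$aligned[, , labels == lv, drop = FALSE],
                         c(1L, 2L), mean)
  out
}

#' PCA of group mean shapes
#'
#' Eigendecomposition of the (small) matrix of vectorized group mean
#' shapes, summarizing similarity relationships among groups; at most
#' (groups - 1) components carry variance.
#'
#' @param means a k x 3 x g array of mean shapes (g >= 3).
#' @return A \code{shape_space} over groups.
#' @export
mean_shape_pca <- function(means) {
  g <- dim(means)[3L]
  if (is.na(g) || g < 3L) stop("at least 3 group means required")
  M <- t(apply(means, 3L, as.vector))
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  structure(list(eigenvectors = pr$rotation, eigenvalues = ev,
                 scores = pr$x,
                 percent_variance = ev / sum(ev) * 100,
                 center = pr$center, consensus = NULL, schema = NULL),
            class = "shape_space")
}

#' Thin-plate-spline warp between two 3D configurations
#'
#' Interpolating deformation mapping the reference landmarks exactly onto
#' the target landmarks, using the 3D biharmonic kernel U(r) = r. The
#' warp decomposes into an affine part and kernel (non-affine) weights;
#' the bending energy is zero iff the target is an affine image of the
#' reference. A sectioned grid (three axis-aligned planes through the
#' reference centroid) is warped for visualization.
#'
#' @param reference,target k x 3 coordinate matrices over the same
#'   landmarks; the reference must not be coplanar.
#' @param grid_spec list with \code{n} (cells per side, default 20) and
#'   \code{margin} (bounding-box margin fraction, default 0.1); NULL
#'   skips grid construction.
#' @return An object of class \code{tps_warp} with the affine part
#'   (3 x 4), kernel \code{weights} (k x 3), \code{bending_energy} and
#'   \code{grid} (per-plane original and warped lattice points).
#' @export
tps_warp <- function(reference, target,
                     grid_spec = list(n = 20L, margin = 0.1)) {
  reference <- as.matrix(reference)
  target <- as.matrix(target)
  k <- nrow(reference)
  stopifnot(nrow(target) == k, ncol(reference) == 3L, ncol(target) == 3L)
  if (qr(center_config(reference))$rank < 3L)
    stop("reference landmarks are coplanar; 3D TPS is undefined")
  K <- as.matrix(stats::dist(reference))
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Y <- rbind(target, matrix(0, 4L, 3L))
  sol <- tryCatch({
    s0 <- solve(L, Y)
    s0 + solve(L, Y - L %*% s0)     # one step of iterative refinement
  }, error = function(e)
    stop("singular TPS system (coincident reference ",
         "landmarks?): ", conditionMessage(e)))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:4, , drop = FALSE]       # 4 x 3: intercept + linear map
  be <- max(0, -sum(W * (K %*% W)))
  warp <- structure(list(reference = reference, target = target,
                         affine = t(A), weights = W, bending_energy = be,
                         grid = NULL),
                    class = "tps_warp")
  if (!is.null(grid_spec)) warp$grid <- tps_grid(warp, grid_spec)
  warp
}

#' Evaluate a TPS warp at arbitrary points
#'
#' @param warp a \code{tps_warp}.
#' @param points an m x 3 matrix of 3D points.
#' @return The warped m x 3 points.
#' @export
tps_evaluate <- function(warp, points) {
  points <- matrix(points, ncol = 3L)
  ref <- warp$reference
  U <- vapply(seq_len(nrow(ref)), function(j)
    sqrt((points[, 1L] - ref[j, 1L])^2 + (points[, 2L] - ref[j, 2L])^2 +
         (points[, 3L] - ref[j, 3L])^2), numeric(nrow(points)))
  U <- matrix(U, nrow = nrow(points))
  cbind(1, points) %*% t(warp$affine) + U %*% warp$weights
}

## three axis-aligned lattice planes through the reference centroid
tps_grid <- function(warp, grid_spec) {
  n <- if (is.null(grid_spec$n)) 20L else as.integer(grid_spec$n)
  margin <- if (is.null(grid_spec$margin)) 0.1 else grid_spec$margin
  ref <- warp$reference
  ctr <- colMeans(ref)
  rng <- apply(ref, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  lo <- rng[1L, ] - margin * span
  hi <- rng[2L, ] + margin * span
  planes <- list()
  for (fixed in 1:3) {
    free <- setdiff(1:3, fixed)
    u <- seq(lo[free[1L]], hi[free[1L]], length.out = n + 1L)
    v <- seq(lo[free[2L]], hi[free[2L]], length.out = n + 1L)
    pts <- matrix(ctr[fixed], (n + 1L)^2, 3L)
    uv <- expand.grid(u = u, v = v)
    pts[, free[1L]] <- uv$u
    pts[, free[2L]] <- uv$v
    planes[[paste0("plane_", c("x", "y", "z")[fixed])]] <-
      list(fixed_axis = fixed, n = n, points = pts,
           warped = tps_evaluate(warp, pts))
  }
  planes
}

#' @export
print.tps_warp <- function(x, ...) {
  cat("tps_warp:", nrow(x$reference), "landmarks; bending energy",
      format(x$bending_energy, digits = 4), "\n")
  invisible(x)
}

#' Plot a warped TPS grid section
#'
#' Draws the deformation of one grid plane (projected onto its two free
#' axes) together with the reference and target landmarks.
#'
#' @param x a \code{tps_warp} with a grid.
#' @param plane index or name of the grid plane to draw.
#' @param ... passed to \code{plot}.
#' @export
plot.tps_warp <- function(x, plane = 3L, ...) {
  if (is.null(x$grid)) stop("warp carries no grid")
  pl <- x$grid[[plane]]
  free <- setdiff(1:3, pl$fixed_axis)
  w <- pl$warped[, free, drop = FALSE]
  n1 <- pl$n + 1L
  graphics::plot(w, type = "n", asp = 1,
                 xlab = c("x", "y", "z")[free[1L]],
                 ylab = c("x", "y", "z")[free[2L]], ...)
  for (i in seq_len(n1)) {
    graphics::lines(w[seq(i, n1^2, by = n1), ], col = "grey50")
    graphics::lines(w[seq((i - 1L) * n1 + 1L, i * n1), ], col = "grey50")
  }
  graphics::points(x$reference[, free], pch = 1, col = "steelblue")
  graphics::points(x$target[, free], pch = 16, col = "firebrick")
  invisible(x)
}
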