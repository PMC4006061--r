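#' Centroid size
#'
#' The square root of the summed squared distances from each landmark to
#' the configuration centroid, in the units of the input coordinates (mm).
#'
#' @param config a k x 3 coordinate matrix.
#' @return A positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (cs <= .Machine$double.eps * max(1, sum(abs(config))))
    stop("degenerate configuration: all landmarks coincident")
  cs
}

center_config <- function(config) {
  sweep(config, 2L, colMeans(config))
}

## center and scale one configuration to unit centroid size
preshape <- function(config) {
  x <- center_config(as.matrix(config))
  cs <- sqrt(sum(x^2))
  if (cs <= .Machine$double.eps * max(1, sum(abs(config))))
    stop("degenerate configuration: all landmarks coincident")
  x / cs
}

#' Optimal rotation between two centered configurations
#'
#' Returns the proper rotation R (3 x 3, det = +1) minimizing
#' ||A - B R||^2 in the Frobenius norm. Reflections are forbidden: the
#' determinant is forced positive by flipping the singular direction of
#' smallest singular value, a deterministic tie-break.
#'
#' @param A,B centered k x 3 coordinate matrices with equal k.
#' @return A 3 x 3 rotation matrix; attribute \code{ambiguous} is TRUE
#'   when the cross-covariance is rank-deficient enough to leave the
#'   optimum non-unique.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  M <- crossprod(B, A)
  sv <- svd(M)
  s <- c(1, 1, sign(det(sv$u %*% t(sv$v))))
  if (s[3L] == 0) s[3L] <- 1
  R <- sv$u %*% (s * t(sv$v))
  ## optimum is non-unique when the two smallest singular values vanish
  tol <- max(sv$d) * 1e-12
  attr(R, "ambiguous") <- (sv$d[2L] + sv$d[3L]) <= tol
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition of all configurations:
#' translation to a common origin, scaling to unit centroid size, and
#' rotation to the running consensus until the consensus stabilizes
#' (root-mean-square change < \code{tol}). The final fit is rotated to the
#' principal axes of the consensus under a deterministic sign convention,
#' so the result does not depend on the original orientation of any input.
#'
#' @param dataset a \code{study_dataset} or a k x 3 x n coordinate array.
#' @param tol consensus convergence tolerance (RMS coordinate change).
#' @param max_iter maximum number of iterations.
#' @return An object of class \code{procrustes_fit} with elements
#'   \code{aligned} (k x 3 x n, unit centroid size), \code{consensus}
#'   (k x 3, unit centroid size), \code{centroid_sizes} (mm),
#'   \code{tangent} (n x 3k tangent-space coordinates), \code{iterations},
#'   \code{converged} and \code{rss} (per-iteration residual sum of
#'   squares, non-increasing).
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  coords <- if (inherits(dataset, "study_dataset")) dataset$coords
            else as_coord_array(dataset)
  n <- dim(coords)[3L]
  k <- dim(coords)[1L]
  if (n < 2L) stop("GPA requires at least 2 specimens")
  cs <- vapply(seq_len(n), function(i) centroid_size(coords[, , i]), 0)
  X <- array(0, dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) X[, , i] <- preshape(coords[, , i])
  ## initial reference: first specimen
  consensus <- X[, , 1L]
  rss <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*%
        optimal_rotation(consensus, X[, , i])
    new_cons <- preshape(apply(X, c(1L, 2L), mean))
    rss <- c(rss, sum(sweep(X, c(1L, 2L), new_cons)^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (it > 1L && delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  ## canonical orientation: principal axes of the consensus
  V <- principal_axes(consensus)
  consensus <- consensus %*% V
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% V
  fit <- structure(list(aligned = X, consensus = consensus,
                        centroid_sizes = cs, iterations = it,
                        converged = converged, rss = rss,
                        specimen_ids = dimnames(coords)[[3L]],
                        schema = if (inherits(dataset, "study_dataset"))
                          dataset$schema else NULL),
                   class = "procrustes_fit")
  fit$tangent <- tangent_coordinates(fit)
  fit
}

## deterministic principal-axis basis: eigenvectors of t(C) %*% C with
## each column's sign fixed on the ROTATED consensus coordinates (the
## largest-magnitude coordinate along each axis made positive) -- a
## convention invariant to the input orientation -- and det forced +1 so
## shapes are never reflected
principal_axes <- function(C) {
  V <- eigen(crossprod(C), symmetric = TRUE)$vectors
  S <- C %*% V
  for (j in 1:3) {
    i <- which.max(abs(S[, j]))
    if (S[i, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  V
}

#' @export
print.procrustes_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat("procrustes_fit:", d[3L], "specimens,", d[1L], "landmarks;",
      x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

vec_config <- function(m) as.vector(m)

#' Tangent-space coordinates
#'
#' Orthogonal projection of the aligned configurations onto the tangent
#' space of shape space at the consensus: each vectorized configuration
#' has its component along the (unit-norm) consensus vector removed.
#' Euclidean distances between rows approximate Procrustes distances for
#' small shape variation.
#'
#' @param fit a \code{procrustes_fit}.
#' @return An n x 3k matrix of tangent coordinates (centered at the
#'   consensus projection).
#' @export
tangent_coordinates <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  n <- dim(fit$aligned)[3L]
  X <- t(vapply(seq_len(n), function(i) vec_config(fit$aligned[, , i]),
                numeric(length(fit$consensus))))
  cvec <- vec_config(fit$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  proj <- X - (X %*% cvec) %*% t(cvec)
  sweep(proj, 2L, colMeans(proj))
}

#' Procrustes distance between two configurations
#'
#' Distance between two optimally superimposed unit-centroid-size
#' configurations: both are centered, scaled to unit centroid size and
#' rotated into optimal alignment, and the root summed squared
#' coordinate difference is returned. Zero iff the shapes are identical
#' up to a similarity transform.
#'
#' @param a,b k x 3 coordinate matrices over the same landmarks.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  A <- preshape(a)
  B <- preshape(b)
  R <- optimal_rotation(A, B)
  sqrt(sum((A - B %*% R)^2))
}

#' All pairwise Procrustes distances
#'
#' @param fit a \code{procrustes_fit} (or k x 3 x n array of shapes).
#' @return A \code{dist} object of full Procrustes shape distances.
#' @export
procrustes_dist_matrix <- function(fit) {
  coords <- if (inherits(fit, "procrustes_fit")) fit$aligned else fit
  n <- dim(coords)[3L]
  d <- numeric(n * (n - 1L) / 2L)
  idx <- 1L
  for (i in seq_len(n - 1L)) {
    A <- coords[, , i]
    for (j in (i + 1L):n) {
      d[idx] <- procrustes_distance(A, coords[, , j])
      idx <- idx + 1L
    }
  }
  structure(d, Size = n, Diag = FALSE, Upper = FALSE, method = "procrustes",
            class = "dist")
}

#' Count shape dimensions carrying variance
#'
#' Number of eigenvalues of the tangent-coordinate covariance exceeding a
#' relative tolerance. For k 3D landmarks and enough specimens this is
#' 3k - 7: superimposition removes three translations, three rotations
#' and one scale.
#'
#' @param fit a \code{procrustes_fit}.
#' @param tol relative eigenvalue tolerance (fraction of the largest).
#' @return Integer count of non-degenerate dimensions.
#' @export
shape_rank <- function(fit, tol = 1e-7) {
  ev <- eigen(stats::cov(fit$tangent), symmetric = TRUE,
              only.values = TRUE)$values
  sum(ev > max(ev) * tol)
}
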