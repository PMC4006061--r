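## shared fixtures and independent oracles, all built in code

## two fixed, clearly non-similar tetrahedra
tetra_a <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0, 0, 1))
tetra_b <- function() rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(-0.1, 0.8, 0.2),
                            c(0.2, 0.1, 1.1))

## random proper rotation built from a quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

## apply a random similarity transform (rotation, translation, scale > 0)
random_similarity <- function(config) {
  config %*% random_rotation() * runif(1, 0.3, 3) +
    matrix(rnorm(3, 0, 20), nrow(config), 3, byrow = TRUE)
}

## brute-force rotation search oracle: minimizes ||A - B R||^2 over
## sampled quaternion rotations (optionally refined by shrinking local
## resampling around the incumbent); independent of the SVD solution
grid_rotation_residual <- function(A, B, n = 1e5, refine_rounds = 0) {
  M <- crossprod(B, A)
  mvec <- as.vector(M)
  sA <- sum(A^2); sB <- sum(B^2)
  score <- function(Q) {
    Q <- Q / sqrt(rowSums(Q^2))
    a <- Q[, 1]; b <- Q[, 2]; c <- Q[, 3]; d <- Q[, 4]
    cbind(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
          2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
          2 * (b * d + a * c), 2 * (c * d - a * b),
          a^2 - b^2 - c^2 + d^2) %*% mvec
  }
  Q <- matrix(rnorm(4 * n), ncol = 4)
  s <- score(Q)
  best <- which.max(s)
  best_q <- Q[best, ] / sqrt(sum(Q[best, ]^2))
  best_s <- s[best]
  spread <- 0.05
  for (r in seq_len(refine_rounds)) {
    Qr <- matrix(rnorm(4 * n / 10, 0, spread), ncol = 4)
    Qr <- sweep(Qr, 2, best_q, `+`)
    s <- score(Qr)
    if (max(s) > best_s) {
      best <- which.max(s)
      best_q <- Qr[best, ] / sqrt(sum(Qr[best, ]^2))
      best_s <- max(s)
    }
    spread <- spread / 4
  }
  sqrt(max(0, sA + sB - 2 * best_s))
}

## small balanced generator spec for fast pipeline runs
small_generator <- function(n_cell = 12L, ...) {
  generator_spec(cell_sizes = cbind(F = rep(n_cell, 4),
                                    M = rep(n_cell, 4)), ...)
}

## flat (null) generator: no group offsets, no size gradient, no allometry
null_generator <- function(n_cell = 10L, noise = 0.15) {
  generator_spec(cell_sizes = cbind(F = rep(n_cell, 4),
                                    M = rep(n_cell, 4)),
                 offset_norms = c(control = 0, mild = 0, moderate = 0,
                                  severe = 0),
                 group_size_means = c(control = 18.6, mild = 18.6,
                                      moderate = 18.6, severe = 18.6),
                 sex_size_effect = 0, allometry_share = 0,
                 landmark_noise_sd = noise)
}
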