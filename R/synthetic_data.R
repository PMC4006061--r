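#' Template molar configuration
#'
#' A fixed, versioned 18-landmark configuration (mm) shaped like a lower
#' left first permanent molar crown and respecting the schema's topology:
#' cusp tips lie occlusal to the pits, gingival-margin points lie
#' cervically, and the mesial/distal contact points sit at opposite ends.
#' The configuration is synthetic (constructed, not measured) and is
#' scaled to a centroid size of 18.6 mm.
#'
#' @return A named 18 x 3 coordinate matrix (x mesiodistal, y
#'   buccolingual, z occlusal).
#' @export
template_molar <- function() {
  m <- rbind(
    md_contact_mesial   = c(-5.5,  0.0, 4.5),
    md_contact_distal   = c( 5.5,  0.3, 4.3),
    buccal_axis_end     = c( 0.2,  5.2, 3.8),
    cusp_mesiolingual   = c(-2.8, -3.6, 7.4),
    cusp_distolingual   = c( 2.2, -3.5, 7.1),
    cusp_mesiobuccal    = c(-3.0,  3.4, 7.2),
    cusp_distobuccal    = c( 1.6,  3.5, 7.0),
    cusp_distal5        = c( 4.6,  2.0, 6.6),
    pit_outer_mesial    = c(-4.0,  0.2, 5.6),
    pit_inner_mesial    = c(-2.0,  0.0, 5.3),
    pit_central         = c( 0.4,  0.1, 5.2),
    pit_distal          = c( 2.9,  0.0, 5.4),
    ging_papilla_mesial = c(-4.8,  4.0, 0.6),
    ging_margin_mid     = c( 0.0,  4.6, 0.3),
    ging_papilla_distal = c( 4.7,  3.9, 0.7),
    groove_buccal       = c(-0.6,  4.4, 6.0),
    groove_distobuccal  = c( 3.2,  3.0, 6.1),
    groove_lingual      = c(-0.2, -4.3, 6.2))
  colnames(m) <- c("x", "y", "z")
  m * (18.6 / centroid_size(m))
}

## project a k x 3 perturbation (in shape units) into the tangent space of
## the unit-size template: remove the translation, scale AND rotation
## directions (all absorbed by superimposition, so they carry no shape
## information), then rescale to the requested Procrustes norm
tangent_vector <- function(pattern, template_shape, norm) {
  k <- nrow(template_shape)
  ## nuisance basis: 3 translations, 1 scale, 3 infinitesimal rotations
  gen <- list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3L, 3L),
              matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3L, 3L),
              matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3L, 3L))
  nuis <- cbind(as.vector(cbind(rep(1, k), 0, 0)),
                as.vector(cbind(0, rep(1, k), 0)),
                as.vector(cbind(0, 0, rep(1, k))),
                as.vector(template_shape),
                vapply(gen, function(G) as.vector(template_shape %*% G),
                       numeric(3L * k)))
  Q <- qr.Q(qr(nuis))
  vv <- as.vector(pattern)
  vv <- vv - Q %*% crossprod(Q, vv)
  nv <- sqrt(sum(vv^2))
  if (norm == 0 || nv == 0) return(rep(0, 3L * k))
  as.vector(vv) / nv * norm
}

## deterministic severity axis: occlusal flattening, gingival-margin rise
## and proximal divergence -- the qualitative pattern of hypodontia crowns
severity_pattern <- function(k = 18L) {
  p <- matrix(0, k, 3L)
  p[4:8, 3L] <- -1           # cusp tips compressed occlusally
  p[13:15, 3L] <- 0.8        # gingival margin shortened crown
  p[13:15, 2L] <- 0.3        # margin flattened buccally
  p[1L, 1L] <- -0.5          # proximal contacts diverge
  p[2L, 1L] <- 0.5
  p
}

## small group-specific lateral patterns, one per hypodontia grade
lateral_patterns <- function(k = 18L) {
  p1 <- matrix(0, k, 3L); p1[6:7, 2L] <- 1          # buccal cusp shift
  p2 <- matrix(0, k, 3L); p2[9:12, 3L] <- -1        # pit deepening
  p3 <- matrix(0, k, 3L); p3[8L, 1L] <- 1; p3[5L, 2L] <- -1
  list(mild = p1, moderate = p2, severe = p3)
}

#' Allometric coefficient norm for a designed variance share
#'
#' Given isotropic landmark noise (mm), the size standard deviation and
#' the mean centroid size, returns the norm of the per-mm allometric
#' shape vector such that regression of shape on size is expected to
#' predict \code{share} of the total shape variance.
#'
#' @param share designed allometric share of shape variance in (0, 1).
#' @param noise_sd isotropic landmark noise sd (mm).
#' @param size_sd centroid-size sd (mm).
#' @param mean_cs mean centroid size (mm).
#' @param k number of landmarks.
#' @return The tangent-vector norm per mm of centroid size.
#' @export
allometry_norm_for_share <- function(share, noise_sd, size_sd, mean_cs,
                                     k = 18L) {
  stopifnot(share > 0, share < 1)
  sqrt(share / (1 - share) * (3 * k - 7)) * noise_sd / (mean_cs * size_sd)
}

#' Scan/digitization noise for designed error shares
#'
#' Inverts the expected sums of squares of the balanced nested
#' individual / scan / digitization design: given the designed percent
#' shares of the three strata and the individual-level noise sd, returns
#' the scan- and digitization-level sds that make the expected Procrustes
#' ANOVA SS shares equal the design.
#'
#' @param shares length-3 vector of percent (or proportion) shares for
#'   individual, scan, digitization (summing to 100 or 1).
#' @param n_individuals,n_scans,n_digitizations design counts.
#' @param individual_sd individual-level landmark noise sd (mm).
#' @return A list with \code{scan_sd} and \code{digit_sd} (mm).
#' @export
error_sds_for_shares <- function(shares, n_individuals = 20L,
                                 n_scans = 2L, n_digitizations = 2L,
                                 individual_sd = 0.15) {
  shares <- shares / sum(shares)
  p1 <- shares[1L]; p2 <- shares[2L]; p3 <- shares[3L]
  n <- n_individuals; s <- n_scans; d <- n_digitizations
  stopifnot(p3 > 0, s >= 2, d >= 2)
  A <- (p1 / p3) * n * s * (d - 1) / (n - 1)
  C <- (p2 / p3) * s * (d - 1) / (s - 1)
  if (A - C <= 0 || C < 1)
    stop("infeasible error shares for this design")
  var_d <- s * d * individual_sd^2 / (A - C)
  var_s <- (C - 1) * var_d / d
  list(scan_sd = sqrt(var_s), digit_sd = sqrt(var_d))
}

#' Synthetic-study generator specification
#'
#' Defines the statistical structure of a simulated landmark study
#' emulating a four-group (control / mild / moderate / severe) by
#' two-sex clinical design: unbalanced cell sizes, a declining group
#' mean-size gradient, designed group mean-shape offsets (Procrustes
#' norm), weak allometry and isotropic landmark noise, plus a replicated
#' scan/digitization error hierarchy.
#'
#' Defaults mirror the emulated study: cell sizes 20/20/20/19 (female)
#' and 20/20/19/15 (male), female group mean sizes 18.58, 17.88, 17.84,
#' 17.51 mm with +0.45 mm for males, size sd 1.05 mm, landmark noise
#' 0.15 mm, shape offset norms 0 / 0.030 / 0.042 / 0.052 along a severity
#' axis, and an allometric coefficient sized for a 7% shape-variance
#' share.
#'
#' @param template k x 3 base configuration (mm).
#' @param cell_sizes 4 x 2 matrix (groups x F/M) of cell counts.
#' @param offset_norms named numeric vector of per-group Procrustes
#'   offset norms (control must be 0 or small).
#' @param group_size_means named numeric vector of female group mean
#'   centroid sizes (mm).
#' @param sex_size_effect mm added to male mean centroid size.
#' @param size_sd centroid-size sd (mm).
#' @param landmark_noise_sd isotropic per-landmark noise sd (mm).
#' @param allometry_share designed allometric share of shape variance.
#' @param error_design list with n_individuals, n_scans, n_digitizations,
#'   scan_sd, digit_sd (defaults solve \code{\link{error_sds_for_shares}}
#'   for shares 82.8/6.2/11.0).
#' @param seed default integer seed for generation.
#' @return A list of class \code{generator_spec}; offset vectors are laid
#'   down deterministically along the severity axis with small
#'   group-specific lateral components, normalized to the given norms.
#' @export
generator_spec <- function(template = template_molar(),
                           cell_sizes = cbind(F = c(20L, 20L, 20L, 19L),
                                              M = c(20L, 20L, 19L, 15L)),
                           offset_norms = c(control = 0, mild = 0.030,
                                            moderate = 0.042,
                                            severe = 0.052),
                           group_size_means = c(control = 18.58,
                                                mild = 17.88,
                                                moderate = 17.84,
                                                severe = 17.51),
                           sex_size_effect = 0.45,
                           size_sd = 1.05,
                           landmark_noise_sd = 0.15,
                           allometry_share = 0.07,
                           error_design = NULL,
                           seed = 1L) {
  k <- nrow(template)
  rownames(cell_sizes) <- GROUP_LEVELS
  stopifnot(all(cell_sizes >= 0), size_sd >= 0, landmark_noise_sd >= 0,
            all(offset_norms >= 0), all(is.finite(template)))
  t0 <- preshape(template)
  sev <- tangent_vector(severity_pattern(k), t0, 1)
  lat <- lapply(lateral_patterns(k), function(p) {
    v <- tangent_vector(p, t0, 1)
    v <- v - sum(v * sev) * sev          # orthogonal to the severity axis
    v / sqrt(sum(v^2))
  })
  mix <- c(control = 0, mild = 0.25, moderate = 0.25, severe = 0.25)
  offsets <- matrix(0, 4L, 3L * k, dimnames = list(GROUP_LEVELS, NULL))
  for (g in GROUP_LEVELS) {
    if (offset_norms[[g]] == 0) next
    v <- sev
    if (g %in% names(lat)) v <- v + mix[[g]] * lat[[g]]
    offsets[g, ] <- v / sqrt(sum(v^2)) * offset_norms[[g]]
  }
  group_size_means <- group_size_means[GROUP_LEVELS]
  means_mat <- cbind(F = group_size_means,
                     M = group_size_means + sex_size_effect)
  mean_cs <- if (sum(cell_sizes) > 0)
    sum(cell_sizes * means_mat) / sum(cell_sizes)
  else mean(means_mat)
  allo_dir <- tangent_vector(matrix(c(rep(0, k), rep(0, k),
                                      (seq_len(k) %% 3) - 1), k, 3L),
                             t0, 1)
  allo_norm <- if (allometry_share > 0 && size_sd > 0 &&
                   landmark_noise_sd > 0)
    allometry_norm_for_share(allometry_share, landmark_noise_sd, size_sd,
                             mean_cs, k)
  else 0
  if (is.null(error_design)) {
    sds <- error_sds_for_shares(c(82.8, 6.2, 11.0), 20L, 2L, 2L,
                                landmark_noise_sd)
    error_design <- list(n_individuals = 20L, n_scans = 2L,
                         n_digitizations = 2L, scan_sd = sds$scan_sd,
                         digit_sd = sds$digit_sd)
  }
  structure(list(template = template,
                 cell_sizes = cell_sizes,
                 group_shape_offsets = offsets,
                 severity_order = GROUP_LEVELS,
                 sex_size_effect = sex_size_effect,
                 group_size_means = group_size_means,
                 size_sd = size_sd,
                 allometry_vector = allo_dir * allo_norm,
                 allometry_share = allometry_share,
                 landmark_noise_sd = landmark_noise_sd,
                 error_design = error_design,
                 mean_cs = mean_cs,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

## uniform random rotation from a normalized quaternion
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b),
           a^2 - b^2 - c^2 + d^2), 3L, 3L)
}

#' Generate a synthetic landmark study
#'
#' Draws one specimen per cell entry: the unit-size template shape is
#' deformed by its group's tangent offset plus the allometric vector
#' times the specimen's centroid-size deviation, renormalized, scaled to
#' a centroid size drawn from the cell's size distribution, perturbed by
#' isotropic landmark noise (mm) and finally randomly rotated and
#' translated.
#'
#' @param spec a \code{generator_spec}.
#' @param seed integer seed (defaults to \code{spec$seed}).
#' @return A \code{study_dataset} with group and sex records.
#' @export
generate_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  total <- sum(spec$cell_sizes)
  if (total == 0L) stop("degenerate spec: zero specimens")
  set.seed(seed)
  k <- nrow(spec$template)
  t0 <- preshape(spec$template)
  coords <- array(NA_real_, c(k, 3L, total))
  ids <- character(total)
  group <- character(total)
  sex <- character(total)
  i <- 0L
  for (g in rownames(spec$cell_sizes)) for (sx in colnames(spec$cell_sizes)) {
    n <- spec$cell_sizes[g, sx]
    if (n == 0L) next
    mu <- spec$group_size_means[[g]] +
      if (sx == "M") spec$sex_size_effect else 0
    for (j in seq_len(n)) {
      i <- i + 1L
      cs <- stats::rnorm(1L, mu, spec$size_sd)
      v <- as.vector(t0) + spec$group_shape_offsets[g, ] +
        spec$allometry_vector * (cs - spec$mean_cs)
      shape <- preshape(matrix(v, k, 3L))
      cfg <- shape * cs +
        matrix(stats::rnorm(3L * k, 0, spec$landmark_noise_sd), k, 3L)
      cfg <- cfg %*% rand_rotation()
      cfg <- sweep(cfg, 2L, stats::rnorm(3L, 0, 10), `+`)
      coords[, , i] <- cfg
      ids[i] <- sprintf("%s_%s_%02d", g, sx, j)
      group[i] <- g
      sex[i] <- sx
    }
  }
  dimnames(coords) <- list(rownames(spec$template), c("x", "y", "z"), ids)
  study_dataset(coords,
                data.frame(specimen_id = ids, group = group, sex = sex,
                           stringsAsFactors = FALSE),
                if (k == 18L) molar_schema() else generic_schema(k))
}

#' Generate a replicated measurement-error study
#'
#' Hierarchical noise model for the error design: each individual's true
#' configuration is drawn once (template scaled to a drawn centroid size
#' plus individual-level landmark noise); each scan adds a scan-level
#' perturbation; each digitization of a scan adds a digitization-level
#' perturbation and its own random orientation.
#'
#' @param spec a \code{generator_spec} with a complete
#'   \code{error_design}.
#' @param seed integer seed (defaults to \code{spec$seed}).
#' @return A \code{study_dataset} whose records carry \code{individual},
#'   \code{scan_session} and \code{digitization} labels.
#' @export
generate_error_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  ed <- spec$error_design
  need <- c("n_individuals", "n_scans", "n_digitizations", "scan_sd",
            "digit_sd")
  if (!all(need %in% names(ed)))
    stop("error_design incomplete: need ", paste(need, collapse = ", "))
  if (ed$n_scans < 2L || ed$n_digitizations < 2L)
    stop("design error: at least two scans and two digitizations required")
  set.seed(seed)
  k <- nrow(spec$template)
  t0 <- preshape(spec$template)
  total <- ed$n_individuals * ed$n_scans * ed$n_digitizations
  coords <- array(NA_real_, c(k, 3L, total))
  rec <- data.frame(specimen_id = character(total),
                    individual = character(total),
                    scan_session = integer(total),
                    digitization = integer(total),
                    stringsAsFactors = FALSE)
  i <- 0L
  for (ind in seq_len(ed$n_individuals)) {
    cs <- stats::rnorm(1L, spec$group_size_means[["control"]],
                       spec$size_sd)
    base <- t0 * cs +
      matrix(stats::rnorm(3L * k, 0, spec$landmark_noise_sd), k, 3L)
    for (s in seq_len(ed$n_scans)) {
      scan_cfg <- base + matrix(stats::rnorm(3L * k, 0, ed$scan_sd), k, 3L)
      for (d in seq_len(ed$n_digitizations)) {
        i <- i + 1L
        cfg <- scan_cfg +
          matrix(stats::rnorm(3L * k, 0, ed$digit_sd), k, 3L)
        cfg <- cfg %*% rand_rotation()
        cfg <- sweep(cfg, 2L, stats::rnorm(3L, 0, 10), `+`)
        coords[, , i] <- cfg
        rec$specimen_id[i] <- sprintf("ind%02d_s%d_d%d", ind, s, d)
        rec$individual[i] <- sprintf("ind%02d", ind)
        rec$scan_session[i] <- s
        rec$digitization[i] <- d
      }
    }
  }
  dimnames(coords) <- list(rownames(spec$template), c("x", "y", "z"),
                           rec$specimen_id)
  study_dataset(coords, rec,
                if (k == 18L) molar_schema() else generic_schema(k))
}
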