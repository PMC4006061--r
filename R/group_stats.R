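#' Rao's F approximation for Wilks' lambda
#'
#' Transforms a Wilks' lambda statistic into an F statistic with
#' hypothesis df p*q and (possibly fractional) error df, using Rao's
#' approximation; the transformation is exact when min(p, q) <= 2.
#' With t the Rao exponent, w = df_residual - (p - q + 1)/2,
#' df2 = w*t - p*q/2 + 1 and F = ((1 - L^(1/t)) / L^(1/t)) * df2/df1.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param p_responses number of response variables p.
#' @param q_hypothesis hypothesis degrees of freedom q.
#' @param df_residual residual degrees of freedom.
#' @return A list with \code{F}, \code{df1}, \code{df2}.
#' @export
rao_f <- function(lambda, p_responses, q_hypothesis, df_residual) {
  p <- p_responses; q <- q_hypothesis
  stopifnot(lambda > 0, lambda <= 1, p >= 1, q >= 1)
  if (df_residual <= p_responses)
    stop("singular system: residual df (", df_residual,
         ") must exceed the number of responses (", p, ")")
  tt <- if (p * q <= 3 || (p^2 + q^2 - 5) <= 0) 1
        else sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  w <- df_residual - (p - q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - p * q / 2 + 1
  lam_t <- lambda^(1 / tt)
  list(F = (1 - lam_t) / lam_t * df2 / df1, df1 = df1, df2 = df2)
}

## sum-to-zero contrasts for every factor in a model frame
sum_contrasts <- function(data) {
  fac <- names(data)[vapply(data, is.factor, TRUE)]
  stats::setNames(rep(list("contr.sum"), length(fac)), fac)
}

## Type III multivariate linear-hypothesis tests (Wilks / Rao) for every
## term of a formula, with sum-to-zero contrasts
wilks_tests <- function(Y, formula, data) {
  Y <- as.matrix(Y)
  X <- stats::model.matrix(formula, data,
                           contrasts.arg = sum_contrasts(data))
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (empty cell?)")
  n <- nrow(Y)
  p <- ncol(Y)
  df_res <- n - ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  if (p > 1L) {
    ldE <- determinant(E)$modulus
    if (!is.finite(ldE) || qr(E)$rank < p)
      stop("singular error matrix; use fewer response components (PCs)")
  }
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(formula, data = data), "term.labels")
  out <- lapply(seq_along(labs), function(t) {
    idx <- which(asgn == t)
    C <- B[idx, , drop = FALSE]
    H <- crossprod(C, solve(XtXi[idx, idx, drop = FALSE], C))
    lambda <- if (p == 1L) {
      if (E + H <= 0) 1 else as.numeric(E / (E + H))
    } else as.numeric(exp(ldE - determinant(E + H)$modulus))
    lambda <- min(1, max(lambda, .Machine$double.xmin))
    q <- length(idx)
    rf <- rao_f(lambda, p, q, df_res)
    s <- min(p, q)
    data.frame(effect = labs[t], wilks_lambda = lambda, F = rf$F,
               df1 = rf$df1, df2 = rf$df2,
               p = stats::pf(rf$F, rf$df1, rf$df2, lower.tail = FALSE),
               eta_squared = 1 - lambda^(1 / s),
               SS = if (p == 1L) as.numeric(H) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "df_residual") <- df_res
  attr(res, "SS_residual") <- if (p == 1L) as.numeric(E) else NA_real_
  res
}

#' Two-way ANOVA with Type III sums of squares
#'
#' Univariate group x sex analysis of variance with sum-to-zero contrasts
#' (so the Type III sums of squares match the usual unbalanced-design
#' convention; with balanced data they equal sequential sums of squares).
#'
#' @param values numeric response (e.g. centroid size in mm).
#' @param group,sex factors (coerced).
#' @param include_interaction include the group:sex term.
#' @return A data.frame of class \code{anova_table} with per-effect SS,
#'   df, MS, F, p and a residual row.
#' @export
two_way_anova <- function(values, group, sex, include_interaction = TRUE) {
  dat <- data.frame(group = factor(group), sex = factor(sex))
  if (nlevels(dat$group) < 2L || nlevels(dat$sex) < 2L)
    stop("both factors need at least two levels")
  if (include_interaction &&
      any(table(dat$group, dat$sex) == 0L))
    stop("empty group x sex cell: interaction model is not estimable")
  form <- if (include_interaction) ~ group * sex else ~ group + sex
  w <- wilks_tests(matrix(as.numeric(values)), form, dat)
  tab <- data.frame(effect = c(w$effect, "residual"),
                    SS = c(w$SS, attr(w, "SS_residual")),
                    df = c(w$df1, attr(w, "df_residual")),
                    stringsAsFactors = FALSE)
  tab$MS <- tab$SS / tab$df
  tab$F <- c(tab$MS[-nrow(tab)] / tab$MS[nrow(tab)], NA)
  tab$p <- stats::pf(tab$F, tab$df, attr(w, "df_residual"),
                     lower.tail = FALSE)
  structure(tab, class = c("anova_table", "data.frame"))
}

#' MANOVA of shape scores on group and sex
#'
#' Wilks' lambda tests (Type III, sum-to-zero contrasts) for group, sex
#' and optionally their interaction on a matrix of response variables
#' (typically the first m shape PCs), with F and degrees of freedom from
#' Rao's approximation.
#'
#' @param scores n x p response matrix.
#' @param group,sex factors (coerced).
#' @param include_interaction include the group:sex term.
#' @return A data.frame of per-effect test results (wilks_lambda, F, df1,
#'   df2, p, eta_squared with eta^2 = 1 - lambda^(1/s), s = min(p, q)).
#' @export
manova_shape <- function(scores, group, sex, include_interaction = TRUE) {
  scores <- as.matrix(scores)
  dat <- data.frame(group = factor(group), sex = factor(sex))
  cells <- if (include_interaction)
    nlevels(dat$group) * nlevels(dat$sex)
  else nlevels(dat$group) + nlevels(dat$sex) - 1L
  if (nrow(scores) <= ncol(scores) + cells)
    stop("too few specimens for ", ncol(scores), " responses")
  form <- if (include_interaction) ~ group * sex else ~ group + sex
  wilks_tests(scores, form, dat)
}

#' MANCOVA of shape scores on group with a size covariate
#'
#' As \code{\link{manova_shape}} but with a continuous covariate
#' (centroid size). Without interaction the residual df is
#' n - groups - 1; with the group:covariate interaction (separate slopes)
#' it is n - 2*groups.
#'
#' @param scores n x p response matrix.
#' @param group factor (coerced).
#' @param covariate_cs numeric covariate (centroid size, mm).
#' @param include_interaction include the group:covariate term.
#' @return A data.frame of per-effect test results.
#' @export
mancova_shape <- function(scores, group, covariate_cs,
                          include_interaction = FALSE) {
  scores <- as.matrix(scores)
  if (stats::sd(covariate_cs) == 0)
    stop("constant covariate")
  dat <- data.frame(group = factor(group), cs = as.numeric(covariate_cs))
  form <- if (include_interaction) ~ group * cs else ~ group + cs
  wilks_tests(scores, form, dat)
}

#' Holm step-down (sequential Bonferroni) adjustment
#'
#' @param p_values numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise permutation tests between groups
#'
#' For every pair of groups, tests the observed statistic (Procrustes
#' distance between group mean shapes, or absolute mean difference of a
#' scalar such as centroid size) against its permutation distribution
#' under random reassignment of the pair's specimens. The permutation
#' p-value is (b + 1) / (n_perm + 1) where b counts permuted statistics
#' at least as large as the observed one. Percent explained is the
#' between-group share of the total sum of squares on the two-group
#' subsample. P-values are Holm-adjusted across pairs.
#'
#' @param x a \code{procrustes_fit} (for \code{procrustes_distance}), a
#'   numeric vector (for \code{mean_difference}), or an n x q coordinate
#'   matrix (for \code{tangent_distance}, the Euclidean distance between
#'   group mean tangent vectors, used for size-corrected shapes).
#' @param labels grouping factor, one entry per specimen.
#' @param statistic \code{"procrustes_distance"},
#'   \code{"mean_difference"} or \code{"tangent_distance"}.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer for reproducibility.
#' @param alpha significance level for the flag (default 0.05).
#' @return A data.frame of class \code{pairwise_tests} with one row per
#'   pair: statistic, percent_explained, p_raw, p_adjusted, significant.
#' @export
pairwise_permutation_tests <- function(x, labels,
                                       statistic = c("procrustes_distance",
                                                     "mean_difference",
                                                     "tangent_distance"),
                                       n_perm = 10000L, seed = NULL,
                                       alpha = 0.05) {
  statistic <- match.arg(statistic)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  labels <- factor(labels)
  if (!is.null(seed)) set.seed(seed)
  if (statistic == "procrustes_distance") {
    stopifnot(inherits(x, "procrustes_fit"))
    n <- dim(x$aligned)[3L]
    tang <- x$tangent
  } else if (statistic == "tangent_distance") {
    x <- as.matrix(x)
    n <- nrow(x)
    tang <- x
  } else {
    x <- as.numeric(x)
    n <- length(x)
  }
  if (length(labels) != n) stop("one label per specimen required")
  if (any(table(labels) < 2L))
    stop("group(s) of size < 2: ",
         paste(levels(labels)[table(labels) < 2L], collapse = ", "))
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2L)
  ## statistic on a subsample given a 0/1 assignment
  stat_fun <- switch(statistic,
    procrustes_distance = function(idx, grp) {
      m1 <- apply(x$aligned[, , idx[grp], drop = FALSE], c(1, 2), mean)
      m2 <- apply(x$aligned[, , idx[!grp], drop = FALSE], c(1, 2), mean)
      procrustes_distance(m1, m2)
    },
    tangent_distance = function(idx, grp) {
      m1 <- colMeans(x[idx[grp], , drop = FALSE])
      m2 <- colMeans(x[idx[!grp], , drop = FALSE])
      sqrt(sum((m1 - m2)^2))
    },
    mean_difference = function(idx, grp)
      abs(mean(x[idx[grp]]) - mean(x[idx[!grp]])))
  res <- apply(pairs, 2L, function(pr) {
    idx <- which(labels %in% pr)
    grp <- labels[idx] == pr[1L]
    obs <- stat_fun(idx, grp)
    b <- 0L
    for (r in seq_len(n_perm)) {
      if (stat_fun(idx, sample(grp)) >= obs) b <- b + 1L
    }
    ## between/total SS on the pair subsample
    Y <- if (statistic == "mean_difference") matrix(x[idx])
         else tang[idx, , drop = FALSE]
    gmean <- colMeans(Y)
    ssb <- 0; sst <- sum(sweep(Y, 2L, gmean)^2)
    for (g in c(TRUE, FALSE)) {
      Yg <- Y[grp == g, , drop = FALSE]
      ssb <- ssb + nrow(Yg) * sum((colMeans(Yg) - gmean)^2)
    }
    c(obs, if (sst > 0) ssb / sst * 100 else 0, (b + 1) / (n_perm + 1))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    statistic = res[1L, ], percent_explained = res[2L, ],
                    p_raw = res[3L, ], stringsAsFactors = FALSE)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  structure(out, statistic = statistic, n_perm = n_perm, alpha = alpha,
            class = c("pairwise_tests", "data.frame"))
}

#' Pairwise table in the publication layout
#'
#' Square group-by-group matrix with percent explained in the upper
#' triangle and (adjusted or raw) p-values in the lower triangle.
#'
#' @param tests a \code{pairwise_tests} data.frame.
#' @param adjusted use Holm-adjusted p-values (default TRUE).
#' @return A character-free numeric matrix with group dimnames.
#' @export
pairwise_matrix <- function(tests, adjusted = TRUE) {
  lv <- unique(c(tests$group1, tests$group2))
  m <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(tests))) {
    a <- tests$group1[i]; b <- tests$group2[i]
    m[a, b] <- tests$percent_explained[i]
    m[b, a] <- if (adjusted) tests$p_adjusted[i] else tests$p_raw[i]
  }
  m
}

#' Multivariate regression of shape on size (allometry)
#'
#' Regresses tangent-space shape coordinates onto centroid size and
#' reports the percent of total shape variance predicted by size, with a
#' permutation p-value obtained by shuffling sizes against shapes.
#'
#' @param tangent_coords n x q matrix of tangent (or PC score)
#'   coordinates.
#' @param cs centroid sizes (mm).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param use_log regress on log(CS) instead of CS (default FALSE).
#' @return A list of class \code{allometry_result} with
#'   \code{percent_predicted}, \code{p_permutation} and
#'   \code{coefficients} (shape change per unit CS).
#' @export
allometry_regression <- function(tangent_coords, cs, n_perm = 999L,
                                 seed = NULL, use_log = FALSE) {
  Y <- as.matrix(tangent_coords)
  cs <- as.numeric(cs)
  if (nrow(Y) < 4L) stop("at least 4 specimens required")
  if (stats::sd(cs) == 0) stop("constant centroid size")
  if (use_log) cs <- log(cs)
  if (!is.null(seed)) set.seed(seed)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sst <- sum(Yc^2)
  pct <- function(x) {
    xc <- x - mean(x)
    b <- crossprod(Yc, xc) / sum(xc^2)
    sum((xc %*% t(b))^2) / sst * 100
  }
  obs <- pct(cs)
  b_count <- 0L
  for (r in seq_len(n_perm))
    if (pct(sample(cs)) >= obs) b_count <- b_count + 1L
  xc <- cs - mean(cs)
  structure(list(percent_predicted = obs,
                 p_permutation = (b_count + 1L) / (n_perm + 1L),
                 coefficients = as.vector(crossprod(Yc, xc) / sum(xc^2))),
            class = "allometry_result")
}

#' Size-correct shape coordinates
#'
#' Removes the pooled within-group allometric component: shapes are
#' replaced by the residuals of the pooled within-group regression of
#' shape on centroid size, evaluated about the grand mean size so that
#' group mean differences (beyond their allometric part) are retained.
#'
#' @param tangent_coords n x q matrix of tangent coordinates.
#' @param cs centroid sizes (mm).
#' @param groups grouping factor.
#' @return The corrected n x q coordinate matrix.
#' @export
size_correct <- function(tangent_coords, cs, groups) {
  Y <- as.matrix(tangent_coords)
  cs <- as.numeric(cs)
  groups <- factor(groups)
  ## pooled within-group slope
  num <- 0; den <- 0
  for (lv in levels(groups)) {
    i <- groups == lv
    xc <- cs[i] - mean(cs[i])
    num <- num + crossprod(Y[i, , drop = FALSE], xc)
    den <- den + sum(xc^2)
  }
  if (den == 0) stop("constant centroid size within all groups")
  b <- as.vector(num / den)
  Y - outer(cs - mean(cs), b)
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Fits a linear discriminant (pooled within-group covariance, equal
#' priors by default), reports resubstitution and leave-one-out confusion
#' matrices and accuracies, and tests overall group separation with a
#' Wilks' lambda / Rao's F one-way MANOVA.
#'
#' @param scores n x p matrix of predictors (typically shape PCs).
#' @param labels grouping factor.
#' @param priors \code{"equal"} or \code{"proportional"}.
#' @return A list of class \code{discriminant_result} with
#'   \code{confusion_resub}, \code{confusion_loo}, \code{accuracy_resub},
#'   \code{accuracy_loo} and \code{wilks} (lambda, F, df1, df2, p).
#' @export
lda_crossval <- function(scores, labels, priors = c("equal",
                                                    "proportional")) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  labels <- factor(labels)
  g <- nlevels(labels)
  n <- nrow(scores)
  if (g < 2L) stop("at least two groups required")
  if (n - g <= ncol(scores))
    stop("singular pooled covariance; use fewer response components (PCs)")
  pr <- if (priors == "equal") rep(1 / g, g)
        else as.vector(table(labels)) / n
  fit <- MASS::lda(scores, grouping = labels, prior = pr)
  pred <- stats::predict(fit, scores)$class
  loo <- MASS::lda(scores, grouping = labels, prior = pr, CV = TRUE)$class
  conf <- function(p) table(truth = labels, predicted = p)
  w <- wilks_tests(scores, ~ group, data.frame(group = labels))
  structure(list(confusion_resub = conf(pred),
                 confusion_loo = conf(loo),
                 accuracy_resub = mean(pred == labels),
                 accuracy_loo = mean(loo == labels),
                 wilks = list(lambda = w$wilks_lambda, F = w$F,
                              df1 = w$df1, df2 = w$df2, p = w$p)),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("discriminant_result: resubstitution %.1f%%, LOO %.1f%%; ",
              100 * x$accuracy_resub, 100 * x$accuracy_loo),
      sprintf("Wilks lambda = %.3f, F(%g, %g) = %.3f, p = %.4g\n",
              x$wilks$lambda, x$wilks$df1, round(x$wilks$df2, 3),
              x$wilks$F, x$wilks$p))
  invisible(x)
}
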