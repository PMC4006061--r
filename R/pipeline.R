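#' Pipeline configuration
#'
#' Bundles all run parameters of the end-to-end analysis: either file
#' inputs (landmarks + classifiers) or a \code{generator_spec}, the
#' number of retained PCs ("auto" selects by the distance-correlation
#' rule), permutation count, seed, split-sex flag, significance level and
#' output directory.
#'
#' @param out_dir output directory (created if missing).
#' @param landmark_path,classifier_path input files (used when
#'   \code{generator} is NULL).
#' @param dialect landmark file dialect.
#' @param generator optional \code{generator_spec}; when given, data are
#'   simulated (including the replicated error study).
#' @param pcs \code{"auto"} or an integer number of PCs.
#' @param n_perm permutations for all permutation tests (>= 99).
#' @param seed integer master seed.
#' @param split_sex analyze the sexes separately (default TRUE).
#' @param alpha significance level in (0, 1).
#' @param with_figures write PDF figures (default TRUE).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, landmark_path = NULL,
                            classifier_path = NULL,
                            dialect = "csv_long", generator = NULL,
                            pcs = "auto", n_perm = 999L, seed = 1L,
                            split_sex = TRUE, alpha = 0.05,
                            with_figures = TRUE) {
  if (!(identical(pcs, "auto") || (is.numeric(pcs) && pcs >= 1)))
    stop("config error: pcs must be 'auto' or a positive integer")
  if (n_perm < 99L) stop("config error: n_perm must be >= 99")
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must be in (0,1)")
  if (is.null(generator) && is.null(landmark_path))
    stop("config error: either input paths or a generator are required")
  structure(list(out_dir = out_dir, landmark_path = landmark_path,
                 classifier_path = classifier_path, dialect = dialect,
                 generator = generator, pcs = pcs,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 split_sex = isTRUE(split_sex), alpha = alpha,
                 with_figures = isTRUE(with_figures)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto \code{\link{pipeline_config}}
#' arguments; a \code{generator: default} entry uses
#' \code{\link{generator_spec}()} defaults.
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) {
    gen <- if (identical(y$generator, "default")) generator_spec()
           else do.call(generator_spec, y$generator)
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  args$generator <- gen
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

## subset a procrustes fit to a set of specimens (no re-superimposition:
## all analyses stay in the common shape space)
subset_fit <- function(fit, idx) {
  out <- fit
  out$aligned <- fit$aligned[, , idx, drop = FALSE]
  out$tangent <- fit$tangent[idx, , drop = FALSE]
  out$centroid_sizes <- fit$centroid_sizes[idx]
  out$specimen_ids <- fit$specimen_ids[idx]
  out
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         " (check the stage's inputs and config)", call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow: measurement-error Procrustes
#' ANOVA, generalized Procrustes analysis, size descriptives and ANOVA,
#' pairwise size permutation tests, shape PCA with dimensionality
#' selection, MANOVA, pairwise shape tests, allometric regression,
#' MANCOVA, size correction with re-run pairwise tests, leave-one-out
#' discriminant analysis, group mean shapes with mean-shape PCA and
#' thin-plate-spline warps from the control mean to each hypodontia
#' group mean. All tables are written as CSV, figures as PDF, and a JSON
#' summary records every decision parameter; a manifest check fails
#' loudly if any expected artifact is missing.
#'
#' @param config a \code{pipeline_config}.
#' @return An \code{analysis_report} (list of tables, figure paths and
#'   run metadata), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(config$out_dir, "figures")
  if (config$with_figures)
    dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  figures <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  ## ---- data ----
  if (!is.null(config$generator)) {
    ds <- pipeline_stage("generate",
                         generate_study(config$generator, config$seed))
    err_ds <- pipeline_stage("generate_error",
                             generate_error_study(config$generator,
                                                  config$seed + 1L))
  } else {
    ds <- pipeline_stage("read", {
      d <- read_landmarks(config$landmark_path, config$dialect)
      if (!is.null(config$classifier_path))
        d <- set_classifiers(d, read_classifiers(config$classifier_path))
      d
    })
    err_ds <- NULL
  }
  note("n_specimens=", n_specimens(ds), " seed=", config$seed,
       " n_perm=", config$n_perm, " alpha=", config$alpha)

  ## ---- measurement error ----
  if (!is.null(err_ds)) {
    tables$error_anova_shape <- pipeline_stage("error_anova",
      as.data.frame(procrustes_anova(err_ds, "shape")))
    tables$error_anova_size <- as.data.frame(
      procrustes_anova(err_ds, "size"))
  }

  ## ---- superimposition ----
  fit <- pipeline_stage("gpa", gpa(ds))
  cs <- fit$centroid_sizes
  rec <- ds$records
  group <- factor(rec$group, levels = GROUP_LEVELS)
  sex <- factor(rec$sex, levels = SEX_LEVELS)
  sexes <- if (config$split_sex) stats::setNames(SEX_LEVELS,
                                                 c("female", "male"))
           else c(pooled = NA)

  ## ---- size ----
  desc <- do.call(rbind, lapply(levels(sex), function(sx)
    do.call(rbind, lapply(levels(group), function(g) {
      i <- which(group == g & sex == sx)
      data.frame(sex = sx, group = g, mean = mean(cs[i]),
                 sd = stats::sd(cs[i]),
                 cv = 100 * stats::sd(cs[i]) / mean(cs[i]),
                 n = length(i))
    }))))
  tables$descriptives_size <- desc
  tables$size_anova_interaction <- pipeline_stage("size_anova",
    as.data.frame(two_way_anova(cs, group, sex, TRUE)))
  tables$size_anova_main <- as.data.frame(
    two_way_anova(cs, group, sex, FALSE))
  for (j in seq_along(sexes)) {
    sx <- sexes[j]
    i <- if (is.na(sx)) seq_along(cs) else which(sex == sx)
    pt <- pipeline_stage("size_pairwise",
      pairwise_permutation_tests(cs[i], droplevels(group[i]),
                                 "mean_difference", config$n_perm,
                                 seed = config$seed + 10L + j,
                                 alpha = config$alpha))
    tables[[paste0("size_pairwise_", names(sexes)[j])]] <-
      as.data.frame(pt)
  }

  ## ---- shape space ----
  space <- pipeline_stage("pca", shape_pca(fit))
  profile <- pipeline_stage("dcor_profile",
                            distance_correlation_profile(fit, space))
  if (identical(config$pcs, "auto")) {
    sel <- select_dimensionality(profile)
    m <- sel$m
    note("pcs=auto selected m=", m, " (r=", round(sel$r, 4),
         ", plateau=", sel$plateau, ")")
  } else {
    m <- as.integer(config$pcs)
    note("pcs fixed at m=", m)
  }
  tables$dimension_selection <- data.frame(
    m = seq_along(profile$r_values), r = profile$r_values,
    selected = seq_along(profile$r_values) == m)
  scores <- space$scores[, seq_len(m), drop = FALSE]

  ## ---- shape tests ----
  tables$manova_shape <- pipeline_stage("manova",
    manova_shape(scores, group, sex, TRUE))
  tables$manova_shape_main <- manova_shape(scores, group, sex, FALSE)
  for (j in seq_along(sexes)) {
    sx <- sexes[j]
    i <- if (is.na(sx)) seq_along(cs) else which(sex == sx)
    pt <- pipeline_stage("shape_pairwise",
      pairwise_permutation_tests(subset_fit(fit, i), droplevels(group[i]),
                                 "procrustes_distance", config$n_perm,
                                 seed = config$seed + 20L + j,
                                 alpha = config$alpha))
    tables[[paste0("shape_pairwise_", names(sexes)[j])]] <-
      as.data.frame(pt)
  }

  ## ---- allometry ----
  allo <- do.call(rbind, lapply(seq_along(sexes), function(j) {
    sx <- sexes[j]
    do.call(rbind, lapply(levels(group), function(g) {
      i <- if (is.na(sx)) which(group == g)
           else which(group == g & sex == sx)
      ar <- allometry_regression(fit$tangent[i, , drop = FALSE], cs[i],
                                 n_perm = config$n_perm,
                                 seed = config$seed + 30L + j)
      data.frame(sex = names(sexes)[j], group = g,
                 percent_predicted = ar$percent_predicted,
                 p = ar$p_permutation)
    }))
  }))
  tables$allometry <- allo
  manc_i <- manc_m <- list()
  for (j in seq_along(sexes)) {
    sx <- sexes[j]
    i <- if (is.na(sx)) seq_along(cs) else which(sex == sx)
    manc_i[[j]] <- cbind(sex = names(sexes)[j],
      pipeline_stage("mancova",
        mancova_shape(scores[i, , drop = FALSE], droplevels(group[i]),
                      cs[i], include_interaction = TRUE)))
    manc_m[[j]] <- cbind(sex = names(sexes)[j],
      mancova_shape(scores[i, , drop = FALSE], droplevels(group[i]),
                    cs[i], include_interaction = FALSE))
  }
  tables$mancova_interaction <- do.call(rbind, manc_i)
  tables$mancova_main <- do.call(rbind, manc_m)

  ## ---- size-corrected shapes, pairwise re-run, DA ----
  da <- list()
  for (j in seq_along(sexes)) {
    sx <- sexes[j]
    i <- if (is.na(sx)) seq_along(cs) else which(sex == sx)
    corr <- pipeline_stage("size_correct",
      size_correct(fit$tangent[i, , drop = FALSE], cs[i],
                   droplevels(group[i])))
    pt <- pairwise_permutation_tests(corr, droplevels(group[i]),
                                     "tangent_distance", config$n_perm,
                                     seed = config$seed + 40L + j,
                                     alpha = config$alpha)
    tables[[paste0("corrected_pairwise_", names(sexes)[j])]] <-
      as.data.frame(pt)
    cpc <- stats::prcomp(corr, center = TRUE)
    mm <- min(m, ncol(cpc$x), length(i) - nlevels(droplevels(group[i])) - 1L)
    dres <- pipeline_stage("lda",
      lda_crossval(cpc$x[, seq_len(mm), drop = FALSE],
                   droplevels(group[i])))
    da[[names(sexes)[j]]] <- dres
    tables[[paste0("discriminant_", names(sexes)[j])]] <- data.frame(
      accuracy_resub = dres$accuracy_resub,
      accuracy_loo = dres$accuracy_loo,
      wilks_lambda = dres$wilks$lambda, F = dres$wilks$F,
      df1 = dres$wilks$df1, df2 = dres$wilks$df2, p = dres$wilks$p)
  }

  ## ---- mean shapes, mean-shape PCA, TPS warps ----
  warps <- list()
  for (j in seq_along(sexes)) {
    sx <- sexes[j]
    i <- if (is.na(sx)) seq_along(cs) else which(sex == sx)
    means <- pipeline_stage("mean_shapes",
      group_mean_shapes(subset_fit(fit, i), droplevels(group[i])))
    mpca <- mean_shape_pca(means)
    tables[[paste0("mean_shape_pca_", names(sexes)[j])]] <- data.frame(
      group = rownames(mpca$scores), mpca$scores[, 1:2, drop = FALSE])
    if ("control" %in% dimnames(means)[[3L]])
      for (g in setdiff(dimnames(means)[[3L]], "control")) {
        w <- pipeline_stage("tps_warp",
          tps_warp(means[, , "control"], means[, , g]))
        warps[[paste(names(sexes)[j], g, sep = "_")]] <- w
        if (config$with_figures) {
          f <- file.path(fig_dir, sprintf("tps_%s_%s.pdf",
                                          names(sexes)[j], g))
          grDevices::pdf(f, width = 5, height = 5)
          plot(w, plane = 3L,
               main = sprintf("control to %s (%s)", g, names(sexes)[j]))
          grDevices::dev.off()
          figures <- c(figures, f)
        }
      }
    if (config$with_figures) {
      f <- file.path(fig_dir, sprintf("pc_scatter_%s.pdf",
                                      names(sexes)[j]))
      grDevices::pdf(f, width = 5.5, height = 5)
      graphics::plot(space$scores[i, 1L], space$scores[i, 2L],
                     col = as.integer(droplevels(group[i])),
                     pch = 16, xlab = sprintf("PC1 (%.1f%%)",
                                              space$percent_variance[1L]),
                     ylab = sprintf("PC2 (%.1f%%)",
                                    space$percent_variance[2L]),
                     main = paste("Shape PCs,", names(sexes)[j]))
      graphics::legend("topright", legend = levels(droplevels(group[i])),
                       col = seq_len(nlevels(droplevels(group[i]))),
                       pch = 16, cex = 0.8)
      grDevices::dev.off()
      figures <- c(figures, f)
    }
  }

  ## ---- serialize ----
  for (nm in names(tables)) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
  }
  meta <- list(seed = config$seed, n_perm = config$n_perm, pcs = m,
               alpha = config$alpha, split_sex = config$split_sex,
               n_specimens = n_specimens(ds),
               r_version = paste(R.version$major, R.version$minor,
                                 sep = "."),
               package_version = as.character(
                 utils::packageVersion("molarmorph")),
               log = log,
               tables = names(tables), figures = basename(figures))
  jsonlite::write_json(meta, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  ## ---- manifest check ----
  expected <- c(paste0(names(tables), ".csv"), "summary.json")
  missing <- expected[!file.exists(file.path(config$out_dir, expected))]
  if (config$with_figures) {
    missf <- figures[!file.exists(figures)]
    missing <- c(missing, basename(missf))
  }
  if (length(missing))
    stop("pipeline incomplete; missing artifacts: ",
         paste(missing, collapse = ", "))

  invisible(structure(list(tables = tables, figures = figures,
                           discriminant = da, warps = warps, fit = fit,
                           space = space, meta = meta),
                      class = "analysis_report"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", length(x$tables), "tables,",
      length(x$figures), "figures; seed", x$meta$seed, "; m =",
      x$meta$pcs, "PCs\n")
  invisible(x)
}
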