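#' Assemble a Procrustes ANOVA table
#'
#' Builds the hierarchical measurement-error table from sums of squares
#' and degrees of freedom for an ordered sequence of nested effects
#' (highest stratum first, e.g. individual, scan error, digitization
#' error). Each F statistic is the ratio of an effect's mean square to the
#' mean square of the next-lower stratum, and percent explained is the
#' effect's share of the total sum of squares.
#'
#' @param effects character vector of effect names, highest stratum first.
#' @param SS sums of squares (Procrustes or size), same length.
#' @param df integer degrees of freedom.
#' @param MS optional mean squares; defaults to \code{SS / df}.
#' @param response label, \code{"shape"} or \code{"size"}.
#' @return A data.frame of class \code{procrustes_anova_table} with
#'   columns effect, percent_explained, SS, MS, df, F, p.
#' @export
procrustes_anova_table <- function(effects, SS, df, MS = NULL,
                                   response = "shape") {
  m <- length(effects)
  stopifnot(length(SS) == m, length(df) == m, all(SS >= 0), all(df > 0))
  if (is.null(MS)) MS <- SS / df
  Fv <- pv <- rep(NA_real_, m)
  for (r in seq_len(m - 1L)) {
    Fv[r] <- MS[r] / MS[r + 1L]
    pv[r] <- stats::pf(Fv[r], df[r], df[r + 1L], lower.tail = FALSE)
  }
  tab <- data.frame(effect = effects,
                    percent_explained = SS / sum(SS) * 100,
                    SS = SS, MS = MS, df = df, F = Fv, p = pv,
                    stringsAsFactors = FALSE)
  structure(tab, response = response,
            class = c("procrustes_anova_table", "data.frame"))
}

## check and describe a balanced individual / scan / digitization design
error_design <- function(records) {
  need <- c("individual", "scan_session", "digitization")
  if (!all(need %in% names(records)) ||
      anyNA(records[need]))
    stop("design error: complete individual, scan_session and ",
         "digitization labels are required")
  tab <- table(records$individual, records$scan_session,
               records$digitization)
  if (any(tab != 1L))
    stop("design error: replicates must be balanced with one ",
         "configuration per individual x scan x digitization cell")
  n_ind <- dim(tab)[1L]
  s <- dim(tab)[2L]
  d <- dim(tab)[3L]
  if (s < 2L || d < 2L)
    stop("design error: at least two scans and two digitizations per ",
         "individual are required to form error strata")
  list(n_ind = n_ind, s = s, d = d)
}

#' Procrustes ANOVA of measurement error
#'
#' Hierarchical decomposition of size or shape variation across the
#' individual / scan-session / digitization strata of a replicated
#' digitization study. For size, this is an ordinary nested ANOVA on
#' centroid size. For shape, squared Procrustes-coordinate deviations are
#' pooled over all landmarks and dimensions (isotropic model) and each
#' ordinary degree of freedom is multiplied by the shape-space dimension
#' 3k - 7. Each stratum is tested against the next-lower stratum.
#'
#' @param dataset a \code{study_dataset} whose records carry complete,
#'   balanced \code{individual}, \code{scan_session} and
#'   \code{digitization} labels.
#' @param response \code{"shape"} or \code{"size"}.
#' @param fit optional pre-computed \code{procrustes_fit} of the dataset.
#' @return A \code{procrustes_anova_table}.
#' @export
procrustes_anova <- function(dataset, response = c("shape", "size"),
                             fit = NULL) {
  response <- match.arg(response)
  stopifnot(inherits(dataset, "study_dataset"))
  des <- error_design(dataset$records)
  rec <- dataset$records
  k <- n_landmarks(dataset)
  if (response == "size") {
    Y <- matrix(vapply(seq_len(n_specimens(dataset)),
                       function(i) centroid_size(dataset$coords[, , i]), 0))
    mult <- 1L
  } else {
    if (is.null(fit)) fit <- gpa(dataset)
    Y <- fit$tangent
    mult <- 3L * k - 7L
  }
  ind <- factor(rec$individual)
  scan <- interaction(ind, rec$scan_session, drop = TRUE)
  grand <- colMeans(Y)
  mean_rows <- function(f) {
    m <- rowsum(Y, f) / as.vector(table(f))
    m[as.character(f), , drop = FALSE]
  }
  Mi <- mean_rows(ind)
  Mis <- mean_rows(scan)
  SS <- c(individual = sum(sweep(Mi, 2L, grand)^2),
          scan_error = sum((Mis - Mi)^2),
          digitization_error = sum((Y - Mis)^2))
  df <- c(des$n_ind - 1L,
          des$n_ind * (des$s - 1L),
          des$n_ind * des$s * (des$d - 1L)) * mult
  procrustes_anova_table(names(SS), unname(SS), df, response = response)
}

#' Total measurement error
#'
#' Sum of the percent-explained entries of all non-individual (error)
#' strata of a Procrustes ANOVA table: the share of total variation
#' attributable to the measurement process rather than to real
#' among-individual differences.
#'
#' @param table a \code{procrustes_anova_table}.
#' @return A percentage in [0, 100].
#' @export
total_measurement_error <- function(table) {
  stopifnot(inherits(table, "procrustes_anova_table"))
  sum(table$percent_explained[table$effect != "individual"])
}
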