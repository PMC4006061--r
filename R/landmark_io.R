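#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("control", "mild", "moderate", "severe")
SEX_LEVELS <- c("F", "M")

## full-precision numeric formatting so write/read round-trips are bit-exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Landmark schema
#'
#' An ordered set of named landmarks with free-text anatomical definitions
#' and an optional wireframe (landmark-name pairs) used for visualization.
#'
#' @param names character vector of unique landmark identifiers.
#' @param definitions optional character vector of per-landmark definitions.
#' @param wireframe optional two-column character matrix of landmark-name
#'   pairs defining wireframe edges.
#' @return An object of class \code{landmark_schema}.
#' @export
landmark_schema <- function(names, definitions = NULL, wireframe = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names) > 0L)
    stop("landmark names must be unique")
  if (is.null(definitions)) definitions <- rep("", length(names))
  if (length(definitions) != length(names))
    stop("one definition per landmark required")
  if (!is.null(wireframe)) {
    wireframe <- as.matrix(wireframe)
    if (ncol(wireframe) != 2L)
      stop("wireframe must have two columns")
    bad <- !(wireframe %in% names)
    if (any(bad))
      stop("wireframe references unknown landmarks: ",
           paste(unique(wireframe[bad]), collapse = ", "))
    if (any(wireframe[, 1L] == wireframe[, 2L]))
      stop("wireframe edges must join two distinct landmarks")
  }
  structure(list(landmark_names = names, definitions = definitions,
                 wireframe_edges = wireframe),
            class = "landmark_schema")
}

#' The 18-landmark lower first molar schema
#'
#' Standard crown landmarks of the (lower left) first permanent molar:
#' mesial/distal contact points, the buccal endpoint of the bucco-lingual
#' axis, four main cusp tips plus the distobuccal (fifth) cusp tip, four
#' occlusal pits, three gingival-margin points on the buccal side, and the
#' occlusal limits of the buccal, distobuccal and lingual grooves.
#'
#' @return A \code{landmark_schema} with 18 entries.
#' @export
molar_schema <- function() {
  nm <- c("md_contact_mesial", "md_contact_distal", "buccal_axis_end",
          "cusp_mesiolingual", "cusp_distolingual",
          "cusp_mesiobuccal", "cusp_distobuccal", "cusp_distal5",
          "pit_outer_mesial", "pit_inner_mesial", "pit_central", "pit_distal",
          "ging_papilla_mesial", "ging_margin_mid", "ging_papilla_distal",
          "groove_buccal", "groove_distobuccal", "groove_lingual")
  def <- c("Mesial contact point", "Distal contact point",
           "Buccal endpoint of the bucco-lingual axis",
           "Mesial lingual cusp tip", "Distal lingual cusp tip",
           "Mesial buccal cusp tip", "Distal buccal cusp tip",
           "Distobuccal (fifth) cusp tip",
           "Outer mesial pit", "Inner mesial pit", "Central pit",
           "Distal pit",
           "End of mesial papilla, buccal side",
           "Midpoint of gingival margin between papillae, buccal side",
           "End of distal papilla, buccal side",
           "Occlusal limit of the buccal groove",
           "Occlusal limit of the distobuccal groove",
           "Occlusal limit of the lingual groove")
  wf <- rbind(
    c("md_contact_mesial", "cusp_mesiobuccal"),
    c("md_contact_mesial", "cusp_mesiolingual"),
    c("md_contact_distal", "cusp_distobuccal"),
    c("md_contact_distal", "cusp_distolingual"),
    c("cusp_mesiobuccal", "cusp_distobuccal"),
    c("cusp_distobuccal", "cusp_distal5"),
    c("cusp_mesiolingual", "cusp_distolingual"),
    c("cusp_mesiobuccal", "cusp_mesiolingual"),
    c("pit_outer_mesial", "pit_inner_mesial"),
    c("pit_inner_mesial", "pit_central"),
    c("pit_central", "pit_distal"),
    c("ging_papilla_mesial", "ging_margin_mid"),
    c("ging_margin_mid", "ging_papilla_distal"),
    c("groove_buccal", "pit_central"),
    c("groove_distobuccal", "pit_distal"),
    c("groove_lingual", "pit_central"))
  landmark_schema(nm, def, wf)
}

generic_schema <- function(k) {
  landmark_schema(paste0("lm", seq_len(k)))
}

#' Assemble a landmark study dataset
#'
#' Bundles per-specimen landmark configurations with specimen records
#' (group, sex, optional replicate labels) under a common schema.
#'
#' @param coords a k x 3 x n numeric array (landmarks x dimensions x
#'   specimens) in mm, with specimen ids as the third dimnames.
#' @param records a data.frame with columns \code{specimen_id} and
#'   optionally \code{group}, \code{sex}, \code{scan_session},
#'   \code{digitization}; \code{NULL} builds minimal records from the
#'   coordinate array.
#' @param schema a \code{landmark_schema}; defaults to \code{molar_schema()}
#'   when k = 18, otherwise to generic names.
#' @return An object of class \code{study_dataset}.
#' @export
study_dataset <- function(coords, records = NULL, schema = NULL) {
  coords <- as_coord_array(coords)
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (is.null(schema))
    schema <- if (k == 18L) molar_schema() else generic_schema(k)
  stopifnot(inherits(schema, "landmark_schema"))
  if (length(schema$landmark_names) != k)
    stop("configurations have ", k, " landmarks but schema defines ",
         length(schema$landmark_names))
  ids <- dimnames(coords)[[3L]]
  if (is.null(ids)) {
    ids <- paste0("spec", seq_len(n))
    dimnames(coords)[[3L]] <- ids
  }
  if (anyDuplicated(ids) > 0L) stop("duplicate specimen ids")
  if (is.null(records)) {
    records <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  } else {
    records <- validate_records(records)
    if (!setequal(records$specimen_id, ids))
      stop("records and configurations must cover the same specimen ids")
    records <- records[match(ids, records$specimen_id), , drop = FALSE]
    rownames(records) <- NULL
  }
  if (n > 0L && !all(is.finite(coords)))
    stop("non-finite coordinates in configurations")
  dimnames(coords)[[1L]] <- schema$landmark_names
  structure(list(coords = coords, records = records, schema = schema),
            class = "study_dataset")
}

as_coord_array <- function(coords) {
  if (is.list(coords)) {
    ks <- vapply(coords, nrow, 0L)
    if (length(unique(ks)) > 1L)
      stop("schema error: configurations disagree in landmark count (",
           paste(unique(ks), collapse = ", "), ")")
    coords <- array(unlist(coords),
                    dim = c(ks[[1L]], 3L, length(ks)),
                    dimnames = list(NULL, c("x", "y", "z"), names(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be a k x 3 x n array")
  storage.mode(coords) <- "double"
  coords
}

validate_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(records))
    stop("records require a specimen_id column")
  records$specimen_id <- as.character(records$specimen_id)
  if ("group" %in% names(records)) {
    g <- as.character(records$group)
    bad <- which(!is.na(g) & !(g %in% GROUP_LEVELS))
    if (length(bad))
      stop("unknown group token(s) in rows ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(g[bad]), collapse = ", "),
           " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
    records$group <- g
  }
  if ("sex" %in% names(records)) {
    s <- as.character(records$sex)
    bad <- which(!is.na(s) & !(s %in% SEX_LEVELS))
    if (length(bad))
      stop("unknown sex token(s) in rows ", paste(bad, collapse = ", "),
           ": ", paste(unique(s[bad]), collapse = ", "),
           " (expected F/M)")
    records$sex <- s
  }
  for (col in c("scan_session", "digitization"))
    if (col %in% names(records)) {
      v <- records[[col]]
      if (any(!is.na(v) & is.na(suppressWarnings(as.integer(v)))))
        stop(col, " labels must be integers")
      has <- !is.na(v)
      if (any(has) && !all(has))
        stop(col, " replicate labels must be present for all specimens ",
             "or none")
      records[[col]] <- as.integer(v)
    }
  records
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- dim(x$coords)
  cat("study_dataset:", d[3L], "specimens x", d[1L], "landmarks (3D)\n")
  if ("group" %in% names(x$records))
    print(table(group = x$records$group,
                sex = if ("sex" %in% names(x$records)) x$records$sex
                      else "unknown"))
  invisible(x)
}

n_specimens <- function(dataset) dim(dataset$coords)[3L]
n_landmarks <- function(dataset) dim(dataset$coords)[1L]

#' Read landmark coordinate files
#'
#' Parses one of three text dialects into a \code{study_dataset}:
#' \describe{
#'   \item{tps}{TPS grammar with \code{LM3=k} 3D records and a required
#'     \code{ID=} line per specimen.}
#'   \item{morphologika}{Morphologika-style header sections
#'     (\code{[individuals]}, \code{[landmarks]}, \code{[dimensions]},
#'     optional \code{[names]}) followed by \code{[rawpoints]} blocks.}
#'   \item{csv_long}{long CSV with columns specimen_id, landmark_name,
#'     x, y, z.}
#' }
#'
#' @param path file path.
#' @param dialect one of \code{"tps"}, \code{"morphologika"},
#'   \code{"csv_long"}.
#' @param schema optional \code{landmark_schema} to attach.
#' @return A \code{study_dataset} (without classifiers; see
#'   \code{\link{read_classifiers}}).
#' @export
read_landmarks <- function(path, dialect = c("csv_long", "tps",
                                             "morphologika"),
                           schema = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  coords <- switch(dialect,
                   csv_long = parse_csv_long(path),
                   tps = parse_tps(lines),
                   morphologika = parse_morphologika(lines))
  if (length(coords) == 0L) {
    k <- if (!is.null(schema)) length(schema$landmark_names) else 18L
    return(study_dataset(array(numeric(0), dim = c(k, 3L, 0L)),
                         schema = schema))
  }
  ks <- vapply(coords, nrow, 0L)
  if (length(unique(ks)) > 1L)
    stop("schema error: specimens disagree in landmark count: ",
         paste(unique(ks), collapse = ", "))
  ds <- study_dataset(coords, schema = schema)
  ## preserve landmark names carried by csv_long
  if (dialect == "csv_long" && is.null(schema)) {
    lm_names <- rownames(coords[[1L]])
    if (!is.null(lm_names) &&
        !identical(lm_names, ds$schema$landmark_names) &&
        !identical(sort(lm_names), sort(ds$schema$landmark_names)))
      ds$schema <- landmark_schema(lm_names)
    dimnames(ds$coords)[[1L]] <- ds$schema$landmark_names
  }
  ds
}

parse_csv_long <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(specimen_id = "character",
                                              landmark_name = "character"),
                         stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark_name", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("parse error: csv_long requires columns ",
         paste(need, collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  ids <- unique(tab$specimen_id)
  lapply(stats::setNames(ids, ids), function(id) {
    sub <- tab[tab$specimen_id == id, , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$landmark_name
    m
  })
}

parse_tps <- function(lines) {
  coords <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM3=([0-9]+)$", ln))[[1L]]
    if (length(m) == 0L)
      stop("parse error at line ", i, ": expected LM3=<count>, got '",
           lines[i], "'")
    k <- as.integer(m[2L])
    rows <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > length(lines) || grepl("^(LM3=|ID=)", trimws(lines[i])))
        stop("parse error at line ", i,
             ": expected ", k, " coordinate rows, found ", j - 1L)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                   "[ \t]+")[[1L]]))
      if (length(vals) != 3L || anyNA(vals))
        stop("parse error at line ", i, ": expected three numbers")
      rows[j, ] <- vals
    }
    i <- i + 1L
    if (i > length(lines) || !grepl("^ID=", trimws(lines[i])))
      stop("parse error at line ", i, ": expected ID= line")
    id <- sub("^ID=", "", trimws(lines[i]))
    coords[[id]] <- rows
    i <- i + 1L
  }
  coords
}

parse_morphologika <- function(lines) {
  sec <- function(tag) {
    hit <- which(trimws(tolower(lines)) == tag)
    if (length(hit) != 1L)
      stop("parse error: expected one '", tag, "' section")
    hit
  }
  n <- as.integer(trimws(lines[sec("[individuals]") + 1L]))
  k <- as.integer(trimws(lines[sec("[landmarks]") + 1L]))
  ndim <- as.integer(trimws(lines[sec("[dimensions]") + 1L]))
  if (!identical(ndim, 3L)) stop("parse error: [dimensions] must be 3")
  has_names <- any(trimws(tolower(lines)) == "[names]")
  ids <- if (has_names) {
    at <- sec("[names]")
    trimws(lines[at + seq_len(n)])
  } else paste0("spec", seq_len(n))
  if (n == 0L) return(list())
  at <- sec("[rawpoints]")
  body <- lines[(at + 1L):length(lines)]
  body <- body[trimws(body) != ""]
  coords <- list()
  i <- 1L
  for (s in seq_len(n)) {
    if (i <= length(body) && grepl("^'", trimws(body[i]))) {
      id <- sub("^'", "", trimws(body[i]))
      i <- i + 1L
    } else id <- ids[s]
    rows <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      if (i > length(body) || grepl("^'", trimws(body[i])))
        stop("parse error: specimen ", s, " has ", j - 1L,
             " coordinate rows, expected ", k)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                   "[ \t]+")[[1L]]))
      if (length(vals) != 3L || anyNA(vals))
        stop("parse error in [rawpoints]: expected three numbers, got '",
             body[i], "'")
      rows[j, ] <- vals
      i <- i + 1L
    }
    coords[[id]] <- rows
  }
  if (i <= length(body))
    stop("parse error: trailing coordinate rows beyond declared ",
         "[individuals] count")
  coords
}

#' Write landmark coordinate files
#'
#' Emits a \code{study_dataset}'s configurations in one of the supported
#' dialects. Coordinates are written at full double precision so that
#' \code{read_landmarks(write_landmarks(x))} round-trips bit-identically.
#'
#' @param dataset a \code{study_dataset}.
#' @param path output file path.
#' @param dialect one of \code{"csv_long"}, \code{"tps"},
#'   \code{"morphologika"}.
#' @return \code{path}, invisibly.
#' @export
write_landmarks <- function(dataset, path,
                            dialect = c("csv_long", "tps", "morphologika")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "study_dataset"))
  n <- n_specimens(dataset)
  k <- n_landmarks(dataset)
  ids <- dimnames(dataset$coords)[[3L]]
  lm_names <- dataset$schema$landmark_names
  out <- switch(dialect,
    csv_long = {
      header <- "specimen_id,landmark_name,x,y,z"
      if (n == 0L) header else {
        body <- unlist(lapply(seq_len(n), function(s) {
          m <- dataset$coords[, , s]
          paste(ids[s], lm_names, fmt_num(m[, 1L]), fmt_num(m[, 2L]),
                fmt_num(m[, 3L]), sep = ",")
        }))
        c(header, body)
      }
    },
    tps = {
      unlist(lapply(seq_len(n), function(s) {
        m <- dataset$coords[, , s]
        c(sprintf("LM3=%d", k),
          paste(fmt_num(m[, 1L]), fmt_num(m[, 2L]), fmt_num(m[, 3L])),
          sprintf("ID=%s", ids[s]))
      }))
    },
    morphologika = {
      head <- c("[individuals]", n, "[landmarks]", k, "[dimensions]", 3,
                "[names]", ids, "[rawpoints]")
      body <- unlist(lapply(seq_len(n), function(s) {
        m <- dataset$coords[, , s]
        c(paste0("'", ids[s]),
          paste(fmt_num(m[, 1L]), fmt_num(m[, 2L]), fmt_num(m[, 3L])),
          "")
      }))
      c(head, body)
    })
  writeLines(as.character(out), path)
  invisible(path)
}

#' Read a classifier table
#'
#' Reads a delimited table with columns \code{specimen_id} (or \code{id}),
#' \code{group}, \code{sex} and optional \code{scan_session},
#' \code{digitization} replicate labels, validating the closed group/sex
#' vocabularies.
#'
#' @param path CSV file path.
#' @return A validated records data.frame.
#' @export
read_classifiers <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(tab) && !"specimen_id" %in% names(tab))
    names(tab)[names(tab) == "id"] <- "specimen_id"
  validate_records(tab)
}

#' Attach classifier records to a dataset
#'
#' @param dataset a \code{study_dataset}.
#' @param records a records data.frame (see \code{\link{read_classifiers}}).
#' @return The dataset with records joined by specimen id.
#' @export
set_classifiers <- function(dataset, records) {
  study_dataset(dataset$coords, records, dataset$schema)
}

#' Write a classifier table
#'
#' @param records a records data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_classifiers <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one configuration
#'
#' @param dataset a \code{study_dataset}.
#' @param i specimen index or id.
#' @return A k x 3 coordinate matrix.
#' @export
configuration <- function(dataset, i) {
  dataset$coords[, , i]
}
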