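test_that("all three dialects round-trip coordinates bit-identically", {
  set.seed(42)
  spec <- small_generator(3L)
  ds <- generate_study(spec, seed = 7L)
  for (dialect in c("csv_long", "tps", "morphologika")) {
    f <- tempfile(fileext = ".txt")
    write_landmarks(ds, f, dialect)
    back <- read_landmarks(f, dialect)
    expect_identical(unname(back$coords), unname(ds$coords),
                     label = dialect)
    expect_identical(dimnames(back$coords)[[3L]],
                     dimnames(ds$coords)[[3L]], label = dialect)
    unlink(f)
  }
})

test_that("csv_long preserves landmark names and order", {
  ds <- study_dataset(array(rnorm(18 * 3 * 2), c(18, 3, 2)))
  f <- tempfile(fileext = ".csv")
  write_landmarks(ds, f, "csv_long")
  back <- read_landmarks(f, "csv_long")
  expect_identical(back$schema$landmark_names,
                   molar_schema()$landmark_names)
  unlink(f)
})

test_that("malformed TPS files fail with a parse error naming the line", {
  f <- tempfile(fileext = ".tps")
  ## specimen declares 4 landmarks but supplies 3 rows
  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "ID=a"), f)
  expect_error(read_landmarks(f, "tps"), "parse error at line 5")
  ## missing ID line
  writeLines(c("LM3=2", "0 0 0", "1 0 0"), f)
  expect_error(read_landmarks(f, "tps"), "expected ID=")
  ## garbage header
  writeLines(c("LM=2", "0 0 0"), f)
  expect_error(read_landmarks(f, "tps"), "parse error at line 1")
  unlink(f)
})

test_that("mixed landmark counts are rejected as a schema error", {
  f <- tempfile(fileext = ".tps")
  writeLines(c("LM3=2", "0 0 0", "1 0 0", "ID=a",
               "LM3=3", "0 0 0", "1 0 0", "0 1 0", "ID=b"), f)
  expect_error(read_landmarks(f, "tps"), "schema error")
  unlink(f)
})

test_that("morphologika declared counts are enforced", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("[individuals]", "2", "[landmarks]", "2", "[dimensions]",
               "3", "[names]", "a", "b", "[rawpoints]",
               "'a", "0 0 0", "1 0 0",
               "'b", "0 0 0"), f)
  expect_error(read_landmarks(f, "morphologika"), "parse error")
  unlink(f)
})

test_that("classifier vocabulary is closed and violations name the rows", {
  rec <- data.frame(specimen_id = c("a", "b"),
                    group = c("control", "extreme"),
                    sex = c("F", "M"), stringsAsFactors = FALSE)
  expect_error(molarmorph:::validate_records(rec), "extreme")
  expect_error(molarmorph:::validate_records(rec), "rows 2")
  rec$group <- c("control", "severe")
  rec$sex <- c("female", "M")
  expect_error(molarmorph:::validate_records(rec), "rows 1")
  rec$sex <- c("F", "M")
  expect_silent(ok <- molarmorph:::validate_records(rec))
  expect_identical(ok$group, c("control", "severe"))
})

test_that("replicate labels must be present for all specimens or none", {
  rec <- data.frame(specimen_id = c("a", "b"),
                    scan_session = c(1L, NA), stringsAsFactors = FALSE)
  expect_error(molarmorph:::validate_records(rec), "all specimens or none")
})

test_that("classifier files round-trip and attach to datasets", {
  ds <- generate_study(small_generator(2L), seed = 3L)
  f <- tempfile(fileext = ".csv")
  write_classifiers(ds$records, f)
  rec <- read_classifiers(f)
  expect_identical(rec$group, ds$records$group)
  ds2 <- set_classifiers(ds, rec[sample(nrow(rec)), ])
  ## join is by specimen id, so order of the classifier table is irrelevant
  expect_identical(ds2$records$group, ds$records$group)
  unlink(f)
})

test_that("dataset validation enforces matching ids and finite coords", {
  coords <- array(rnorm(18 * 3 * 2), c(18, 3, 2),
                  dimnames = list(NULL, NULL, c("a", "b")))
  rec <- data.frame(specimen_id = c("a", "c"), stringsAsFactors = FALSE)
  expect_error(study_dataset(coords, rec), "same specimen ids")
  coords[1, 1, 1] <- NA
  expect_error(study_dataset(coords), "non-finite")
})

test_that("generated study carries the expected unbalanced cell counts", {
  ds <- generate_study(generator_spec(), seed = 11L)
  tab <- table(ds$records$group, ds$records$sex)
  expect_identical(as.vector(tab[c("control", "mild", "moderate",
                                   "severe"), c("F", "M")]),
                   c(20L, 20L, 20L, 19L, 20L, 20L, 19L, 15L))
  expect_identical(sum(tab), 153L)
})
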