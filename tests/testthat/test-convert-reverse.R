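test_that("ODM data types map back to canonical SPSS formats", {
  f <- function(...) map_datatype_to_format(...)$format
  expect_identical(format(f("float", 12L, 2L)), "F12.2")
  expect_identical(format(f("integer")), "F8")
  expect_identical(format(f("integer", 5L)), "F5")
  expect_identical(format(f("float")), "F8.2")
  expect_identical(format(f("string", 40L)), "A40")
  expect_identical(format(f("text")), "A255")
  expect_identical(format(f("date")), "DATE11")
  expect_identical(format(f("time")), "TIME8")
  expect_identical(format(f("datetime")), "DATETIME20")
  # minimal widening keeps decimals < width
  widened <- f("float", 2L, 4L)
  expect_true(widened$decimals < widened$width)
  expect_identical(widened$decimals, 4L)
  # unsupported datatypes fall back to text with a flag
  r <- map_datatype_to_format("boolean")
  expect_false(r$supported)
  expect_identical(format(r$format), "A255")
})

test_that("OIDs sanitise to valid, unique SPSS variable names", {
  reg <- odmconvert:::new_oid_registry()
  expect_identical(sanitize_variable_name("age", reg), "age")
  expect_identical(sanitize_variable_name("age", reg), "age_1")
  expect_identical(sanitize_variable_name("AGE", reg), "AGE_2")
  expect_identical(sanitize_variable_name("IT.weight kg", reg), "IT.weight_kg")
  expect_identical(sanitize_variable_name("1start", reg), "V_1start")
  long <- paste(rep("x", 70), collapse = "")
  out <- sanitize_variable_name(long, reg)
  expect_identical(nchar(out), 64L)
  out2 <- sanitize_variable_name(long, reg)
  expect_identical(nchar(out2), 64L)
  expect_false(identical(out, out2))
})

test_that("the sample conversion flattens back to 16+1 variables and 5 cases", {
  ds <- make_sample_dataset()
  res <- spss_to_odm(ds, convert_options(include_data = TRUE))
  rev <- odm_to_dataset(res$odm)
  expect_identical(length(rev$dataset$variables), 17L)
  expect_identical(nrow(rev$dataset$data), 5L)
  expect_identical(rev$dataset$variables[[1]]$name, "SUBJECTKEY")
  expect_identical(rev$dataset$data$SUBJECTKEY, as.character(1:5))
  expect_identical(nrow(validate_dataset(rev$dataset)), 0L)
  # reverse defaults: columns = 8, alignment by storage class, no
  # measure/role/missing
  v <- rev$dataset$variables[[3]]  # sex (after the key column and PID)
  expect_identical(v$columns, 8L)
  expect_null(v$measure)
  expect_null(v$missing)
  num_aligns <- vapply(rev$dataset$variables[-1], function(v)
    v$align, character(1))
  str_vars <- vapply(rev$dataset$variables[-1], function(v)
    v$format$code == "A", logical(1))
  expect_true(all(num_aligns[str_vars] == "left"))
  expect_true(all(num_aligns[!str_vars] == "right"))
})

test_that("a metadata-only document yields a zero-case dataset", {
  res <- spss_to_odm(make_sample_dataset())
  rev <- odm_to_dataset(res$odm)
  expect_identical(nrow(rev$dataset$data), 0L)
  expect_identical(length(rev$dataset$variables), 17L)
})

test_that("ISO calendar values parse back to epoch-seconds", {
  ds <- make_sample_dataset()
  res <- spss_to_odm(ds, convert_options(include_data = TRUE, subjectkey = "PID"))
  rev <- odm_to_dataset(res$odm, subject_column_name = "PID")$dataset
  expect_identical(rev$data$visit_date, ds$data$visit_date)
  expect_identical(rev$data$visit_time, ds$data$visit_time)
  expect_identical(rev$data$admission, ds$data$admission)
  # absent ItemData (the system-missing bmi cell) comes back system-missing
  expect_identical(is.na(rev$data$bmi), is.na(ds$data$bmi))
})

test_that("round trip is the identity on the mapped projection", {
  for (seed in c(1, 7, 23, 99)) {
    ds <- make_random_dataset(2L + seed %% 6L, 1L + seed %% 8L, seed,
                              mappable_only = TRUE)
    res <- spss_to_odm(ds, convert_options(include_data = TRUE,
                                           subjectkey = "PID"))
    rev <- odm_to_dataset(res$odm, subject_column_name = "PID")$dataset
    expect_roundtrip_equal(rev, ds, key = "PID", seed = seed)
  }
})

test_that("convert of a reverse conversion reproduces the first document", {
  ds <- make_random_dataset(5, 6, 31, mappable_only = TRUE)
  opts <- convert_options(include_data = TRUE, subjectkey = "PID",
                          timestamp = "2020-06-01T12:00:00",
                          file_oid = "ODM.fixed")
  first <- spss_to_odm(ds, opts)$odm
  rev <- odm_to_dataset(first, subject_column_name = "PID")$dataset
  second <- spss_to_odm(rev, opts)$odm
  expect_equal(second, first)
})

test_that("multi-event documents and duplicate item refs are refused", {
  res <- spss_to_odm(tiny_dataset())
  odm <- res$odm
  mdv <- odm$studies[[1]]$metadata_versions[[1]]

  two_events <- odm
  ev2 <- mdv$studyevent_defs[[1]]
  ev2$oid <- "SE.2"
  two_events$studies[[1]]$metadata_versions[[1]]$studyevent_defs <-
    c(mdv$studyevent_defs, list(ev2))
  two_events$studies[[1]]$metadata_versions[[1]]$protocol <-
    odm_protocol(list(odm_ref("SE.1", 1L), odm_ref("SE.2", 2L)))
  expect_error(odm_to_dataset(two_events), "SE.2")

  dup_ref <- odm
  ig <- mdv$itemgroup_defs[[1]]
  ig$item_refs <- c(ig$item_refs,
                    list(odm_ref(ig$item_refs[[1]]$oid,
                                 length(ig$item_refs) + 1L)))
  dup_ref$studies[[1]]$metadata_versions[[1]]$itemgroup_defs <- list(ig)
  expect_error(odm_to_dataset(dup_ref), "duplicate ItemRef")
})

test_that("reverse conversion insists on referential integrity", {
  res <- spss_to_odm(tiny_dataset())
  broken <- delete_itemdef(res$odm, "age")
  expect_error(odm_to_dataset(broken), "referential")
})
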