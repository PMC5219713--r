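test_that("print formats map to ODM data types per the mapping model", {
  m <- function(code, w, d = 0, ...) map_format_to_datatype(spss_format(code, w, d), ...)

  r <- m("A", 10)
  expect_identical(r[c("datatype", "length", "lossy")],
                   list(datatype = "string", length = 10L, lossy = FALSE))
  r <- m("F", 8, 0)
  expect_identical(r[c("datatype", "length", "lossy")],
                   list(datatype = "integer", length = 8L, lossy = FALSE))
  r <- m("F", 8, 2)
  expect_identical(r[c("datatype", "significant_digits")],
                   list(datatype = "float", significant_digits = 2L))
  r <- m("DOT", 12, 2)
  expect_identical(r$datatype, "float")
  expect_true(r$lossy)
  for (code in c("COMMA", "DOLLAR", "CC", "E", "PCT"))
    expect_identical(m(code, 10, 1)$datatype, "float")
  for (code in c("DATE", "ADATE", "EDATE", "SDATE", "JDATE")) {
    r <- m(code, 11)
    expect_identical(r$datatype, "date")
    expect_true(r$lossy)
  }
  expect_identical(m("TIME", 8)$datatype, "time")
  expect_identical(m("DATETIME", 20)$datatype, "datetime")
  for (code in c("DTIME", "WKYR", "WKDAY", "MONTH", "MOYR", "QYR")) {
    r <- m(code, 10)
    expect_identical(r$datatype, "string")
    expect_true(r$lossy)
  }
  # the string datatype is switchable to ODM "text"
  expect_identical(m("A", 5, opts = convert_options(string_datatype = "text"))$datatype,
                   "text")
})

test_that("OIDs follow the declared conventions with collision suffixes", {
  reg <- new_oid_registry()
  expect_identical(make_oid("item", "age", reg), "age")
  expect_identical(make_oid("codelist", "sex", reg), "CL.sex")
  expect_identical(make_oid("item", "age", reg), "age.1")
  expect_identical(make_oid("item", "age", reg), "age.2")
  reg2 <- new_oid_registry()
  expect_identical(make_oid("study", "whatever", reg2), "S.1")
  expect_identical(make_oid("mdv", "whatever", reg2), "MDV.1")
  expect_identical(make_oid("event", "x", reg2), "SE.1")
  expect_identical(make_oid("form", "x", reg2), "F.1")
  expect_identical(make_oid("itemgroup", "x", reg2), "IG.1")
})

test_that("build_metadata emits the default hierarchy with one ItemDef per variable", {
  ds <- make_sample_dataset()
  res <- build_metadata(ds)
  mdv <- first_mdv(res$odm)
  expect_identical(length(mdv$item_defs), 16L)
  expect_identical(length(mdv$studyevent_defs), 1L)
  expect_identical(length(mdv$form_defs), 1L)
  expect_identical(length(mdv$itemgroup_defs), 1L)
  expect_identical(length(mdv$itemgroup_defs[[1]]$item_refs), 16L)

  # subject-key column is excluded from item conversion
  res2 <- build_metadata(ds, convert_options(subjectkey = "PID"))
  expect_identical(length(first_mdv(res2$odm)$item_defs), 15L)
  expect_false("PID" %in% item_oids_of(res2$odm))

  expect_error(build_metadata(ds, convert_options(subjectkey = "pid")),
               "subjectkey")
})

test_that("value labels become code lists in dictionary order", {
  ds <- make_sample_dataset()
  res <- build_metadata(ds)
  mdv <- first_mdv(res$odm)
  cls <- stats::setNames(mdv$code_lists,
                         vapply(mdv$code_lists, `[[`, character(1), "oid"))
  expect_true("CL.sex" %in% names(cls))
  sex_cl <- cls[["CL.sex"]]
  expect_identical(vapply(sex_cl$items, `[[`, character(1), "coded_value"),
                   c("1", "2"))
  expect_identical(vapply(sex_cl$items, function(i) i$decode$text, character(1)),
                   c("male", "female"))
  sex_item <- Filter(function(d) d$oid == "sex", mdv$item_defs)[[1]]
  expect_identical(sex_item$codelist_oid, "CL.sex")
  # one code list per labelled variable only
  expect_identical(length(mdv$code_lists), 1L)
})

test_that("dropped attributes and lossy mappings are warned about", {
  ds <- spss_dataset(
    list(spss_variable("x", spss_format("F", 8), missing = list(values = 9),
                       measure = "scale", role = "input")),
    data.frame(x = 1))
  res <- spss_to_odm(ds)
  w <- res$report$warnings
  expect_identical(sum(w$category == "dropped_attribute" & w$variable == "x"), 3L)

  ds2 <- spss_dataset(
    list(spss_variable("y", spss_format("DOT", 10, 2), columns = 8,
                       align = "right")),
    data.frame(y = 1.5))
  w2 <- spss_to_odm(ds2)$report$warnings
  expect_identical(sum(w2$category == "lossy_type"), 1L)
  expect_identical(sum(w2$category == "dropped_display_format"), 2L)
})

test_that("labels drive ItemDef names and Question text, with name fallback", {
  ds <- spss_dataset(
    list(spss_variable("lab", spss_format("F", 3), label = "Has label"),
         spss_variable("nolab", spss_format("F", 3))),
    data.frame(lab = 1, nolab = 2))
  mdv <- first_mdv(build_metadata(ds)$odm)
  expect_identical(mdv$item_defs[[1]]$name, "Has label")
  expect_identical(mdv$item_defs[[1]]$question$text, "Has label")
  expect_identical(mdv$item_defs[[2]]$name, "nolab")
  expect_identical(mdv$item_defs[[2]]$question$text, "nolab")
})

test_that("the lang option controls TranslatedText language attributes", {
  ds <- tiny_dataset()
  with_lang <- first_mdv(build_metadata(ds, convert_options(lang = "de-DE"))$odm)
  expect_identical(with_lang$item_defs[[1]]$question$lang, "de-DE")
  without <- first_mdv(build_metadata(ds)$odm)
  expect_null(without$item_defs[[1]]$question$lang)
})

test_that("a zero-variable dataset yields a valid metadata-only file", {
  ds <- spss_dataset(list(), data.frame())
  res <- spss_to_odm(ds)
  expect_identical(length(first_mdv(res$odm)$item_defs), 0L)
  expect_identical(sum(check_structure(res$odm)$severity == "error"), 0L)
  expect_identical(sum(check_referential_integrity(res$odm)$severity == "error"), 0L)
})

test_that("SPSS epoch-seconds render to ISO 8601 calendar strings", {
  expect_identical(spss_seconds_to_iso(0, "date"), "1582-10-14")
  expect_identical(spss_seconds_to_iso(86400, "date"), "1582-10-15")
  expect_identical(spss_seconds_to_iso(c(0, 3661, 86399), "time"),
                   c("00:00:00", "01:01:01", "23:59:59"))
  expect_error(spss_seconds_to_iso(86400, "time"), "out of range")
  expect_error(spss_seconds_to_iso(-1, "time"), "out of range")
  # fractional seconds are truncated
  expect_identical(spss_seconds_to_iso(3661.9, "time"), "01:01:01")
  d <- (as.numeric(as.Date("2014-03-12")) - as.numeric(as.Date("1582-10-14"))) * 86400
  expect_identical(spss_seconds_to_iso(d, "date"), "2014-03-12")
  expect_identical(spss_seconds_to_iso(d + 8 * 3600 + 61, "datetime"),
                   "2014-03-12T08:01:01")
})

test_that("date arithmetic agrees with an independent calendar over 1900-2100", {
  set.seed(11)
  lo <- as.numeric(as.Date("1900-01-01"))
  hi <- as.numeric(as.Date("2100-12-31"))
  days <- sample(lo:hi, 1000, replace = TRUE)
  secs <- (days - as.numeric(as.Date("1582-10-14"))) * 86400
  expect_identical(spss_seconds_to_iso(secs, "date"),
                   format(as.Date(days, origin = "1970-01-01"), "%Y-%m-%d"))
  # and back
  expect_identical(iso_to_spss_seconds(spss_seconds_to_iso(secs, "date"), "date"),
                   secs)
})

test_that("cell values render canonically", {
  expect_identical(convert_value(42.0, spss_format("F", 8), "integer"), "42")
  expect_identical(convert_value(NA_real_, spss_format("F", 8, 2), "float"),
                   NA_character_)
  # grouped formats render as plain decimal literals
  expect_identical(convert_value(1234567.25, spss_format("DOT", 12, 2), "float"),
                   "1234567.25")
  expect_identical(convert_value(0.1, spss_format("F", 8, 2), "float"), "0.1")
  # floats round-trip exactly through their rendering
  set.seed(3)
  x <- c(stats::runif(200) * 1e6, 1/3, 2/7, .Machine$double.eps)
  expect_identical(as.numeric(odmconvert:::render_double(x)), x)
  expect_false(any(grepl("[eE,]", odmconvert:::render_double(x))))
})

test_that("subject keys default to an incrementing number", {
  ds <- make_sample_dataset()
  sk <- extract_subject_keys(ds)
  expect_identical(sk$keys, c("1", "2", "3", "4", "5"))
  expect_identical(sk$excluded_index, NA_integer_)

  sk2 <- extract_subject_keys(ds, "PID")
  expect_identical(sk2$keys, c("P1", "P2", "P3", "P4", "P5"))
  expect_identical(sk2$excluded_index, 1L)
  expect_error(extract_subject_keys(ds, "pid"), "case-sensitive")
})

test_that("duplicate subject keys follow the chosen policy", {
  ds <- spss_dataset(
    list(spss_variable("PID", spss_format("A", 5)),
         spss_variable("x", spss_format("F", 3))),
    data.frame(PID = c("P1", "P1", "P2", "P1"), x = c(1, 2, 3, 4),
               stringsAsFactors = FALSE))
  expect_error(extract_subject_keys(ds, "PID"), "multiple cases per patient")
  sk <- extract_subject_keys(ds, "PID", duplicate_key_policy = "suffix")
  expect_identical(sk$keys, c("P1", "P1.2", "P2", "P1.3"))
})

test_that("clinical data mirrors the case table", {
  ds <- make_sample_dataset()
  res <- spss_to_odm(ds, convert_options(include_data = TRUE, subjectkey = "PID"))
  cd <- res$odm$clinical_data
  expect_identical(length(cd$subjects), 5L)
  expect_identical(vapply(cd$subjects, `[[`, character(1), "subject_key"),
                   c("P1", "P2", "P3", "P4", "P5"))
  # case 3 has one system-missing cell (bmi) out of 15 converted variables
  items3 <- cd$subjects[[3]]$events[[1]]$forms[[1]]$itemgroups[[1]]$items
  expect_identical(nrow(items3), 14L)
  expect_false("bmi" %in% items3$item_oid)
  items1 <- cd$subjects[[1]]$events[[1]]$forms[[1]]$itemgroups[[1]]$items
  expect_identical(nrow(items1), 15L)
  expect_identical(items1$value[items1$item_oid == "visit_date"], "2014-03-12")
  expect_identical(items1$value[items1$item_oid == "visit_time"], "08:15:00")

  # user-missing codes in the data are exported verbatim
  items4 <- cd$subjects[[4]]$events[[1]]$forms[[1]]$itemgroups[[1]]$items
  expect_identical(items4$value[items4$item_oid == "sex"], "9")
})

test_that("metadata is always exported; clinical data only on request", {
  ds <- tiny_dataset()
  res <- spss_to_odm(ds)
  expect_null(res$odm$clinical_data)
  res2 <- spss_to_odm(ds, convert_options(include_data = TRUE))
  expect_identical(length(res2$odm$clinical_data$subjects), 2L)
  # zero-case dataset with data requested: empty ClinicalData
  ds0 <- make_random_dataset(2, 0, 5)
  res0 <- spss_to_odm(ds0, convert_options(include_data = TRUE))
  expect_identical(length(res0$odm$clinical_data$subjects), 0L)
})

test_that("conservation invariants hold across seeded conversions", {
  for (seed in 1:10) {
    ds <- make_random_dataset(2L + seed %% 5L, seed %% 6L, seed,
                              mappable_only = TRUE)
    res <- spss_to_odm(ds, convert_options(include_data = TRUE,
                                           subjectkey = "PID"))
    mdv <- first_mdv(res$odm)
    expect_identical(length(mdv$item_defs), length(ds$variables) - 1L)
    expect_identical(length(res$odm$clinical_data$subjects), nrow(ds$data))
    n_labelled <- sum(vapply(ds$variables[-1], function(v)
      !is.null(v$value_labels) && nrow(v$value_labels) > 0, logical(1)))
    expect_identical(length(mdv$code_lists), n_labelled)
  }
})

test_that("the language validator implements the RFC 3066 grammar", {
  for (good in c("en", "de-DE", "x-klingon", "EN", "abcdefgh",
                 "zh-Hant-TW", "a-1", "en-123"))
    expect_true(validate_lang(good))
  for (bad in c("english language", "", "a--b", "-en", "en-", "abcdefghi",
                "de_DE", "en-toolongsubtag9", "e n"))
    expect_error(validate_lang(bad), "RFC 3066")

  # property: never accepts what the grammar rejects (generated cases)
  set.seed(7)
  alphabet <- c(letters, LETTERS, 0:9, "-", "_", " ", ".")
  for (i in 1:200) {
    cand <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE),
                  collapse = "")
    grammar_ok <- grepl("^[A-Za-z]{1,8}(-[A-Za-z0-9]{1,8})*$", cand)
    got <- tryCatch({ validate_lang(cand); TRUE }, error = function(e) FALSE)
    expect_identical(got, grammar_ok, info = cand)
  }
})
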