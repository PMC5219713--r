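# Synthetic dataset generators.
#
# make_sample_dataset() is the deterministic 16-variable / 5-case file
# exercising every major print-format family; make_random_dataset() emits
# seeded datasets up to clinical-registry scale (hundreds of variables,
# thousands of cases) for property tests and scale smoke tests.

# Raw SPSS value for a calendar date: seconds since 1582-10-14.
spss_date_seconds <- function(y, m, d) {
  (days_from_civil(y, m, d) - SPSS_EPOCH_DAYS) * 86400
}

#' Deterministic sample dataset covering all major SPSS data types
#'
#' Sixteen variables over five cases: a string patient identifier (`PID`),
#' a coded variable with value labels and a user-missing code, plain and
#' decimal numerics, grouped/currency/scientific numerics, five calendar
#' date formats, a clock time, a timestamp, and two rarely used calendar
#' renderings (`WKYR`, `WKDAY`) that have no XML counterpart. One cell is
#' system-missing. Repeated calls return the identical dataset.
#'
#' @return An [spss_dataset] with 16 variables and 5 cases.
#' @export
make_sample_dataset <- function() {
  v <- function(...) spss_variable(...)
  f <- spss_format
  variables <- list(
    v("PID", f("A", 5), label = "Patient identifier"),
    v("sex", f("F", 1), label = "Sex",
      value_labels = data.frame(value = c(1, 2),
                                label = c("male", "female"),
                                stringsAsFactors = FALSE),
      missing = list(values = 9), measure = "nominal", role = "input",
      columns = 8L, align = "right"),
    v("bmi", f("F", 6, 2), label = "Body mass index", measure = "scale"),
    v("income", f("COMMA", 12, 2), label = "Yearly income"),
    v("weight", f("DOT", 10, 2), label = "Weight in kg"),
    v("cost", f("DOLLAR", 10, 2), label = "Treatment cost"),
    v("ratio", f("E", 10, 3), label = "Lab ratio"),
    v("visit_date", f("DATE", 11), label = "Date of visit"),
    v("birth_date", f("ADATE", 10), label = "Date of birth"),
    v("exam_date", f("EDATE", 10), label = "Date of examination"),
    v("reg_date", f("SDATE", 10), label = "Date of registration"),
    v("julian_day", f("JDATE", 7), label = "Julian visit day"),
    v("visit_time", f("TIME", 8), label = "Time of visit"),
    v("admission", f("DATETIME", 20), label = "Admission timestamp"),
    v("week_year", f("WKYR", 10), label = "Week and year"),
    v("weekday", f("WKDAY", 9), label = "Day of the week"))

  d <- spss_date_seconds
  data <- data.frame(
    PID = c("P1", "P2", "P3", "P4", "P5"),
    sex = c(1, 2, 1, 9, 2),
    bmi = c(24.5, 31.02, NA, 19.8, 27.33),  # one system-missing cell
    income = c(42000.5, 39500, 51250.75, 28000, 61999.99),
    weight = c(80.5, 92.3, 61.2, 70, 85.1),
    cost = c(1250.4, 980, 2100.55, 430.2, 1775),
    ratio = c(0.00125, 1340, 2.5, 0.75, 12.125),
    visit_date = c(d(2014, 3, 12), d(2014, 5, 2), d(2014, 6, 30),
                   d(2014, 8, 14), d(2014, 12, 24)),
    birth_date = c(d(1960, 1, 15), d(1975, 11, 3), d(1982, 7, 21),
                   d(1990, 2, 28), d(1955, 9, 9)),
    exam_date = c(d(2014, 3, 13), d(2014, 5, 3), d(2014, 7, 1),
                  d(2014, 8, 15), d(2014, 12, 27)),
    reg_date = c(d(2013, 12, 1), d(2014, 1, 20), d(2014, 2, 11),
                 d(2014, 3, 5), d(2014, 4, 18)),
    julian_day = c(d(2014, 3, 12), d(2014, 5, 2), d(2014, 6, 30),
                   d(2014, 8, 14), d(2014, 12, 24)),
    visit_time = c(8 * 3600 + 15 * 60, 9 * 3600 + 30 * 60, 11 * 3600 + 5 * 60,
                   14 * 3600 + 45 * 60 + 30, 16 * 3600),
    admission = c(d(2014, 3, 12) + 8 * 3600, d(2014, 5, 2) + 9 * 3600 + 1800,
                  d(2014, 6, 30) + 11 * 3600, d(2014, 8, 14) + 14 * 3600,
                  d(2014, 12, 24) + 16 * 3600 + 60),
    week_year = c(d(2014, 3, 10), d(2014, 4, 28), d(2014, 6, 30),
                  d(2014, 8, 11), d(2014, 12, 22)),
    weekday = c(4, 6, 2, 5, 4),
    stringsAsFactors = FALSE)
  spss_dataset(variables, data, source_name = "sample")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Seeded random dataset generator
#'
#' Emulates clinical-registry datasets of arbitrary size: unique valid
#' variable names, roughly 20% of variables carrying value labels, 10%
#' a user-missing specification, 5% system-missing cells, and (unless
#' `mappable_only`) every print-format code reachable. The same seed always
#' yields the identical dataset, and every generated dataset passes
#' [validate_dataset()].
#'
#' @param n_vars Number of variables (>= 1).
#' @param n_cases Number of cases (>= 0).
#' @param seed Integer seed.
#' @param mappable_only Restrict to formats that survive a forward/reverse
#'   round trip unchanged (`A`, `F`, `DATE11`, `TIME8`, `DATETIME20`) and
#'   include a unique `PID` identifier column as the first variable.
#' @return An [spss_dataset].
#' @export
make_random_dataset <- function(n_vars, n_cases, seed, mappable_only = FALSE) {
  stopifnot(n_vars >= 1, n_cases >= 0)
  with_seed(seed, {
    variables <- vector("list", n_vars)
    cols <- vector("list", n_vars)

    mappable_formats <- function() {
      k <- sample(5L, 1L)
      switch(k,
        spss_format("A", sample(2:12, 1)),
        spss_format("F", sample(4:10, 1), 0L),
        {w <- sample(6:12, 1); spss_format("F", w, sample(seq_len(min(4, w - 2)), 1))},
        spss_format("DATE", 11L),
        sample(list(spss_format("TIME", 8L), spss_format("DATETIME", 20L)), 1)[[1]])
    }
    any_format <- function() {
      code <- sample(spss_format_codes, 1)
      switch(code,
        A = spss_format("A", sample(1:12, 1)),
        F = {w <- sample(4:10, 1); spss_format("F", w, sample(0:min(3, w - 2), 1))},
        COMMA = , DOT = , DOLLAR = , CC = , PCT =
          spss_format(code, sample(8:14, 1), sample(0:2, 1)),
        E = spss_format("E", sample(9:14, 1), sample(1:3, 1)),
        DATE = spss_format("DATE", 11L),
        ADATE = , EDATE = , SDATE = spss_format(code, 10L),
        JDATE = spss_format("JDATE", 7L),
        TIME = spss_format("TIME", 8L),
        DTIME = spss_format("DTIME", 13L, 0L),
        DATETIME = spss_format("DATETIME", 20L),
        WKYR = spss_format("WKYR", 10L),
        WKDAY = spss_format("WKDAY", 9L),
        MONTH = spss_format("MONTH", 8L),
        MOYR = spss_format("MOYR", 8L),
        QYR = spss_format("QYR", 8L))
    }
    rand_word <- function(n = 1, len = 6)
      vapply(seq_len(n), function(i) paste(
        sample(letters, sample(2:len, 1), replace = TRUE), collapse = ""),
        character(1))
    date_pool_days <- days_from_civil(1900, 1, 1):days_from_civil(2100, 12, 31)

    for (i in seq_len(n_vars)) {
      if (mappable_only && i == 1L) {
        wid <- max(8L, nchar(as.character(n_cases)) + 1L)
        variables[[i]] <- spss_variable("PID", spss_format("A", wid),
                                        label = "Subject identifier")
        cols[[i]] <- if (n_cases) sprintf("P%d", seq_len(n_cases)) else character(0)
        next
      }
      fmt <- if (mappable_only) mappable_formats() else any_format()
      name <- paste0("V", i, "_", rand_word(1, 5))
      label <- if (mappable_only || stats::runif(1) < 0.8)
        paste(rand_word(sample(2:4, 1)), collapse = " ")

      numeric_plain <- fmt$code %in% c("F", "COMMA", "DOT", "DOLLAR", "CC",
                                       "E", "PCT")
      vl <- NULL
      if (stats::runif(1) < 0.2) {
        k <- sample(2:5, 1)
        vl <- if (identical(fmt$code, "A"))
          data.frame(value = paste0(substr(rand_word(k, 4), 1, fmt$width), seq_len(k)),
                     label = rand_word(k), stringsAsFactors = FALSE)
        else if (numeric_plain && fmt$decimals == 0L)
          data.frame(value = as.numeric(seq_len(k)), label = rand_word(k),
                     stringsAsFactors = FALSE)
        else NULL
        if (!is.null(vl) && identical(fmt$code, "A") &&
            anyDuplicated(vl$value)) vl <- NULL
      }
      miss <- if (numeric_plain && stats::runif(1) < 0.1)
        list(values = c(-99)) else NULL
      measure <- if (stats::runif(1) < 0.3)
        sample(c("nominal", "ordinal", "scale"), 1)
      role <- if (stats::runif(1) < 0.2)
        sample(c("input", "target", "both", "none"), 1)

      variables[[i]] <- spss_variable(name, fmt, label = label,
                                      value_labels = vl, missing = miss,
                                      measure = measure, role = role)

      col <- switch(fmt$code,
        A = {
          s <- rand_word(n_cases, max(2L, min(fmt$width, 10L)))
          substr(s, 1, fmt$width)
        },
        TIME = as.numeric(sample(0:86399, n_cases, replace = TRUE)),
        DTIME = round(stats::runif(n_cases, 0, 86400 * 30)),
        DATETIME = (sample(date_pool_days, n_cases, replace = TRUE) -
                      SPSS_EPOCH_DAYS) * 86400 +
                   sample(0:86399, n_cases, replace = TRUE),
        DATE = , ADATE = , EDATE = , SDATE = , JDATE = , WKYR = , MOYR = ,
        QYR = (sample(date_pool_days, n_cases, replace = TRUE) -
                 SPSS_EPOCH_DAYS) * 86400,
        WKDAY = as.numeric(sample(1:7, n_cases, replace = TRUE)),
        MONTH = as.numeric(sample(1:12, n_cases, replace = TRUE)),
        {
          if (fmt$decimals == 0L)
            as.numeric(sample.int(10^min(fmt$width - 1L, 6L), n_cases,
                                  replace = TRUE))
          else round(stats::runif(n_cases, 0, 10^min(fmt$width - fmt$decimals - 2L, 5L)),
                     fmt$decimals)
        })
      if (!identical(fmt$code, "A") && n_cases > 0) {
        mis <- stats::runif(n_cases) < 0.05
        col[mis] <- NA_real_
      }
      cols[[i]] <- col
    }
    names(cols) <- vapply(variables, `[[`, character(1), "name")
    data <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
    if (n_cases == 0L)
      data <- as.data.frame(lapply(cols, function(x) x[0]),
                            stringsAsFactors = FALSE, optional = TRUE)
    spss_dataset(variables, data,
                 source_name = sprintf("synthetic_%d", seed))
  })
}
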