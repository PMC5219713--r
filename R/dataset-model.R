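# In-memory model of an SPSS-style dataset: an ordered variable dictionary
# plus rectangular case data. Cases live in a data.frame whose columns are
# character for string (A) variables and double for everything else; NA is
# the system-missing sentinel (distinct from "" on string variables).

#' SPSS print-format codes understood by the package
#'
#' The print format of a variable determines its storage class (string for
#' `A`, numeric otherwise) and how values are displayed: plain numbers
#' (`F`), grouped/currency/scientific numbers (`COMMA`, `DOT`, `DOLLAR`,
#' `CC`, `E`, `PCT`), calendar dates in several national display orders
#' (`DATE`, `ADATE`, `EDATE`, `SDATE`, `JDATE`), clock times and timestamps
#' (`TIME`, `DTIME`, `DATETIME`), and rarely used calendar renderings
#' (`WKYR`, `WKDAY`, `MONTH`, `MOYR`, `QYR`).
#'
#' @format A character vector of format codes.
#' @export
spss_format_codes <- c(
  "F", "A", "COMMA", "DOT", "DOLLAR", "CC", "E", "PCT",
  "DATE", "ADATE", "EDATE", "SDATE", "JDATE",
  "TIME", "DTIME", "DATETIME", "WKYR", "WKDAY", "MONTH", "MOYR", "QYR"
)

# Codes on which a decimals component is meaningful.
decimal_capable_codes <- c("F", "COMMA", "DOT", "DOLLAR", "CC", "E", "PCT",
                           "TIME", "DTIME", "DATETIME")

#' Construct an SPSS print-format specification
#'
#' @param code One of [spss_format_codes], e.g. `"F"`, `"A"`, `"DATE"`.
#' @param width Display width in characters (>= 1).
#' @param decimals Number of decimal places; must be 0 for codes that do not
#'   carry decimals (dates, `A`, ...) and strictly less than `width`.
#' @return An object of class `spss_format`.
#' @examples
#' spss_format("F", 8, 2)   # F8.2
#' spss_format("A", 10)     # A10
#' @export
spss_format <- function(code, width, decimals = 0L) {
  stopifnot(is.character(code), length(code) == 1L)
  structure(list(code = code, width = as.integer(width),
                 decimals = as.integer(decimals)),
            class = "spss_format")
}

#' @export
format.spss_format <- function(x, ...) {
  if (x$decimals > 0) sprintf("%s%d.%d", x$code, x$width, x$decimals)
  else sprintf("%s%d", x$code, x$width)
}

#' @export
print.spss_format <- function(x, ...) {
  cat("<spss_format ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Construct an SPSS variable definition
#'
#' Captures everything the SPSS dictionary stores about one variable: its
#' name, descriptive label, print format, value labels (permissible coded
#' values with human-readable decodes), user-missing specification, and the
#' statistical/display attributes `measure`, `role`, `columns` and `align`.
#' The last five are never representable in ODM; they are stored here so the
#' information loss of a conversion is measurable.
#'
#' @param name Variable name (<= 64 characters, starts with a letter or one
#'   of `@ # $`, no whitespace).
#' @param format An [spss_format] object.
#' @param label Optional descriptive label.
#' @param value_labels Optional `data.frame` with columns `value` and
#'   `label`; `value` is numeric for numeric formats and character for `A`.
#' @param missing Optional user-missing specification: a list with either
#'   `values` (up to 3 discrete codes) or `range = c(lo, hi)` plus at most
#'   one discrete `values` entry.
#' @param measure Optional: `"nominal"`, `"ordinal"` or `"scale"`.
#' @param role Optional: one of `"input"`, `"target"`, `"both"`, `"none"`,
#'   `"partition"`, `"split"`.
#' @param columns Optional display column width (positive integer).
#' @param align Optional: `"left"`, `"right"` or `"center"`.
#' @return An object of class `spss_variable`.
#' @export
spss_variable <- function(name, format, label = NULL, value_labels = NULL,
                          missing = NULL, measure = NULL, role = NULL,
                          columns = NULL, align = NULL) {
  if (!inherits(format, "spss_format"))
    stop("`format` must be an spss_format object", call. = FALSE)
  if (!is.null(value_labels)) {
    value_labels <- as.data.frame(value_labels, stringsAsFactors = FALSE)
    stopifnot(all(c("value", "label") %in% names(value_labels)))
  }
  structure(list(name = name, label = label, format = format,
                 value_labels = value_labels, missing = missing,
                 measure = measure, role = role,
                 columns = if (!is.null(columns)) as.integer(columns),
                 align = align),
            class = "spss_variable")
}

#' Construct an SPSS-style dataset
#'
#' Light on checks by design: structurally questionable datasets can be
#' built and then inspected with [validate_dataset()], which reports issues
#' as data rather than refusing construction.
#'
#' @param variables List of [spss_variable] definitions, in column order.
#' @param data A `data.frame` of cases, one row per case, columns in
#'   variable order; character columns for `A` variables, double otherwise.
#'   `NA` is the system-missing sentinel.
#' @param source_name Name describing where the dataset came from.
#' @return An object of class `spss_dataset`.
#' @examples
#' ds <- spss_dataset(
#'   list(spss_variable("PID", spss_format("A", 5)),
#'        spss_variable("age", spss_format("F", 3))),
#'   data.frame(PID = c("P1", "P2"), age = c(34, 57)))
#' validate_dataset(ds)
#' @export
spss_dataset <- function(variables, data, source_name = "dataset") {
  stopifnot(is.list(variables), is.data.frame(data))
  structure(list(source_name = source_name, variables = variables,
                 data = data),
            class = "spss_dataset")
}

#' @export
print.spss_dataset <- function(x, ...) {
  cat(sprintf("<spss_dataset '%s': %d variables, %d cases>\n",
              x$source_name, length(x$variables), nrow(x$data)))
  for (v in x$variables[seq_len(min(10L, length(x$variables)))]) {
    cat(sprintf("  %-16s %-12s %s\n", v$name, format(v$format),
                v$label %||% ""))
  }
  if (length(x$variables) > 10) cat("  ...\n")
  invisible(x)
}

valid_spss_name <- function(name) {
  nzchar(name) &&
    nchar(name) <= 64L &&
    grepl("^[A-Za-z@#$]", name) &&
    !grepl("[[:space:]]", name)
}

#' Validate an SPSS-style dataset
#'
#' Checks the dictionary and case data against the SPSS system-file
#' conventions: variable names are non-empty, at most 64 characters, start
#' with a letter or `@ # $`, contain no whitespace, and are unique under
#' case-insensitive comparison; print formats are well-formed; case columns
#' match the dictionary in count, order and storage class; value-label keys
#' are type-compatible with the format. Issues are returned as data, never
#' thrown, and the dataset is never modified.
#'
#' @param ds An [spss_dataset].
#' @return A `data.frame` of issues with columns `severity`, `locus`,
#'   `message`; zero rows when all invariants hold.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "spss_dataset"))
  issues <- new_issue_frame()
  nv <- length(ds$variables)

  names_seen <- character(0)
  for (i in seq_len(nv)) {
    v <- ds$variables[[i]]
    loc <- sprintf("variable %d (%s)", i, v$name %||% "")
    if (is.null(v$name) || !nzchar(v$name)) {
      issues <- add_issue(issues, "error", loc, "variable name is empty")
    } else {
      if (nchar(v$name) > 64L)
        issues <- add_issue(issues, "error", loc, sprintf(
          "variable name has %d characters; SPSS names are limited to 64 characters",
          nchar(v$name)))
      if (!grepl("^[A-Za-z@#$]", v$name))
        issues <- add_issue(issues, "error", loc,
                            "variable name must start with a letter or one of @ # $")
      if (grepl("[[:space:]]", v$name))
        issues <- add_issue(issues, "error", loc,
                            "variable name contains whitespace")
      if (tolower(v$name) %in% names_seen)
        issues <- add_issue(issues, "error", loc, sprintf(
          "duplicate variable name '%s' (names are unique case-insensitively)",
          v$name))
      names_seen <- c(names_seen, tolower(v$name))
    }

    f <- v$format
    if (!inherits(f, "spss_format") || !(f$code %in% spss_format_codes)) {
      issues <- add_issue(issues, "error", loc,
                          sprintf("unknown format code '%s'",
                                  if (inherits(f, "spss_format")) f$code else "<none>"))
    } else {
      if (f$width < 1L)
        issues <- add_issue(issues, "error", loc, "format width must be >= 1")
      if (f$decimals < 0L)
        issues <- add_issue(issues, "error", loc, "format decimals must be >= 0")
      if (f$decimals >= f$width && f$width >= 1L)
        issues <- add_issue(issues, "error", loc,
                            "format decimals must be smaller than width")
      if (f$decimals > 0L && !(f$code %in% decimal_capable_codes))
        issues <- add_issue(issues, "error", loc, sprintf(
          "format %s does not carry decimals", f$code))
    }

    if (!is.null(v$value_labels) && nrow(v$value_labels) > 0 &&
        inherits(f, "spss_format")) {
      want_char <- identical(f$code, "A")
      got_char <- is.character(v$value_labels$value)
      if (want_char != got_char)
        issues <- add_issue(issues, "error", loc, sprintf(
          "value-label keys must be %s for format %s",
          if (want_char) "character" else "numeric", f$code))
      if (anyDuplicated(v$value_labels$value))
        issues <- add_issue(issues, "error", loc, "duplicate value-label keys")
    }

    if (!is.null(v$missing)) {
      nval <- length(v$missing$values %||% numeric(0))
      has_range <- !is.null(v$missing$range)
      if (has_range && (length(v$missing$range) != 2L || nval > 1L))
        issues <- add_issue(issues, "error", loc,
                            "missing range must be c(lo, hi) with at most one discrete value")
      if (!has_range && (nval < 1L || nval > 3L))
        issues <- add_issue(issues, "error", loc,
                            "discrete missing specification takes 1 to 3 values")
    }
  }

  # rectangularity: columns must match the dictionary one-to-one, in order
  if (ncol(ds$data) != nv) {
    issues <- add_issue(issues, "error", "cases", sprintf(
      "case table has %d columns but the dictionary defines %d variables",
      ncol(ds$data), nv))
  } else if (nv > 0) {
    var_names <- vapply(ds$variables, function(v) v$name %||% "", character(1))
    bad <- which(names(ds$data) != var_names)
    for (j in bad)
      issues <- add_issue(issues, "error", sprintf("column %d", j), sprintf(
        "column name '%s' does not match variable name '%s'",
        names(ds$data)[j], var_names[j]))
    for (j in seq_len(nv)) {
      f <- ds$variables[[j]]$format
      if (!inherits(f, "spss_format")) next
      col <- ds$data[[j]]
      if (identical(f$code, "A")) {
        if (!is.character(col))
          issues <- add_issue(issues, "error", sprintf("column %d (%s)", j, var_names[j]),
                              "string (A) variable requires a character column")
      } else if (!is.numeric(col)) {
        issues <- add_issue(issues, "error", sprintf("column %d (%s)", j, var_names[j]),
                            "numeric variable requires a numeric column")
      }
    }
  }
  issues
}

#' Find a variable by name (case-sensitive)
#'
#' SPSS subject-identifier columns are matched case-sensitively, so `"PID"`
#' and `"pid"` are different lookups even though variable names must be
#' unique case-insensitively.
#'
#' @param ds An [spss_dataset].
#' @param name Variable name to look for.
#' @return The 1-based index of the variable, or `NA_integer_` if absent.
#' @export
find_variable <- function(ds, name) {
  var_names <- vapply(ds$variables, function(v) v$name %||% "", character(1))
  idx <- match(name, var_names)
  if (is.na(idx)) NA_integer_ else as.integer(idx)
}
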