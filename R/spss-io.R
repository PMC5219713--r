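# Dataset I/O.
#
# Two backends: (a) the portable plain-text dialect (JSON variable
# dictionary + RFC 4180 CSV case data) that round-trips a dataset exactly
# and needs no SPSS installation; (b) binary .sav reading through
# foreign::read.spss, which exposes only part of the dictionary (no print
# formats, measure, role, columns, align), so formats are inferred and the
# degradation is reported per variable. No .sav writer is installed in R;
# write_sav raises a capability error pointing at the portable dialect.

variable_to_portable <- function(v) {
  list(name = v$name,
       label = v$label,
       format = list(code = v$format$code, width = v$format$width,
                     decimals = v$format$decimals),
       value_labels = if (!is.null(v$value_labels) && nrow(v$value_labels))
         lapply(seq_len(nrow(v$value_labels)), function(i)
           list(value = v$value_labels$value[i],
                label = v$value_labels$label[i]))
       else list(),
       missing = v$missing,
       measure = v$measure, role = v$role,
       columns = v$columns, align = v$align)
}

portable_to_variable <- function(rec) {
  vl <- NULL
  if (length(rec$value_labels)) {
    vals <- lapply(rec$value_labels, `[[`, "value")
    labs <- vapply(rec$value_labels, function(x) as.character(x$label),
                   character(1))
    vl <- data.frame(
      value = if (is.character(vals[[1]])) vapply(vals, as.character, character(1))
              else vapply(vals, as.numeric, numeric(1)),
      label = labs, stringsAsFactors = FALSE)
  }
  missing <- rec$missing
  if (!is.null(missing)) {
    if (!is.null(missing$values)) missing$values <- as.numeric(unlist(missing$values))
    if (!is.null(missing$range)) missing$range <- as.numeric(unlist(missing$range))
  }
  spss_variable(
    rec$name,
    spss_format(rec$format$code, rec$format$width, rec$format$decimals),
    label = if (!is.null(rec$label)) as.character(rec$label),
    value_labels = vl, missing = missing,
    measure = rec$measure, role = rec$role,
    columns = rec$columns, align = rec$align)
}

#' Write a dataset in the portable plain-text dialect
#'
#' The dictionary goes to JSON, the cases to RFC 4180 CSV (comma separator,
#' double-quote quoting, UTF-8, mandatory header row matching the variable
#' names in order). Numeric cells are written as shortest round-tripping
#' decimals, so [read_portable()] recovers them bit-identically; empty CSV
#' cells denote system-missing for numeric variables and the empty string
#' for string variables.
#'
#' @param ds A valid [spss_dataset].
#' @param dict_path Path for the JSON dictionary.
#' @param data_path Path for the CSV case data.
#' @return Invisibly, the two paths.
#' @export
write_portable <- function(ds, dict_path, data_path) {
  issues <- validate_dataset(ds)
  if (nrow(issues))
    stop(sprintf("refusing to write an invalid dataset (%d issue(s)); first: %s",
                 nrow(issues), issues$message[1]), call. = FALSE)
  dict <- list(source_name = ds$source_name,
               variables = lapply(ds$variables, variable_to_portable))
  jsonlite::write_json(dict, dict_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  cols <- lapply(seq_along(ds$variables), function(j) {
    col <- ds$data[[j]]
    if (is.character(col)) ifelse(is.na(col), "", col)
    else ifelse(is.na(col), "", render_double(col))
  })
  names(cols) <- vapply(ds$variables, `[[`, character(1), "name")
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  con <- file(data_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(c(dict = dict_path, data = data_path))
}

#' Read a dataset from the portable plain-text dialect
#'
#' Inverse of [write_portable()]. The CSV header must match the dictionary
#' variable names in order; an empty cell becomes system-missing under a
#' numeric format and the empty string under `A`.
#'
#' @param dict_path Path to the JSON dictionary.
#' @param data_path Path to the CSV case data.
#' @return An [spss_dataset] that passes [validate_dataset()].
#' @export
read_portable <- function(dict_path, data_path) {
  for (p in c(dict_path, data_path))
    if (!file.exists(p))
      stop(sprintf("cannot read portable dataset: '%s' does not exist", p),
           call. = FALSE)
  dict <- jsonlite::read_json(dict_path, simplifyVector = FALSE)
  variables <- lapply(dict$variables, portable_to_variable)
  var_names <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(tolower(var_names)))
    stop(sprintf("dictionary defines duplicate variable name(s): %s",
                 paste(unique(var_names[duplicated(tolower(var_names))]),
                       collapse = ", ")), call. = FALSE)

  raw <- as.data.frame(readr::read_csv(
    data_path, col_types = readr::cols(.default = readr::col_character()),
    na = character(0), progress = FALSE, name_repair = "minimal"),
    stringsAsFactors = FALSE, optional = TRUE)
  if (length(var_names) && !identical(names(raw), var_names)) {
    off <- union(setdiff(names(raw), var_names), setdiff(var_names, names(raw)))
    if (!length(off)) off <- names(raw)[names(raw) != var_names]
    stop(sprintf("CSV header does not match the dictionary; offending column(s): %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }

  cols <- lapply(seq_along(variables), function(j) {
    v <- variables[[j]]
    col <- raw[[j]]
    if (identical(v$format$code, "A")) return(col)
    out <- suppressWarnings(as.numeric(col))
    out[col == ""] <- NA_real_
    bad <- which(is.na(out) & col != "")
    if (length(bad))
      stop(sprintf("non-numeric token '%s' at row %d, column '%s'",
                   col[bad[1]], bad[1], v$name), call. = FALSE)
    out
  })
  names(cols) <- var_names
  data <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  spss_dataset(variables, data,
               source_name = dict$source_name %||% "portable")
}

#' Read a binary SPSS .sav file
#'
#' Delegates to `foreign::read.spss()`. That reader exposes variable names,
#' labels, value labels, and user-missing declarations, but not print
#' formats, measure, role, columns or align; print formats are therefore
#' inferred from the stored data (string width from the longest value,
#' `F` decimals from whether values are integral) and a warning is recorded
#' for every variable whose format had to be inferred. Calendar variables
#' cannot be distinguished from plain numerics without the stored format
#' and come back as `F` numerics holding raw epoch-seconds.
#'
#' @param path Path to a .sav file.
#' @return An [spss_dataset].
#' @export
read_sav <- function(path) {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("reading .sav files requires the 'foreign' package; use the portable dialect (read_portable) instead",
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read SPSS file: '%s' does not exist", path),
         call. = FALSE)
  raw <- tryCatch(
    suppressWarnings(foreign::read.spss(path, use.value.labels = FALSE,
                                        to.data.frame = FALSE,
                                        use.missings = FALSE)),
    error = function(e) stop(sprintf(
      "cannot read SPSS file '%s': %s", path, conditionMessage(e)),
      call. = FALSE))
  var_labels <- attr(raw, "variable.labels")
  missings <- attr(raw, "missings")

  variables <- vector("list", length(raw))
  cols <- vector("list", length(raw))
  for (j in seq_along(raw)) {
    nm <- names(raw)[j]
    col <- raw[[j]]
    vl_attr <- attr(col, "value.labels")
    if (is.character(col)) {
      col <- sub("[[:space:]]+$", "", col)
      width <- max(1L, nchar(col), na.rm = TRUE)
      fmt <- spss_format("A", width)
    } else {
      col <- as.numeric(col)
      integral <- all(is.na(col) | col == trunc(col))
      fmt <- spss_format("F", 8L, if (integral) 0L else 2L)
    }
    warning(sprintf(
      "variable '%s': print format not stored by the reader backend; inferred %s",
      nm, format(fmt)), call. = FALSE)
    vl <- NULL
    if (!is.null(vl_attr) && length(vl_attr)) {
      vl <- data.frame(
        value = if (is.character(col)) as.character(vl_attr)
                else as.numeric(vl_attr),
        label = names(vl_attr), stringsAsFactors = FALSE)
      vl <- vl[nrow(vl):1, , drop = FALSE]  # foreign returns them reversed
      rownames(vl) <- NULL
    }
    miss <- NULL
    m <- missings[[nm]]
    if (!is.null(m) && !identical(m$type, "none")) {
      miss <- if (grepl("range", m$type %||% ""))
        list(range = as.numeric(m$value[1:2]),
             values = if (length(m$value) > 2) as.numeric(m$value[3]))
      else list(values = as.numeric(m$value))
    }
    lab <- if (!is.null(var_labels) && nzchar(var_labels[[j]] %||% ""))
      var_labels[[j]]
    variables[[j]] <- spss_variable(nm, fmt, label = lab,
                                    value_labels = vl, missing = miss)
    attributes(col) <- NULL
    cols[[j]] <- col
  }
  names(cols) <- names(raw)
  data <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  spss_dataset(variables, data,
               source_name = tools::file_path_sans_ext(basename(path)))
}

#' Write a binary SPSS .sav file
#'
#' No installed R library writes the .sav system-file format; this backend
#' is therefore unavailable and the function raises a capability error
#' (after validating the dataset, so invalid input is still refused before
#' any write attempt). Use [write_portable()] for a lossless plain-text
#' serialization.
#'
#' @param ds A valid [spss_dataset].
#' @param path Target path.
#' @export
write_sav <- function(ds, path) {
  issues <- validate_dataset(ds)
  if (nrow(issues))
    stop(sprintf("refusing to write an invalid dataset (%d issue(s)); first: %s",
                 nrow(issues), issues$message[1]), call. = FALSE)
  stop("no .sav writer backend is available; write the portable dialect instead (write_portable)",
       call. = FALSE)
}
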