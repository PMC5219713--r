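# Forward conversion: SPSS-style dataset -> ODM 1.3.1 document.
#
# The flat SPSS variable list is inserted into a default study hierarchy
# (one protocol, one scheduled study event, one form, one item group); one
# ItemDef per variable, one CodeList per variable with value labels. Case
# rows become SubjectData trees. Statistical attributes (missing, measure,
# role) and display attributes (columns, align, national date formats) have
# no ODM counterpart and are dropped with a warning each.

#' Options controlling an SPSS-to-ODM conversion
#'
#' @param include_data Convert case data into a ClinicalData element?
#'   Metadata is always exported.
#' @param subjectkey Optional name (case-sensitive) of the variable holding
#'   the patient identifier. That column becomes the `SubjectKey` attribute
#'   and is not converted as a separate item. When absent, subjects are
#'   keyed by an incrementing number `"1", "2", ...`.
#' @param lang Optional IETF RFC 3066 language code attached to every
#'   TranslatedText; when absent no language attribute is written.
#' @param string_datatype ODM datatype used for string variables:
#'   `"string"` (default) or `"text"`.
#' @param duplicate_key_policy What to do when subject keys repeat:
#'   `"error"` (default; multiple rows per patient are not supported) or
#'   `"suffix"` (append `".2"`, `".3"`, ... to repeats).
#' @param timestamp Optional fixed ISO 8601 CreationDateTime (for
#'   reproducible output); defaults to the current time.
#' @param file_oid Optional fixed FileOID; defaults to one derived from the
#'   dataset's source name.
#' @return An object of class `convert_options`.
#' @export
convert_options <- function(include_data = FALSE, subjectkey = NULL,
                            lang = NULL,
                            string_datatype = c("string", "text"),
                            duplicate_key_policy = c("error", "suffix"),
                            timestamp = NULL, file_oid = NULL) {
  if (!is.null(lang)) validate_lang(lang)
  structure(list(include_data = isTRUE(include_data),
                 subjectkey = subjectkey, lang = lang,
                 string_datatype = match.arg(string_datatype),
                 duplicate_key_policy = match.arg(duplicate_key_policy),
                 timestamp = timestamp, file_oid = file_oid),
            class = "convert_options")
}

new_report <- function() {
  structure(list(
    warnings = data.frame(variable = character(0), category = character(0),
                          message = character(0), stringsAsFactors = FALSE),
    oid_registry = list()),
    class = "conversion_report")
}

add_warning <- function(report, variable, category, message) {
  report$warnings <- rbind(report$warnings, data.frame(
    variable = variable, category = category, message = message,
    stringsAsFactors = FALSE))
  report
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("<conversion_report: %d warning(s), %d OID(s) issued>\n",
              nrow(x$warnings), length(x$oid_registry)))
  if (nrow(x$warnings)) {
    tab <- table(x$warnings$category)
    for (k in names(tab)) cat(sprintf("  %-22s %d\n", k, tab[[k]]))
  }
  invisible(x)
}

#' Validate an IETF RFC 3066 language code
#'
#' Accepts codes matching the RFC 3066 grammar: a primary subtag of 1-8
#' letters, optionally followed by `-`-separated subtags of 1-8 letters or
#' digits (`"en"`, `"de-DE"`, `"x-klingon"`).
#'
#' @param code The candidate language code.
#' @return `TRUE` invisibly on acceptance; otherwise an error naming the
#'   offending code.
#' @export
validate_lang <- function(code) {
  if (!is.character(code) || length(code) != 1L ||
      !grepl("^[A-Za-z]{1,8}(-[A-Za-z0-9]{1,8})*$", code))
    stop(sprintf("'%s' is not a valid RFC 3066 language code",
                 paste(code, collapse = " ")), call. = FALSE)
  invisible(TRUE)
}

#' Map an SPSS print format to an ODM data type
#'
#' Plain numerics map exactly (`F` with 0 decimals to `integer`, with
#' decimals to `float` carrying `SignificantDigits`); strings map to
#' `string` (or `text`) carrying `Length`. Grouped, currency, percent and
#' scientific numerics (`COMMA`, `DOT`, `DOLLAR`, `CC`, `E`, `PCT`) can only
#' be matched to the less specific `float`. All calendar date formats
#' collapse onto the single XML `date` type, losing the national display
#' format. Rarely used renderings (`DTIME`, `WKYR`, `WKDAY`, `MONTH`,
#' `MOYR`, `QYR`) have no XML counterpart and fall back to string.
#'
#' @param fmt An [spss_format].
#' @param opts [convert_options] (controls the string datatype).
#' @return A list with `datatype`, optional `length` and
#'   `significant_digits`, and a logical `lossy` flag.
#' @export
map_format_to_datatype <- function(fmt, opts = convert_options()) {
  str_type <- opts$string_datatype
  code <- fmt$code
  if (code == "A")
    return(list(datatype = str_type, length = fmt$width,
                significant_digits = NULL, lossy = FALSE))
  if (code == "F") {
    if (fmt$decimals == 0L)
      return(list(datatype = "integer", length = fmt$width,
                  significant_digits = NULL, lossy = FALSE))
    return(list(datatype = "float", length = fmt$width,
                significant_digits = fmt$decimals, lossy = FALSE))
  }
  if (code %in% c("COMMA", "DOT", "DOLLAR", "CC", "E", "PCT"))
    return(list(datatype = "float", length = fmt$width,
                significant_digits = if (fmt$decimals > 0L) fmt$decimals,
                lossy = TRUE))
  if (code %in% c("DATE", "ADATE", "EDATE", "SDATE", "JDATE"))
    return(list(datatype = "date", length = NULL,
                significant_digits = NULL, lossy = TRUE))
  if (code == "TIME")
    return(list(datatype = "time", length = NULL,
                significant_digits = NULL, lossy = FALSE))
  if (code == "DATETIME")
    return(list(datatype = "datetime", length = NULL,
                significant_digits = NULL, lossy = FALSE))
  # DTIME, WKYR, WKDAY, MONTH, MOYR, QYR: no XML counterpart
  list(datatype = str_type, length = fmt$width,
       significant_digits = NULL, lossy = TRUE)
}

#' OID generation with collision handling
#'
#' Item OIDs are the SPSS variable name verbatim; code lists are prefixed
#' `"CL."`; the default structural elements use fixed OIDs (`S.1`, `MDV.1`,
#' `SE.1`, `F.1`, `IG.1`). On collision the smallest positive integer
#' suffix making the OID unique is appended.
#'
#' @param kind One of `"study"`, `"mdv"`, `"event"`, `"form"`,
#'   `"itemgroup"`, `"item"`, `"codelist"`.
#' @param base Base name (non-empty; for items the variable name).
#' @param registry An environment created by [new_oid_registry()].
#' @return The issued OID string; the registry is updated in place.
#' @export
make_oid <- function(kind, base, registry = new_oid_registry()) {
  stopifnot(nzchar(base))
  candidate <- switch(kind,
    study = "S.1", mdv = "MDV.1", event = "SE.1", form = "F.1",
    itemgroup = "IG.1",
    item = base,
    codelist = paste0("CL.", base),
    stop(sprintf("unknown OID kind '%s'", kind), call. = FALSE))
  oid <- candidate
  n <- 0L
  while (oid %in% registry$used) {
    n <- n + 1L
    oid <- paste0(candidate, ".", n)
  }
  registry$used <- c(registry$used, oid)
  registry$by_base[[paste(kind, base, sep = ":")]] <- oid
  oid
}

#' @rdname make_oid
#' @export
new_oid_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$used <- character(0)
  e$by_base <- list()
  e
}

#' Convert SPSS epoch-seconds to an ISO 8601 date, time or datetime string
#'
#' SPSS stores calendar values as seconds elapsed since 1582-10-14 00:00:00
#' in the proleptic Gregorian calendar, and clock times as seconds since
#' midnight. Fractional seconds are truncated.
#'
#' @param seconds Numeric vector of raw SPSS values.
#' @param target `"date"`, `"time"` or `"datetime"`.
#' @return Character vector: `"YYYY-MM-DD"`, `"hh:mm:ss"` or
#'   `"YYYY-MM-DDThh:mm:ss"`; `NA` maps to `NA`.
#' @examples
#' spss_seconds_to_iso(0, "date")      # the SPSS epoch, "1582-10-14"
#' spss_seconds_to_iso(3661, "time")   # "01:01:01"
#' @export
spss_seconds_to_iso <- function(seconds, target = c("date", "time", "datetime")) {
  target <- match.arg(target)
  out <- rep(NA_character_, length(seconds))
  ok <- !is.na(seconds)
  if (!any(ok)) return(out)
  s <- trunc(seconds[ok])
  if (target == "time") {
    if (any(s < 0 | s >= 86400))
      stop(sprintf("time value out of range [0, 86400): %s",
                   paste(utils::head(s[s < 0 | s >= 86400], 3), collapse = ", ")),
           call. = FALSE)
    out[ok] <- sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
    return(out)
  }
  days <- floor(s / 86400)
  civ <- civil_from_days(SPSS_EPOCH_DAYS + days)
  date_str <- sprintf("%04d-%02d-%02d", civ$year, civ$month, civ$day)
  if (target == "date") {
    out[ok] <- date_str
  } else {
    tod <- s - days * 86400
    out[ok] <- sprintf("%sT%02d:%02d:%02d", date_str,
                       tod %/% 3600, (tod %% 3600) %/% 60, tod %% 60)
  }
  out
}

#' Parse ISO 8601 date/time/datetime strings back to SPSS epoch-seconds
#'
#' Inverse of [spss_seconds_to_iso()] (to whole-second precision).
#'
#' @param x Character vector of ISO values.
#' @param target `"date"`, `"time"` or `"datetime"`.
#' @return Numeric vector of seconds; unparseable entries give `NA` with a
#'   warning.
#' @export
iso_to_spss_seconds <- function(x, target = c("date", "time", "datetime")) {
  target <- match.arg(target)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  v <- x[ok]
  parse_date <- function(d) {
    m <- regmatches(d, regexec("^(-?[0-9]{4})-([0-9]{2})-([0-9]{2})", d))
    vapply(m, function(g) {
      if (length(g) != 4L) return(NA_real_)
      (days_from_civil(as.numeric(g[2]), as.numeric(g[3]), as.numeric(g[4])) -
         SPSS_EPOCH_DAYS) * 86400
    }, numeric(1))
  }
  parse_time <- function(t) {
    m <- regmatches(t, regexec("^([0-9]{2}):([0-9]{2}):([0-9]{2}(\\.[0-9]+)?)", t))
    vapply(m, function(g) {
      if (length(g) < 4L) return(NA_real_)
      as.numeric(g[2]) * 3600 + as.numeric(g[3]) * 60 + as.numeric(g[4])
    }, numeric(1))
  }
  res <- switch(target,
    date = parse_date(v),
    time = parse_time(v),
    datetime = {
      halves <- strsplit(v, "T", fixed = TRUE)
      d <- parse_date(vapply(halves, `[`, character(1), 1))
      t <- vapply(halves, function(h)
        if (length(h) > 1) parse_time(h[2]) else 0, numeric(1))
      d + t
    })
  if (anyNA(res))
    warning(sprintf("could not parse %d %s value(s), stored as system-missing",
                    sum(is.na(res)), target), call. = FALSE)
  out[ok] <- res
  out
}

# Render one case-data column to ODM value strings (NA = no ItemData).
render_column <- function(values, fmt, datatype) {
  switch(datatype,
    string = , text = {
      if (is.character(values)) values else render_double(values)
    },
    integer = render_integer(values),
    float = render_double(values),
    date = spss_seconds_to_iso(values, "date"),
    time = spss_seconds_to_iso(values, "time"),
    datetime = spss_seconds_to_iso(values, "datetime"),
    stop(sprintf("unknown datatype '%s'", datatype), call. = FALSE))
}

#' Render a single cell as an ODM value string
#'
#' System-missing cells yield `NA` (no ItemData element is emitted).
#' Integers render as minimal integer literals, floats as the shortest
#' decimal that round-trips the double (no grouping separators, no exponent
#' below 10^15), calendar values via [spss_seconds_to_iso()], strings
#' verbatim.
#'
#' @param cell A single value (number, string or `NA`).
#' @param fmt The variable's [spss_format].
#' @param datatype The mapped ODM datatype.
#' @return A string, or `NA` for system-missing.
#' @export
convert_value <- function(cell, fmt, datatype) {
  render_column(cell, fmt, datatype)[1]
}

#' Extract per-subject keys from a dataset
#'
#' With a designated subject-key variable the keys are that column's values
#' rendered as ODM value strings and the column is excluded from item
#' conversion. Without one, subjects are keyed `"1", "2", ..., "n"`.
#' Duplicate keys signal multiple rows per patient, which the default
#' hierarchy cannot represent: policy `"error"` refuses, `"suffix"` appends
#' `".2"`, `".3"`, ... to repeats.
#'
#' @param ds An [spss_dataset].
#' @param subjectkey Optional variable name (case-sensitive).
#' @param duplicate_key_policy `"error"` or `"suffix"`.
#' @return A list with `keys` (character) and `excluded_index` (the key
#'   column's position, or `NA` when no key variable is set).
#' @export
extract_subject_keys <- function(ds, subjectkey = NULL,
                                 duplicate_key_policy = c("error", "suffix")) {
  duplicate_key_policy <- match.arg(duplicate_key_policy)
  n <- nrow(ds$data)
  if (is.null(subjectkey))
    return(list(keys = as.character(seq_len(n)), excluded_index = NA_integer_))
  idx <- find_variable(ds, subjectkey)
  if (is.na(idx))
    stop(sprintf("subjectkey variable '%s' not found (names are matched case-sensitively)",
                 subjectkey), call. = FALSE)
  v <- ds$variables[[idx]]
  m <- map_format_to_datatype(v$format)
  keys <- render_column(ds$data[[idx]], v$format, m$datatype)
  if (anyNA(keys))
    stop(sprintf("subjectkey variable '%s' contains system-missing values", subjectkey),
         call. = FALSE)
  if (anyDuplicated(keys)) {
    if (duplicate_key_policy == "error") {
      dups <- unique(keys[duplicated(keys)])
      stop(sprintf(paste0("duplicate subject keys (%s): multiple cases per patient ",
                          "are not supported by the single-row-per-subject model; ",
                          "use duplicate_key_policy = 'suffix' to disambiguate"),
                   paste(utils::head(dups, 5), collapse = ", ")), call. = FALSE)
    }
    seen <- stats::ave(seq_along(keys), keys, FUN = seq_along)
    keys <- ifelse(seen > 1L, paste0(keys, ".", seen), keys)
  }
  list(keys = keys, excluded_index = idx)
}

#' Build the ODM metadata part from a dataset
#'
#' Emits exactly one Study, MetaDataVersion, Protocol, StudyEventDef,
#' FormDef and ItemGroupDef (the default hierarchy: SPSS stores no
#' study-specific structure), one ItemDef per variable except the
#' subject-key column, and one CodeList per variable with value labels.
#' ItemDef name and Question text come from the SPSS label, falling back to
#' the variable name. Missing, measure and role specifications, and the
#' display attributes columns and align, are dropped with one warning each.
#'
#' @param ds A valid [spss_dataset].
#' @param opts [convert_options].
#' @return A list with `odm` (an [odm_file] without clinical data) and
#'   `report` (a `conversion_report`).
#' @export
build_metadata <- function(ds, opts = convert_options()) {
  issues <- validate_dataset(ds)
  if (nrow(issues))
    stop(sprintf("dataset fails validation (%d issue(s)); first: %s",
                 nrow(issues), issues$message[1]), call. = FALSE)
  report <- new_report()
  registry <- new_oid_registry()

  excluded <- NA_integer_
  if (!is.null(opts$subjectkey)) {
    excluded <- find_variable(ds, opts$subjectkey)
    if (is.na(excluded))
      stop(sprintf("subjectkey variable '%s' not found (names are matched case-sensitively)",
                   opts$subjectkey), call. = FALSE)
  }

  study_oid <- make_oid("study", ds$source_name, registry)
  mdv_oid <- make_oid("mdv", ds$source_name, registry)
  event_oid <- make_oid("event", "Default event", registry)
  form_oid <- make_oid("form", "Default form", registry)
  ig_oid <- make_oid("itemgroup", "Default item group", registry)

  item_defs <- list()
  code_lists <- list()
  item_refs <- list()
  order <- 0L
  for (i in seq_along(ds$variables)) {
    if (!is.na(excluded) && i == excluded) next
    v <- ds$variables[[i]]
    m <- map_format_to_datatype(v$format, opts)
    oid <- make_oid("item", v$name, registry)
    display <- if (!is.null(v$label) && nzchar(v$label)) v$label else v$name

    if (m$lossy) {
      cat_ <- if (v$format$code %in% c("COMMA", "DOT", "DOLLAR", "CC", "E", "PCT"))
        "lossy_type"
      else if (v$format$code %in% c("DATE", "ADATE", "EDATE", "SDATE", "JDATE"))
        "dropped_display_format"
      else "unmappable_format"
      report <- add_warning(report, v$name, cat_, sprintf(
        "format %s mapped to the less specific ODM type '%s'",
        format(v$format), m$datatype))
    }
    for (attr_ in c("missing", "measure", "role"))
      if (!is.null(v[[attr_]]))
        report <- add_warning(report, v$name, "dropped_attribute", sprintf(
          "statistical attribute '%s' is not represented in ODM and was dropped",
          attr_))
    for (attr_ in c("columns", "align"))
      if (!is.null(v[[attr_]]))
        report <- add_warning(report, v$name, "dropped_display_format", sprintf(
          "display attribute '%s' cannot be mapped to ODM and was dropped",
          attr_))

    cl_oid <- NULL
    if (!is.null(v$value_labels) && nrow(v$value_labels) > 0) {
      cl_oid <- make_oid("codelist", v$name, registry)
      coded <- if (is.character(v$value_labels$value)) v$value_labels$value
               else render_column(v$value_labels$value, v$format, m$datatype)
      items <- Map(function(cv, lb) odm_codelist_item(
        cv, odm_translated_text(lb, opts$lang)), coded, v$value_labels$label)
      cl_dt <- if (m$datatype %in% c("string", "text", "integer", "float"))
        m$datatype else "string"
      code_lists[[length(code_lists) + 1L]] <-
        odm_codelist(cl_oid, v$name, cl_dt, unname(items))
    }

    item_defs[[length(item_defs) + 1L]] <- odm_itemdef(
      oid, display, m$datatype, length = m$length,
      significant_digits = m$significant_digits,
      question = odm_translated_text(display, opts$lang),
      codelist_oid = cl_oid)
    order <- order + 1L
    item_refs[[order]] <- odm_ref(oid, order)
  }

  mdv <- odm_metadataversion(
    mdv_oid, "Metadata version 1",
    protocol = odm_protocol(list(odm_ref(event_oid, 1L))),
    studyevent_defs = list(odm_studyeventdef(event_oid, "Default event",
                                             form_refs = list(odm_ref(form_oid, 1L)))),
    form_defs = list(odm_formdef(form_oid, "Default form",
                                 itemgroup_refs = list(odm_ref(ig_oid, 1L)))),
    itemgroup_defs = list(odm_itemgroupdef(ig_oid, "Default item group",
                                           item_refs = item_refs)),
    item_defs = item_defs, code_lists = code_lists)

  study <- odm_study(study_oid, study_name = ds$source_name,
                     study_description = sprintf(
                       "Converted from SPSS-style dataset '%s'", ds$source_name),
                     metadata_versions = list(mdv))

  file_oid <- opts$file_oid %||%
    paste0("ODM.", gsub("[^A-Za-z0-9._-]", "_", ds$source_name))
  odm <- odm_file(file_oid, studies = list(study),
                  creation_datetime = opts$timestamp %||% iso_timestamp_now())
  report$oid_registry <- registry$by_base
  list(odm = odm, report = report)
}

#' Build the ClinicalData part from a dataset and its converted metadata
#'
#' One SubjectData per case, in case order, each holding exactly one
#' StudyEventData -> FormData -> ItemGroupData chain over the default
#' definitions, with one ItemData per non-excluded, non-missing cell.
#'
#' @param ds The [spss_dataset] the metadata was built from.
#' @param metadata The [odm_file] returned by [build_metadata()].
#' @param keys Character vector of subject keys (one per case).
#' @param excluded_index Position of the subject-key column, or `NA`.
#' @param opts [convert_options].
#' @return An [odm_clinical_data].
#' @export
build_clinical_data <- function(ds, metadata, keys, excluded_index = NA_integer_,
                                opts = convert_options()) {
  stopifnot(length(keys) == nrow(ds$data))
  mdv <- metadata$studies[[1]]$metadata_versions[[1]]
  event_oid <- mdv$studyevent_defs[[1]]$oid
  form_oid <- mdv$form_defs[[1]]$oid
  ig_oid <- mdv$itemgroup_defs[[1]]$oid
  item_oids <- vapply(mdv$item_defs, `[[`, character(1), "oid")

  keep <- seq_along(ds$variables)
  if (!is.na(excluded_index)) keep <- keep[keep != excluded_index]
  stopifnot(length(keep) == length(item_oids))

  n <- nrow(ds$data)
  rendered <- matrix(NA_character_, nrow = n, ncol = length(keep))
  for (j in seq_along(keep)) {
    v <- ds$variables[[keep[j]]]
    m <- map_format_to_datatype(v$format, opts)
    rendered[, j] <- render_column(ds$data[[keep[j]]], v$format, m$datatype)
  }

  subjects <- vector("list", n)
  for (r in seq_len(n)) {
    present <- which(!is.na(rendered[r, ]))
    # plain structure() instead of data.frame(): called once per case
    items <- structure(
      list(item_oid = item_oids[present], value = rendered[r, present]),
      class = "data.frame", row.names = c(NA_integer_, -length(present)))
    subjects[[r]] <- odm_subject_data(
      keys[r],
      events = list(odm_studyevent_data(event_oid, forms = list(
        odm_form_data(form_oid, itemgroups = list(
          odm_itemgroup_data(ig_oid, items)))))))
  }
  odm_clinical_data(metadata$studies[[1]]$oid, mdv$oid, subjects)
}

#' Convert an SPSS-style dataset to an ODM 1.3.1 document
#'
#' The top-level forward conversion. Metadata is always exported; clinical
#' data is included when `opts$include_data` is set. The result passes
#' [check_structure()] and [check_referential_integrity()] with zero
#' error-level issues.
#'
#' @param ds A valid [spss_dataset].
#' @param opts [convert_options].
#' @return A list with `odm` (an [odm_file]) and `report` (a
#'   `conversion_report` listing every dropped or degraded attribute and
#'   the OID registry).
#' @examples
#' ds <- make_sample_dataset()
#' res <- spss_to_odm(ds, convert_options(include_data = TRUE,
#'                                        subjectkey = "PID"))
#' res$odm
#' res$report
#' @export
spss_to_odm <- function(ds, opts = convert_options()) {
  built <- build_metadata(ds, opts)
  if (opts$include_data) {
    sk <- extract_subject_keys(ds, opts$subjectkey, opts$duplicate_key_policy)
    built$odm$clinical_data <- build_clinical_data(
      ds, built$odm, sk$keys, sk$excluded_index, opts)
  }
  built
}
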