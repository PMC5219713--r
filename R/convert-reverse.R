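# Reverse conversion: ODM document -> SPSS-style dataset.
#
# The metadata tree is flattened in Protocol -> study-event -> form ->
# item-group -> item reference order into a variable dictionary, preceded
# by an injected subject-key column. Attributes ODM cannot carry (missing,
# measure, role) come back absent; display attributes are set to declared
# defaults (columns = 8, alignment right for numerics / left for strings).

#' Map an ODM data type back to an SPSS print format
#'
#' Canonical inverses of the forward mapping: `integer` to `F` with 0
#' decimals, `float` to `F` with `SignificantDigits` decimals, strings to
#' `A`, and the calendar types to the canonical display formats `DATE11`,
#' `TIME8`, `DATETIME20` (ODM stores no national display format, so one
#' must be chosen).
#'
#' @param datatype An ODM data type.
#' @param length Optional ODM Length.
#' @param significant_digits Optional ODM SignificantDigits.
#' @return A list with `format` (an [spss_format]) and a logical
#'   `supported`; unsupported datatypes fall back to `A255` with
#'   `supported = FALSE`.
#' @export
map_datatype_to_format <- function(datatype, length = NULL,
                                   significant_digits = NULL) {
  fmt <- switch(datatype,
    integer = spss_format("F", length %||% 8L, 0L),
    float = {
      d <- significant_digits %||% 2L
      w <- length %||% 8L
      if (d >= w) w <- d + 1L  # minimal widening to keep decimals < width
      spss_format("F", w, d)
    },
    string = , text = spss_format("A", length %||% 255L, 0L),
    date = spss_format("DATE", 11L, 0L),
    time = spss_format("TIME", 8L, 0L),
    datetime = spss_format("DATETIME", 20L, 0L),
    NULL)
  if (is.null(fmt))
    return(list(format = spss_format("A", 255L, 0L), supported = FALSE))
  list(format = fmt, supported = TRUE)
}

#' Derive a valid SPSS variable name from an OID
#'
#' Characters outside `[A-Za-z0-9_@#$.]` become `_`; a `V_` prefix is added
#' when the first character cannot start an SPSS name; the result is
#' truncated to 64 characters; case-insensitive uniqueness is enforced with
#' a numeric suffix replacing the tail.
#'
#' @param oid Source OID (non-empty).
#' @param registry Environment tracking names already taken (see
#'   [new_oid_registry()]); lowercased names are stored in `$used`.
#' @return A valid, unique SPSS variable name.
#' @export
sanitize_variable_name <- function(oid, registry = new_oid_registry()) {
  stopifnot(nzchar(oid))
  name <- gsub("[^A-Za-z0-9_@#$.]", "_", oid)
  if (!grepl("^[A-Za-z@#$]", name)) name <- paste0("V_", name)
  if (nchar(name) > 64L) name <- substr(name, 1, 64L)
  if (tolower(name) %in% registry$used) {
    n <- 1L
    repeat {
      suffix <- paste0("_", n)
      cand <- paste0(substr(name, 1, 64L - nchar(suffix)), suffix)
      if (!(tolower(cand) %in% registry$used)) { name <- cand; break }
      n <- n + 1L
    }
  }
  registry$used <- c(registry$used, tolower(name))
  name
}

#' Convert an ODM document to an SPSS-style dataset
#'
#' The reverse direction of the converter. The first study's first metadata
#' version is flattened into a variable dictionary: a subject-key column
#' (string, width at least 8) followed by one variable per ItemDef in
#' Protocol -> event -> form -> item group -> item reference order.
#' Variable names come from the item OIDs (sanitised), labels from the
#' Question text (Name as fallback), value labels from referenced code
#' lists. ISO date/time/datetime values are parsed back to epoch-seconds
#' doubles; absent ItemData becomes system-missing. Only a single study
#' event is supported (the default hierarchy the forward direction emits);
#' additional events raise an error listing their OIDs.
#'
#' @param odm An [odm_file] passing [check_referential_integrity()].
#' @param subject_column_name Name for the injected subject-key variable.
#' @return A list with `dataset` (an [spss_dataset]) and `report` (a
#'   `conversion_report` noting attributes set to defaults).
#' @export
odm_to_dataset <- function(odm, subject_column_name = "SUBJECTKEY") {
  ref <- check_referential_integrity(odm)
  err <- ref[ref$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop(sprintf("ODM document fails referential-integrity validation (%d issue(s)); first: %s [%s]",
                 nrow(err), err$message[1], err$locus[1]), call. = FALSE)
  if (length(odm$studies) == 0L)
    stop("ODM document contains no Study", call. = FALSE)
  st <- odm$studies[[1]]
  if (length(st$metadata_versions) == 0L)
    stop("Study contains no MetaDataVersion", call. = FALSE)
  mdv <- st$metadata_versions[[1]]
  report <- new_report()

  ev_refs <- vapply(mdv$protocol$studyevent_refs, `[[`, character(1), "oid")
  if (length(ev_refs) > 1L)
    stop(sprintf("only a single study event can be flattened into one row per subject; extra event OID(s): %s",
                 paste(ev_refs[-1], collapse = ", ")), call. = FALSE)

  defs_by_oid <- function(defs) {
    o <- vapply(defs, `[[`, character(1), "oid")
    stats::setNames(defs, o)
  }
  events <- defs_by_oid(mdv$studyevent_defs)
  forms <- defs_by_oid(mdv$form_defs)
  igs <- defs_by_oid(mdv$itemgroup_defs)
  items <- defs_by_oid(mdv$item_defs)
  cls <- defs_by_oid(mdv$code_lists)

  # flatten in reference order
  item_order <- character(0)
  for (eo in ev_refs)
    for (fr in events[[eo]]$form_refs)
      for (gr in forms[[fr$oid]]$itemgroup_refs)
        for (ir in igs[[gr$oid]]$item_refs)
          item_order <- c(item_order, ir$oid)
  if (anyDuplicated(item_order))
    stop(sprintf("duplicate ItemRef target(s) would create duplicate columns: %s",
                 paste(unique(item_order[duplicated(item_order)]), collapse = ", ")),
         call. = FALSE)

  subjects <- if (!is.null(odm$clinical_data)) odm$clinical_data$subjects
              else list()
  keys <- vapply(subjects, `[[`, character(1), "subject_key")

  name_reg <- new_oid_registry()
  key_name <- sanitize_variable_name(subject_column_name, name_reg)
  key_width <- max(8L, if (length(keys)) max(nchar(keys)) else 0L)
  variables <- list(spss_variable(
    key_name, spss_format("A", key_width), label = "Subject key",
    columns = 8L, align = "left"))
  data_cols <- list(keys)

  for (oid in item_order) {
    it <- items[[oid]]
    mapped <- map_datatype_to_format(it$datatype, it$length,
                                     it$significant_digits)
    if (!mapped$supported)
      report <- add_warning(report, oid, "unmappable_format", sprintf(
        "ODM datatype '%s' has no SPSS counterpart; stored as A255 text",
        it$datatype))
    fmt <- mapped$format
    is_string <- identical(fmt$code, "A")

    vlabels <- NULL
    if (!is.null(it$codelist_oid)) {
      cl <- cls[[it$codelist_oid]]
      coded <- vapply(cl$items, `[[`, character(1), "coded_value")
      decodes <- vapply(cl$items, function(ci) ci$decode$text, character(1))
      vlabels <- data.frame(
        value = if (is_string) coded else as.numeric(coded),
        label = decodes, stringsAsFactors = FALSE)
    }

    name <- sanitize_variable_name(oid, name_reg)
    label <- if (!is.null(it$question)) it$question$text else it$name
    variables[[length(variables) + 1L]] <- spss_variable(
      name, fmt, label = label, value_labels = vlabels,
      columns = 8L, align = if (is_string) "left" else "right")

    # gather this item's value per subject (first occurrence in the tree)
    raw <- vapply(subjects, function(subj) {
      for (ev in subj$events) for (fo in ev$forms) for (ig in fo$itemgroups) {
        hit <- match(oid, ig$items$item_oid)
        if (!is.na(hit)) return(ig$items$value[hit])
      }
      NA_character_
    }, character(1))

    data_cols[[length(data_cols) + 1L]] <- switch(it$datatype,
      integer = , float = as.numeric(raw),
      date = iso_to_spss_seconds(raw, "date"),
      time = iso_to_spss_seconds(raw, "time"),
      datetime = iso_to_spss_seconds(raw, "datetime"),
      { raw[is.na(raw)] <- ""; raw })  # string/text/unknown: text verbatim
  }
  report <- add_warning(report, "*", "dropped_attribute",
    "missing, measure and role are not stored in ODM; reverse-converted variables carry none")

  names(data_cols) <- vapply(variables, `[[`, character(1), "name")
  data <- as.data.frame(data_cols, stringsAsFactors = FALSE, optional = TRUE)
  ds <- spss_dataset(variables, data,
                     source_name = st$study_name %||% odm$file_oid)
  list(dataset = ds, report = report)
}

#' @rdname odm_to_dataset
#' @export
odm_to_spss <- odm_to_dataset
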