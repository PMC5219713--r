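# Object model of a CDISC ODM 1.3.1 document. Metadata definitions live in
# flat per-class collections under MetaDataVersion and are wired together by
# referencing OIDs; ClinicalData mirrors the hierarchy with per-subject
# value trees. AdminData, ReferenceData and Association are out of scope.

#' ODM data types supported by the converter
#' @export
odm_datatypes <- c("string", "integer", "float", "date", "time",
                   "datetime", "text")

#' Translated text with an optional language tag
#' @param text The text.
#' @param lang Optional IETF RFC 3066 language code (checked by
#'   [validate_lang()]).
#' @return An object of class `odm_translated_text`.
#' @export
odm_translated_text <- function(text, lang = NULL) {
  if (!is.null(lang)) validate_lang(lang)
  structure(list(lang = lang, text = text), class = "odm_translated_text")
}

#' ODM CodeList and CodeListItem
#'
#' A code list enumerates the permissible coded values of an item together
#' with their human-readable decodes.
#'
#' @param coded_value The stored code (non-empty string).
#' @param decode An [odm_translated_text] decode.
#' @return Objects of class `odm_codelist_item` / `odm_codelist`.
#' @export
odm_codelist_item <- function(coded_value, decode) {
  stopifnot(nzchar(coded_value))
  structure(list(coded_value = coded_value, decode = decode),
            class = "odm_codelist_item")
}

#' @rdname odm_codelist_item
#' @param oid,name Identifier and display name of the code list.
#' @param datatype One of [odm_datatypes] (excluding none).
#' @param items Ordered list of [odm_codelist_item]s.
#' @export
odm_codelist <- function(oid, name, datatype, items = list()) {
  structure(list(oid = oid, name = name, datatype = datatype, items = items),
            class = "odm_codelist")
}

#' ODM ItemDef: the definition of a single data element
#'
#' @param oid Item OID (referenced by ItemRef and ItemData).
#' @param name Machine-readable name.
#' @param datatype One of [odm_datatypes].
#' @param length Optional display length.
#' @param significant_digits Optional; only meaningful for `float`.
#' @param question Optional [odm_translated_text] shown to data-entry users.
#' @param description Optional [odm_translated_text].
#' @param codelist_oid Optional OID of the item's [odm_codelist].
#' @return An object of class `odm_itemdef`.
#' @export
odm_itemdef <- function(oid, name, datatype, length = NULL,
                        significant_digits = NULL, question = NULL,
                        description = NULL, codelist_oid = NULL) {
  stopifnot(nzchar(oid))
  structure(list(oid = oid, name = name, datatype = datatype,
                 length = length, significant_digits = significant_digits,
                 question = question, description = description,
                 codelist_oid = codelist_oid),
            class = "odm_itemdef")
}

#' Ordered reference from a container definition to a child definition
#'
#' @param oid Target definition OID.
#' @param order_number Position within the referencing list (1-based,
#'   strictly increasing).
#' @param mandatory `"Yes"` or `"No"`.
#' @return An object of class `odm_ref`.
#' @export
odm_ref <- function(oid, order_number, mandatory = "No") {
  structure(list(oid = oid, order_number = as.integer(order_number),
                 mandatory = mandatory),
            class = "odm_ref")
}

#' Container definitions of the ODM metadata hierarchy
#'
#' `Protocol -> StudyEventDef -> FormDef -> ItemGroupDef` each carry an
#' ordered list of [odm_ref]s to the next level down.
#'
#' @param oid,name Identifier and display name.
#' @param repeating `"Yes"` or `"No"`.
#' @param item_refs,itemgroup_refs,form_refs,studyevent_refs Ordered lists
#'   of [odm_ref].
#' @param type Study-event type: `"Scheduled"`, `"Unscheduled"` or
#'   `"Common"`.
#' @return Objects of the corresponding `odm_*` class.
#' @export
odm_itemgroupdef <- function(oid, name, repeating = "No", item_refs = list()) {
  structure(list(oid = oid, name = name, repeating = repeating,
                 item_refs = item_refs),
            class = "odm_itemgroupdef")
}

#' @rdname odm_itemgroupdef
#' @export
odm_formdef <- function(oid, name, repeating = "No", itemgroup_refs = list()) {
  structure(list(oid = oid, name = name, repeating = repeating,
                 itemgroup_refs = itemgroup_refs),
            class = "odm_formdef")
}

#' @rdname odm_itemgroupdef
#' @export
odm_studyeventdef <- function(oid, name, repeating = "No",
                              type = "Scheduled", form_refs = list()) {
  structure(list(oid = oid, name = name, repeating = repeating, type = type,
                 form_refs = form_refs),
            class = "odm_studyeventdef")
}

#' @rdname odm_itemgroupdef
#' @export
odm_protocol <- function(studyevent_refs = list()) {
  structure(list(studyevent_refs = studyevent_refs), class = "odm_protocol")
}

#' ODM MetaDataVersion: one complete version of a study's definitions
#'
#' @param oid,name Identifier and display name.
#' @param protocol An [odm_protocol].
#' @param studyevent_defs,form_defs,itemgroup_defs,item_defs,code_lists
#'   Ordered lists of the respective definitions; OIDs must be unique
#'   within each class.
#' @return An object of class `odm_metadataversion`.
#' @export
odm_metadataversion <- function(oid, name, protocol = odm_protocol(),
                                studyevent_defs = list(), form_defs = list(),
                                itemgroup_defs = list(), item_defs = list(),
                                code_lists = list()) {
  structure(list(oid = oid, name = name, protocol = protocol,
                 studyevent_defs = studyevent_defs, form_defs = form_defs,
                 itemgroup_defs = itemgroup_defs, item_defs = item_defs,
                 code_lists = code_lists),
            class = "odm_metadataversion")
}

#' ODM Study with its GlobalVariables
#'
#' @param oid Study OID.
#' @param study_name,study_description,protocol_name The GlobalVariables.
#' @param metadata_versions Ordered list of [odm_metadataversion].
#' @return An object of class `odm_study`.
#' @export
odm_study <- function(oid, study_name, study_description = "",
                      protocol_name = study_name, metadata_versions = list()) {
  structure(list(oid = oid, study_name = study_name,
                 study_description = study_description,
                 protocol_name = protocol_name,
                 metadata_versions = metadata_versions),
            class = "odm_study")
}

#' ClinicalData value hierarchy
#'
#' One [odm_subject_data] per subject; each subject holds study-event, form
#' and item-group nodes referencing the metadata definitions by OID. The
#' item-group level stores its ItemData children as a two-column table
#' (`item_oid`, `value`), an ordered collection that keeps conversion and
#' serialization fast at registry scale.
#'
#' @param study_oid,metadata_version_oid OIDs linking the data to its
#'   metadata.
#' @param subjects Ordered list of [odm_subject_data].
#' @return An object of class `odm_clinical_data`.
#' @export
odm_clinical_data <- function(study_oid, metadata_version_oid,
                              subjects = list()) {
  structure(list(study_oid = study_oid,
                 metadata_version_oid = metadata_version_oid,
                 subjects = subjects),
            class = "odm_clinical_data")
}

#' @rdname odm_clinical_data
#' @param subject_key Non-empty per-subject identifier.
#' @param events Ordered list of study-event data nodes.
#' @export
odm_subject_data <- function(subject_key, events = list()) {
  stopifnot(nzchar(subject_key))
  structure(list(subject_key = subject_key, events = events),
            class = "odm_subject_data")
}

#' @rdname odm_clinical_data
#' @param oid OID of the corresponding definition.
#' @param forms,itemgroups,items Children of the node; `items` is a
#'   `data.frame` with columns `item_oid` and `value`.
#' @export
odm_studyevent_data <- function(oid, forms = list()) {
  structure(list(oid = oid, forms = forms), class = "odm_studyevent_data")
}

#' @rdname odm_clinical_data
#' @export
odm_form_data <- function(oid, itemgroups = list()) {
  structure(list(oid = oid, itemgroups = itemgroups), class = "odm_form_data")
}

#' @rdname odm_clinical_data
#' @export
odm_itemgroup_data <- function(oid, items = data.frame(
  item_oid = character(0), value = character(0), stringsAsFactors = FALSE)) {
  structure(list(oid = oid, items = items), class = "odm_itemgroup_data")
}

#' ODM document root
#'
#' @param file_oid Unique identifier of this file.
#' @param studies Ordered list of [odm_study].
#' @param clinical_data Optional [odm_clinical_data]; when present its
#'   `study_oid` must match an emitted study.
#' @param file_type `"Snapshot"` or `"Transactional"`.
#' @param creation_datetime ISO 8601 timestamp.
#' @param odm_version Always `"1.3.1"`.
#' @param granularity Optional granularity attribute.
#' @return An object of class `odm_file`.
#' @export
odm_file <- function(file_oid, studies, clinical_data = NULL,
                     file_type = "Snapshot",
                     creation_datetime = iso_timestamp_now(),
                     odm_version = "1.3.1", granularity = "All") {
  structure(list(file_oid = file_oid, file_type = file_type,
                 creation_datetime = creation_datetime,
                 odm_version = odm_version, granularity = granularity,
                 studies = studies, clinical_data = clinical_data),
            class = "odm_file")
}

#' @export
print.odm_file <- function(x, ...) {
  n_items <- 0L
  if (length(x$studies) && length(x$studies[[1]]$metadata_versions))
    n_items <- length(x$studies[[1]]$metadata_versions[[1]]$item_defs)
  cat(sprintf("<odm_file '%s' (ODM %s, %s): %d study(ies), %d item defs%s>\n",
              x$file_oid, x$odm_version, x$file_type, length(x$studies),
              n_items,
              if (!is.null(x$clinical_data))
                sprintf(", %d subjects", length(x$clinical_data$subjects))
              else ", metadata only"))
  invisible(x)
}

#' Collect the definition OIDs of a MetaDataVersion, grouped by class
#'
#' @param mdv An [odm_metadataversion].
#' @return A named list with elements `event`, `form`, `itemgroup`, `item`,
#'   `codelist`, each a character vector of unique OIDs.
#' @export
collect_oids <- function(mdv) {
  stopifnot(inherits(mdv, "odm_metadataversion"))
  grab <- function(defs) unique(vapply(defs, `[[`, character(1), "oid"))
  list(event = grab(mdv$studyevent_defs),
       form = grab(mdv$form_defs),
       itemgroup = grab(mdv$itemgroup_defs),
       item = grab(mdv$item_defs),
       codelist = grab(mdv$code_lists))
}
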