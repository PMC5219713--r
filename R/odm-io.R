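# ODM 1.3.1 XML serialization, parsing and semantic validation.
#
# Serialization is a purpose-built text emitter: element order follows the
# ODM 1.3.1 schema sequence and ClinicalData is rendered with vectorised
# sprintf so documents at clinical-registry scale (millions of ItemData
# elements) write in seconds. Parsing goes through xml2/libxml2, which also
# serves as the independent well-formedness check in the test suite.

ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

tt_xml <- function(tt, indent) {
  lang_attr <- if (!is.null(tt$lang))
    sprintf(' xml:lang="%s"', xml_escape_attr(tt$lang)) else ""
  sprintf('%s<TranslatedText%s>%s</TranslatedText>', indent, lang_attr,
          xml_escape_text(tt$text))
}

ref_xml <- function(refs, elem, attr, indent) {
  vapply(refs, function(r) sprintf(
    '%s<%s %s="%s" OrderNumber="%d" Mandatory="%s"/>',
    indent, elem, attr, xml_escape_attr(r$oid), r$order_number, r$mandatory),
    character(1))
}

#' Serialize an ODM document model to XML text
#'
#' Emits UTF-8 ODM 1.3.1 XML in the default namespace
#' `http://www.cdisc.org/ns/odm/v1.3`, with element and attribute names and
#' child ordering exactly per the ODM 1.3.1 schema; TranslatedText language
#' codes are carried as `xml:lang`.
#'
#' @param odm An [odm_file] that passes [check_structure()].
#' @return A single string of XML text (ending in a newline).
#' @export
serialize_odm <- function(odm) {
  issues <- check_structure(odm)
  err <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop(sprintf("ODM model fails structural validation (%d issue(s)); first: %s [%s]",
                 nrow(err), err$message[1], err$locus[1]), call. = FALSE)

  out <- list()
  push <- function(x) out[[length(out) + 1L]] <<- x
  push('<?xml version="1.0" encoding="UTF-8"?>')
  gran <- if (!is.null(odm$granularity))
    sprintf(' Granularity="%s"', xml_escape_attr(odm$granularity)) else ""
  push(sprintf(paste0('<ODM xmlns="%s" FileOID="%s" FileType="%s" ',
                      'CreationDateTime="%s" ODMVersion="%s"%s>'),
               ODM_NS, xml_escape_attr(odm$file_oid),
               xml_escape_attr(odm$file_type),
               xml_escape_attr(odm$creation_datetime),
               xml_escape_attr(odm$odm_version), gran))

  for (st in odm$studies) {
    push(sprintf('  <Study OID="%s">', xml_escape_attr(st$oid)))
    push('    <GlobalVariables>')
    push(sprintf('      <StudyName>%s</StudyName>', xml_escape_text(st$study_name)))
    push(sprintf('      <StudyDescription>%s</StudyDescription>',
                 xml_escape_text(st$study_description)))
    push(sprintf('      <ProtocolName>%s</ProtocolName>',
                 xml_escape_text(st$protocol_name)))
    push('    </GlobalVariables>')
    for (mdv in st$metadata_versions) {
      push(sprintf('    <MetaDataVersion OID="%s" Name="%s">',
                   xml_escape_attr(mdv$oid), xml_escape_attr(mdv$name)))
      push('      <Protocol>')
      push(ref_xml(mdv$protocol$studyevent_refs, "StudyEventRef",
                   "StudyEventOID", '        '))
      push('      </Protocol>')
      for (ev in mdv$studyevent_defs) {
        push(sprintf('      <StudyEventDef OID="%s" Name="%s" Repeating="%s" Type="%s">',
                     xml_escape_attr(ev$oid), xml_escape_attr(ev$name),
                     ev$repeating, ev$type))
        push(ref_xml(ev$form_refs, "FormRef", "FormOID", '        '))
        push('      </StudyEventDef>')
      }
      for (fd in mdv$form_defs) {
        push(sprintf('      <FormDef OID="%s" Name="%s" Repeating="%s">',
                     xml_escape_attr(fd$oid), xml_escape_attr(fd$name),
                     fd$repeating))
        push(ref_xml(fd$itemgroup_refs, "ItemGroupRef", "ItemGroupOID",
                     '        '))
        push('      </FormDef>')
      }
      for (ig in mdv$itemgroup_defs) {
        push(sprintf('      <ItemGroupDef OID="%s" Name="%s" Repeating="%s">',
                     xml_escape_attr(ig$oid), xml_escape_attr(ig$name),
                     ig$repeating))
        push(ref_xml(ig$item_refs, "ItemRef", "ItemOID", '        '))
        push('      </ItemGroupDef>')
      }
      for (it in mdv$item_defs) {
        attrs <- sprintf('OID="%s" Name="%s" DataType="%s"',
                         xml_escape_attr(it$oid), xml_escape_attr(it$name),
                         it$datatype)
        if (!is.null(it$length))
          attrs <- paste0(attrs, sprintf(' Length="%d"', as.integer(it$length)))
        if (!is.null(it$significant_digits))
          attrs <- paste0(attrs, sprintf(' SignificantDigits="%d"',
                                         as.integer(it$significant_digits)))
        has_children <- !is.null(it$description) || !is.null(it$question) ||
          !is.null(it$codelist_oid)
        if (!has_children) {
          push(sprintf('      <ItemDef %s/>', attrs))
        } else {
          push(sprintf('      <ItemDef %s>', attrs))
          if (!is.null(it$description)) {
            push('        <Description>')
            push(tt_xml(it$description, '          '))
            push('        </Description>')
          }
          if (!is.null(it$question)) {
            push('        <Question>')
            push(tt_xml(it$question, '          '))
            push('        </Question>')
          }
          if (!is.null(it$codelist_oid))
            push(sprintf('        <CodeListRef CodeListOID="%s"/>',
                         xml_escape_attr(it$codelist_oid)))
          push('      </ItemDef>')
        }
      }
      for (cl in mdv$code_lists) {
        push(sprintf('      <CodeList OID="%s" Name="%s" DataType="%s">',
                     xml_escape_attr(cl$oid), xml_escape_attr(cl$name),
                     cl$datatype))
        for (ci in cl$items) {
          push(sprintf('        <CodeListItem CodedValue="%s">',
                       xml_escape_attr(ci$coded_value)))
          push('          <Decode>')
          push(tt_xml(ci$decode, '            '))
          push('          </Decode>')
          push('        </CodeListItem>')
        }
        push('      </CodeList>')
      }
      push('    </MetaDataVersion>')
    }
    push('  </Study>')
  }

  cd <- odm$clinical_data
  if (!is.null(cd)) {
    push(sprintf('  <ClinicalData StudyOID="%s" MetaDataVersionOID="%s">',
                 xml_escape_attr(cd$study_oid),
                 xml_escape_attr(cd$metadata_version_oid)))
    for (subj in cd$subjects) {
      push(sprintf('    <SubjectData SubjectKey="%s">',
                   xml_escape_attr(subj$subject_key)))
      for (ev in subj$events) {
        push(sprintf('      <StudyEventData StudyEventOID="%s">',
                     xml_escape_attr(ev$oid)))
        for (fo in ev$forms) {
          push(sprintf('        <FormData FormOID="%s">',
                       xml_escape_attr(fo$oid)))
          for (ig in fo$itemgroups) {
            if (nrow(ig$items) == 0L) {
              push(sprintf('          <ItemGroupData ItemGroupOID="%s"/>',
                           xml_escape_attr(ig$oid)))
            } else {
              push(sprintf('          <ItemGroupData ItemGroupOID="%s">',
                           xml_escape_attr(ig$oid)))
              push(sprintf('            <ItemData ItemOID="%s" Value="%s"/>',
                           xml_escape_attr(ig$items$item_oid),
                           xml_escape_attr(ig$items$value)))
              push('          </ItemGroupData>')
            }
          }
          push('        </FormData>')
        }
      }
      push('      </StudyEventData>')
      push('    </SubjectData>')
    }
    push('  </ClinicalData>')
  }
  push('</ODM>')
  paste0(paste(unlist(out), collapse = "\n"), "\n")
}

parse_tt <- function(parent_node, ns) {
  tt <- xml2::xml_find_first(parent_node, "./d1:TranslatedText", ns)
  if (inherits(tt, "xml_missing")) return(NULL)
  lang <- xml2::xml_attr(tt, "lang")  # xml2 resolves xml:lang as "lang"
  odm_translated_text(xml2::xml_text(tt),
                      lang = if (!is.na(lang)) lang)
}

parse_refs <- function(node, elem, attr, ns) {
  refs <- xml2::xml_find_all(node, sprintf("./d1:%s", elem), ns)
  lapply(seq_along(refs), function(i) {
    r <- refs[[i]]
    odm_ref(xml2::xml_attr(r, attr),
            order_number = as.integer(xml2::xml_attr(r, "OrderNumber") %na% i),
            mandatory = xml2::xml_attr(r, "Mandatory") %na% "No")
  })
}

`%na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

warn_unknown_children <- function(node, known, where) {
  kids <- unique(xml2::xml_name(xml2::xml_children(node)))
  unknown <- setdiff(kids, known)
  if (length(unknown))
    warning(sprintf("skipping unrecognised element(s) under %s: %s",
                    where, paste(unknown, collapse = ", ")), call. = FALSE)
}

#' Parse ODM 1.3.1 XML into the document model
#'
#' Inverse of [serialize_odm()] on converter output. Elements outside the
#' supported ODM subset (AdminData, ReferenceData, vendor extensions, ...)
#' are skipped with a warning, never silently corrupted.
#'
#' @param xml XML text, or a path to an XML file.
#' @return An [odm_file].
#' @export
parse_odm <- function(xml) {
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(doc)[["d1"]]
  if (!identical(xml2::xml_name(root), "ODM") || !identical(ns_uri, ODM_NS))
    stop(sprintf("not a CDISC ODM 1.3 document (root <%s>, namespace '%s'; expected <ODM> in '%s')",
                 xml2::xml_name(root), ns_uri %na% "", ODM_NS), call. = FALSE)
  ns <- c(d1 = ODM_NS)

  version <- xml2::xml_attr(root, "ODMVersion")
  if (is.na(version)) {
    warning("ODMVersion attribute missing; assuming 1.3.1", call. = FALSE)
    version <- "1.3.1"
  }
  warn_unknown_children(root, c("Study", "ClinicalData"), "ODM")

  studies <- lapply(xml2::xml_find_all(root, "./d1:Study", ns), function(st) {
    gv <- xml2::xml_find_first(st, "./d1:GlobalVariables", ns)
    get_gv <- function(nm) {
      n <- xml2::xml_find_first(gv, sprintf("./d1:%s", nm), ns)
      if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
    }
    warn_unknown_children(st, c("GlobalVariables", "MetaDataVersion",
                                "BasicDefinitions"), "Study")
    mdvs <- lapply(xml2::xml_find_all(st, "./d1:MetaDataVersion", ns),
                   function(mv) parse_mdv(mv, ns))
    odm_study(xml2::xml_attr(st, "OID"),
              study_name = get_gv("StudyName"),
              study_description = get_gv("StudyDescription"),
              protocol_name = get_gv("ProtocolName"),
              metadata_versions = mdvs)
  })

  cd_node <- xml2::xml_find_first(root, "./d1:ClinicalData", ns)
  clinical <- if (!inherits(cd_node, "xml_missing")) parse_clinical(cd_node, ns)

  odm_file(file_oid = xml2::xml_attr(root, "FileOID"),
           studies = studies, clinical_data = clinical,
           file_type = xml2::xml_attr(root, "FileType") %na% "Snapshot",
           creation_datetime = xml2::xml_attr(root, "CreationDateTime") %na% "",
           odm_version = version,
           granularity = {
             g <- xml2::xml_attr(root, "Granularity")
             if (!is.na(g)) g
           })
}

parse_mdv <- function(mv, ns) {
  warn_unknown_children(mv, c("Protocol", "StudyEventDef", "FormDef",
                              "ItemGroupDef", "ItemDef", "CodeList"),
                        "MetaDataVersion")
  prot_node <- xml2::xml_find_first(mv, "./d1:Protocol", ns)
  protocol <- odm_protocol(
    if (!inherits(prot_node, "xml_missing"))
      parse_refs(prot_node, "StudyEventRef", "StudyEventOID", ns) else list())

  events <- lapply(xml2::xml_find_all(mv, "./d1:StudyEventDef", ns), function(n)
    odm_studyeventdef(xml2::xml_attr(n, "OID"), xml2::xml_attr(n, "Name"),
                      repeating = xml2::xml_attr(n, "Repeating") %na% "No",
                      type = xml2::xml_attr(n, "Type") %na% "Scheduled",
                      form_refs = parse_refs(n, "FormRef", "FormOID", ns)))
  forms <- lapply(xml2::xml_find_all(mv, "./d1:FormDef", ns), function(n)
    odm_formdef(xml2::xml_attr(n, "OID"), xml2::xml_attr(n, "Name"),
                repeating = xml2::xml_attr(n, "Repeating") %na% "No",
                itemgroup_refs = parse_refs(n, "ItemGroupRef", "ItemGroupOID", ns)))
  igs <- lapply(xml2::xml_find_all(mv, "./d1:ItemGroupDef", ns), function(n)
    odm_itemgroupdef(xml2::xml_attr(n, "OID"), xml2::xml_attr(n, "Name"),
                     repeating = xml2::xml_attr(n, "Repeating") %na% "No",
                     item_refs = parse_refs(n, "ItemRef", "ItemOID", ns)))
  items <- lapply(xml2::xml_find_all(mv, "./d1:ItemDef", ns), function(n) {
    q <- xml2::xml_find_first(n, "./d1:Question", ns)
    d <- xml2::xml_find_first(n, "./d1:Description", ns)
    clr <- xml2::xml_find_first(n, "./d1:CodeListRef", ns)
    len <- xml2::xml_attr(n, "Length")
    sig <- xml2::xml_attr(n, "SignificantDigits")
    odm_itemdef(
      xml2::xml_attr(n, "OID"), xml2::xml_attr(n, "Name"),
      xml2::xml_attr(n, "DataType"),
      length = if (!is.na(len)) as.integer(len),
      significant_digits = if (!is.na(sig)) as.integer(sig),
      question = if (!inherits(q, "xml_missing")) parse_tt(q, ns),
      description = if (!inherits(d, "xml_missing")) parse_tt(d, ns),
      codelist_oid = if (!inherits(clr, "xml_missing"))
        xml2::xml_attr(clr, "CodeListOID"))
  })
  cls <- lapply(xml2::xml_find_all(mv, "./d1:CodeList", ns), function(n) {
    cis <- lapply(xml2::xml_find_all(n, "./d1:CodeListItem", ns), function(ci) {
      dec <- xml2::xml_find_first(ci, "./d1:Decode", ns)
      odm_codelist_item(xml2::xml_attr(ci, "CodedValue"),
                        decode = if (!inherits(dec, "xml_missing"))
                          parse_tt(dec, ns)
                        else odm_translated_text(""))
    })
    odm_codelist(xml2::xml_attr(n, "OID"), xml2::xml_attr(n, "Name"),
                 xml2::xml_attr(n, "DataType"), cis)
  })
  odm_metadataversion(xml2::xml_attr(mv, "OID"), xml2::xml_attr(mv, "Name"),
                      protocol = protocol, studyevent_defs = events,
                      form_defs = forms, itemgroup_defs = igs,
                      item_defs = items, code_lists = cls)
}

parse_clinical <- function(cd_node, ns) {
  subjects <- lapply(xml2::xml_find_all(cd_node, "./d1:SubjectData", ns),
                     function(sd) {
    events <- lapply(xml2::xml_find_all(sd, "./d1:StudyEventData", ns),
                     function(ed) {
      forms <- lapply(xml2::xml_find_all(ed, "./d1:FormData", ns),
                      function(fd) {
        igs <- lapply(xml2::xml_find_all(fd, "./d1:ItemGroupData", ns),
                      function(igd) {
          idata <- xml2::xml_find_all(igd, "./d1:ItemData", ns)
          odm_itemgroup_data(
            xml2::xml_attr(igd, "ItemGroupOID"),
            data.frame(item_oid = xml2::xml_attr(idata, "ItemOID"),
                       value = xml2::xml_attr(idata, "Value"),
                       stringsAsFactors = FALSE))
        })
        odm_form_data(xml2::xml_attr(fd, "FormOID"), igs)
      })
      odm_studyevent_data(xml2::xml_attr(ed, "StudyEventOID"), forms)
    })
    odm_subject_data(xml2::xml_attr(sd, "SubjectKey"), events)
  })
  odm_clinical_data(xml2::xml_attr(cd_node, "StudyOID"),
                    xml2::xml_attr(cd_node, "MetaDataVersionOID"),
                    subjects)
}

#' Structural validation of an ODM document model
#'
#' Flags missing required attributes (OIDs, names, data types, subject
#' keys, file attributes), data types outside the supported enumeration,
#' duplicate OIDs within a definition class, and order-number violations in
#' reference lists. Issues are returned as data, never thrown.
#'
#' @param odm An [odm_file].
#' @return A `data.frame` with columns `severity`, `locus`, `message`.
#' @export
check_structure <- function(odm) {
  issues <- new_issue_frame()
  req <- function(val, locus, what) {
    if (is.null(val) || is.na(val) || !nzchar(val))
      issues <<- add_issue(issues, "error", locus,
                           sprintf("required attribute %s is missing", what))
  }
  req(odm$file_oid, "ODM", "FileOID")
  req(odm$file_type, "ODM", "FileType")
  req(odm$creation_datetime, "ODM", "CreationDateTime")
  if (!identical(odm$odm_version, "1.3.1"))
    issues <- add_issue(issues, "warning", "ODM", sprintf(
      "ODMVersion is '%s', expected '1.3.1'", odm$odm_version %||% ""))

  check_order <- function(refs, locus) {
    if (length(refs) < 2L) return()
    ord <- vapply(refs, `[[`, integer(1), "order_number")
    if (any(diff(ord) <= 0L))
      issues <<- add_issue(issues, "error", locus,
                           "OrderNumber values must be strictly increasing")
  }
  check_dupes <- function(defs, locus, class_) {
    oids <- vapply(defs, function(d) d$oid %||% "", character(1))
    dup <- unique(oids[duplicated(oids)])
    for (d in dup)
      issues <<- add_issue(issues, "error", locus, sprintf(
        "duplicate %s OID '%s'", class_, d))
  }

  for (st in odm$studies) {
    req(st$oid, "Study", "OID")
    for (mdv in st$metadata_versions) {
      loc <- sprintf("MetaDataVersion %s", mdv$oid %||% "?")
      req(mdv$oid, loc, "OID")
      req(mdv$name, loc, "Name")
      check_order(mdv$protocol$studyevent_refs, paste(loc, "/ Protocol"))
      check_dupes(mdv$studyevent_defs, loc, "StudyEventDef")
      check_dupes(mdv$form_defs, loc, "FormDef")
      check_dupes(mdv$itemgroup_defs, loc, "ItemGroupDef")
      check_dupes(mdv$item_defs, loc, "ItemDef")
      check_dupes(mdv$code_lists, loc, "CodeList")
      for (ev in mdv$studyevent_defs)
        check_order(ev$form_refs, sprintf("StudyEventDef %s", ev$oid %||% "?"))
      for (fd in mdv$form_defs)
        check_order(fd$itemgroup_refs, sprintf("FormDef %s", fd$oid %||% "?"))
      for (ig in mdv$itemgroup_defs)
        check_order(ig$item_refs, sprintf("ItemGroupDef %s", ig$oid %||% "?"))
      for (it in mdv$item_defs) {
        iloc <- sprintf("ItemDef %s", it$oid %||% "?")
        req(it$oid, iloc, "OID")
        req(it$name, iloc, "Name")
        if (is.null(it$datatype) || is.na(it$datatype) || !nzchar(it$datatype))
          issues <- add_issue(issues, "error", iloc,
                              "required attribute DataType is missing")
        else if (!(it$datatype %in% odm_datatypes))
          issues <- add_issue(issues, "error", iloc, sprintf(
            "DataType '%s' outside the supported enumeration", it$datatype))
        if (!is.null(it$significant_digits) &&
            !identical(it$datatype, "float"))
          issues <- add_issue(issues, "warning", iloc,
                              "SignificantDigits is only meaningful for float items")
      }
      for (cl in mdv$code_lists) {
        cloc <- sprintf("CodeList %s", cl$oid %||% "?")
        req(cl$oid, cloc, "OID")
        if (!is.null(cl$datatype) && !is.na(cl$datatype) &&
            !(cl$datatype %in% odm_datatypes))
          issues <- add_issue(issues, "error", cloc, sprintf(
            "DataType '%s' outside the supported enumeration", cl$datatype))
        coded <- vapply(cl$items, `[[`, character(1), "coded_value")
        for (d in unique(coded[duplicated(coded)]))
          issues <- add_issue(issues, "error", cloc, sprintf(
            "duplicate CodedValue '%s'", d))
      }
    }
  }

  cd <- odm$clinical_data
  if (!is.null(cd)) {
    req(cd$study_oid, "ClinicalData", "StudyOID")
    req(cd$metadata_version_oid, "ClinicalData", "MetaDataVersionOID")
    for (i in seq_along(cd$subjects)) {
      k <- cd$subjects[[i]]$subject_key
      if (is.null(k) || is.na(k) || !nzchar(k))
        issues <- add_issue(issues, "error", sprintf("SubjectData %d", i),
                            "required attribute SubjectKey is missing")
    }
  }
  issues
}

#' Referential-integrity validation of an ODM document model
#'
#' Inspects the association of ODM elements through their OIDs: every
#' StudyEventRef, FormRef, ItemGroupRef, ItemRef and CodeListRef must point
#' at a definition, and every OID used in ClinicalData (study, metadata
#' version, event, form, item group, item) must resolve against the
#' metadata. Definitions never referenced are reported at severity
#' `"info"`.
#'
#' @param odm An [odm_file].
#' @return A `data.frame` with columns `severity`, `locus`, `message`.
#' @export
check_referential_integrity <- function(odm) {
  issues <- new_issue_frame()
  study_oids <- vapply(odm$studies, `[[`, character(1), "oid")

  all_oids <- list()
  for (st in odm$studies) {
    for (mdv in st$metadata_versions) {
      oids <- collect_oids(mdv)
      all_oids[[paste0(st$oid, "/", mdv$oid)]] <- oids
      loc <- sprintf("MetaDataVersion %s", mdv$oid)

      referenced <- list(event = character(0), form = character(0),
                         itemgroup = character(0), item = character(0),
                         codelist = character(0))
      check_refs <- function(refs, class_, from) {
        targets <- vapply(refs, `[[`, character(1), "oid")
        referenced[[class_]] <<- c(referenced[[class_]], targets)
        for (t in setdiff(targets, oids[[class_]]))
          issues <<- add_issue(issues, "error", from, sprintf(
            "reference to undefined %s OID '%s'", class_, t))
      }
      check_refs(mdv$protocol$studyevent_refs, "event", paste(loc, "/ Protocol"))
      for (ev in mdv$studyevent_defs)
        check_refs(ev$form_refs, "form", sprintf("StudyEventDef %s", ev$oid))
      for (fd in mdv$form_defs)
        check_refs(fd$itemgroup_refs, "itemgroup", sprintf("FormDef %s", fd$oid))
      for (ig in mdv$itemgroup_defs)
        check_refs(ig$item_refs, "item", sprintf("ItemGroupDef %s", ig$oid))
      for (it in mdv$item_defs)
        if (!is.null(it$codelist_oid))
          check_refs(list(odm_ref(it$codelist_oid, 1L)), "codelist",
                     sprintf("ItemDef %s", it$oid))

      for (class_ in names(referenced))
        for (o in setdiff(oids[[class_]], unique(referenced[[class_]])))
          issues <- add_issue(issues, "info", loc, sprintf(
            "%s '%s' is defined but never referenced", class_, o))
    }
  }

  cd <- odm$clinical_data
  if (!is.null(cd)) {
    if (!(cd$study_oid %in% study_oids)) {
      issues <- add_issue(issues, "error", "ClinicalData", sprintf(
        "StudyOID '%s' does not match any emitted Study", cd$study_oid))
    } else {
      key <- paste0(cd$study_oid, "/", cd$metadata_version_oid)
      if (is.null(all_oids[[key]])) {
        issues <- add_issue(issues, "error", "ClinicalData", sprintf(
          "MetaDataVersionOID '%s' not found in Study '%s'",
          cd$metadata_version_oid, cd$study_oid))
      } else {
        oids <- all_oids[[key]]
        flag <- function(bad, class_, locus) {
          for (o in unique(bad))
            issues <<- add_issue(issues, "error", locus, sprintf(
              "ClinicalData uses %s OID '%s' with no metadata definition",
              class_, o))
        }
        for (i in seq_along(cd$subjects)) {
          subj <- cd$subjects[[i]]
          locus <- sprintf("SubjectData '%s'", subj$subject_key)
          for (ev in subj$events) {
            flag(setdiff(ev$oid, oids$event), "event", locus)
            for (fo in ev$forms) {
              flag(setdiff(fo$oid, oids$form), "form", locus)
              for (ig in fo$itemgroups) {
                flag(setdiff(ig$oid, oids$itemgroup), "itemgroup", locus)
                flag(setdiff(unique(ig$items$item_oid), oids$item), "item",
                     locus)
              }
            }
          }
        }
      }
    }
  }
  issues
}

#' Validate serialized ODM output against the official schema
#'
#' The ODM 1.3.1 XSD is licensed by CDISC and not bundled; when a local
#' copy is available this helper runs libxml2 schema validation on
#' serialized output. The internal validators ([check_structure()],
#' [check_referential_integrity()]) are always available regardless.
#'
#' @param xml XML text or file path.
#' @param xsd_path Path to a local `ODM1-3-1.xsd`.
#' @return `TRUE` if the document validates; otherwise `FALSE` with the
#'   schema errors attached as attribute `"errors"`.
#' @export
validate_against_xsd <- function(xml, xsd_path) {
  if (!file.exists(xsd_path))
    stop(sprintf("schema file not found: %s", xsd_path), call. = FALSE)
  doc <- xml2::read_xml(xml)
  schema <- xml2::read_xml(xsd_path)
  xml2::xml_validate(doc, schema)
}
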