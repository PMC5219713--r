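test_that("serialize then parse is the identity on converter output", {
  for (seed in c(2, 13)) {
    ds <- make_random_dataset(4, 5, seed)
    res <- spss_to_odm(ds, convert_options(include_data = TRUE,
                                           timestamp = "2021-03-01T09:00:00"))
    xml <- serialize_odm(res$odm)
    back <- parse_odm(xml)
    expect_equal(back, res$odm, info = seed)
    # and a second round is byte-stable
    expect_identical(serialize_odm(back), xml, info = seed)
  }
})

test_that("serialized output is well-formed XML in the ODM namespace", {
  res <- spss_to_odm(make_sample_dataset(),
                     convert_options(include_data = TRUE, lang = "en"))
  xml <- serialize_odm(res$odm)
  doc <- xml2::read_xml(xml)  # libxml2 is the independent well-formedness check
  expect_identical(xml2::xml_name(doc), "ODM")
  expect_identical(xml2::xml_ns(doc)[["d1"]],
                   "http://www.cdisc.org/ns/odm/v1.3")
  ns <- c(d1 = "http://www.cdisc.org/ns/odm/v1.3")
  # data values live in the Value attribute of ItemData
  idata <- xml2::xml_find_all(doc, "//d1:ItemData", ns)
  expect_gt(length(idata), 0)
  expect_false(any(is.na(xml2::xml_attr(idata, "ItemOID"))))
  expect_false(any(is.na(xml2::xml_attr(idata, "Value"))))
  # question text carries xml:lang
  tt <- xml2::xml_find_first(doc, "//d1:Question/d1:TranslatedText", ns)
  expect_identical(xml2::xml_attr(tt, "lang"), "en")
  # schema child order inside MetaDataVersion
  kids <- unique(xml2::xml_name(xml2::xml_children(
    xml2::xml_find_first(doc, "//d1:MetaDataVersion", ns))))
  expect_identical(kids, c("Protocol", "StudyEventDef", "FormDef",
                           "ItemGroupDef", "ItemDef", "CodeList"))
})

test_that("special characters survive serialization", {
  ds <- spss_dataset(
    list(spss_variable("txt", spss_format("A", 60),
                       label = 'Result <5 & "high" grade')),
    data.frame(txt = 'a<b & c>"d"é', stringsAsFactors = FALSE))
  res <- spss_to_odm(ds, convert_options(include_data = TRUE,
                                         timestamp = "2021-01-01T00:00:00"))
  back <- parse_odm(serialize_odm(res$odm))
  expect_equal(back, res$odm)
})

test_that("parser warns and recovers on deviant input", {
  res <- spss_to_odm(tiny_dataset(),
                     convert_options(timestamp = "2021-01-01T00:00:00"))
  xml <- serialize_odm(res$odm)

  no_version <- sub(' ODMVersion="1.3.1"', "", xml, fixed = TRUE)
  expect_warning(parsed <- parse_odm(no_version), "ODMVersion")
  expect_identical(parsed$odm_version, "1.3.1")

  alien <- sub("</ODM>", "<AdminData/></ODM>", xml, fixed = TRUE)
  expect_warning(parsed2 <- parse_odm(alien), "AdminData")
  expect_equal(parsed2$studies, res$odm$studies)

  expect_error(parse_odm("<foo xmlns='urn:other'/>"), "namespace|ODM")
  expect_error(parse_odm("<ODM><unclosed></ODM>"))
})

test_that("check_structure flags missing attributes and duplicates", {
  res <- spss_to_odm(make_sample_dataset(), convert_options(include_data = TRUE))
  expect_identical(sum(check_structure(res$odm)$severity == "error"), 0L)

  odm <- res$odm
  odm$studies[[1]]$metadata_versions[[1]]$item_defs[[1]]$datatype <- NA_character_
  issues <- check_structure(odm)
  expect_true(any(grepl("DataType", issues$message)))

  odm2 <- res$odm
  defs <- odm2$studies[[1]]$metadata_versions[[1]]$item_defs
  defs[[2]]$oid <- defs[[1]]$oid
  odm2$studies[[1]]$metadata_versions[[1]]$item_defs <- defs
  issues2 <- check_structure(odm2)
  expect_identical(sum(grepl("duplicate ItemDef OID", issues2$message)), 1L)

  odm3 <- res$odm
  refs <- odm3$studies[[1]]$metadata_versions[[1]]$itemgroup_defs[[1]]$item_refs
  refs[[2]]$order_number <- refs[[1]]$order_number
  odm3$studies[[1]]$metadata_versions[[1]]$itemgroup_defs[[1]]$item_refs <- refs
  expect_true(any(grepl("strictly increasing", check_structure(odm3)$message)))

  odm4 <- res$odm
  odm4$clinical_data$subjects[[1]]$subject_key <- ""
  expect_true(any(grepl("SubjectKey", check_structure(odm4)$message)))
})

test_that("referential integrity catches dangling references", {
  res <- spss_to_odm(make_sample_dataset(), convert_options(include_data = TRUE))
  base <- check_referential_integrity(res$odm)
  expect_identical(sum(base$severity == "error"), 0L)

  # deleting one ItemDef leaves both the ItemRef and the ItemData dangling
  broken <- delete_itemdef(res$odm, "bmi")
  issues <- check_referential_integrity(broken)
  errs <- issues[issues$severity == "error", ]
  expect_gte(nrow(errs), 2L)
  expect_true(any(grepl("undefined item OID 'bmi'", errs$message)))
  expect_true(any(grepl("ClinicalData uses item OID 'bmi'", errs$message)))

  # dangling CodeListRef
  odm2 <- res$odm
  odm2$studies[[1]]$metadata_versions[[1]]$code_lists <- list()
  issues2 <- check_referential_integrity(odm2)
  expect_identical(sum(grepl("codelist OID 'CL.sex'", issues2$message)), 1L)

  # ClinicalData pointing at an unknown study
  odm3 <- res$odm
  odm3$clinical_data$study_oid <- "S.999"
  expect_true(any(grepl("S.999", check_referential_integrity(odm3)$message)))

  # unreferenced definitions are informational, not errors
  odm4 <- res$odm
  mdv <- odm4$studies[[1]]$metadata_versions[[1]]
  mdv$item_defs <- c(mdv$item_defs, list(odm_itemdef("orphan", "orphan", "string")))
  odm4$studies[[1]]$metadata_versions[[1]]$mdv <- NULL
  odm4$studies[[1]]$metadata_versions[[1]] <- mdv
  issues4 <- check_referential_integrity(odm4)
  orphan <- issues4[grepl("orphan", issues4$message), ]
  expect_identical(unique(orphan$severity), "info")
})

test_that("validators are insensitive to sibling definition order", {
  res <- spss_to_odm(make_sample_dataset(), convert_options(include_data = TRUE))
  odm <- res$odm
  mdv <- odm$studies[[1]]$metadata_versions[[1]]
  set.seed(4)
  mdv$item_defs <- mdv$item_defs[sample(seq_along(mdv$item_defs))]
  mdv$code_lists <- mdv$code_lists[sample(seq_along(mdv$code_lists))]
  odm$studies[[1]]$metadata_versions[[1]] <- mdv
  sorted_issues <- function(x) {
    x <- x[order(x$severity, x$locus, x$message), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(sorted_issues(check_referential_integrity(odm)),
                   sorted_issues(check_referential_integrity(res$odm)))
  expect_identical(sorted_issues(check_structure(odm)),
                   sorted_issues(check_structure(res$odm)))
})

test_that("collect_oids groups definition OIDs by class", {
  res <- spss_to_odm(make_sample_dataset())
  oids <- collect_oids(first_mdv(res$odm))
  expect_identical(length(oids$item), 16L)
  expect_identical(oids$event, "SE.1")
  expect_identical(oids$codelist, "CL.sex")
  empty <- collect_oids(odm_metadataversion("M", "m"))
  expect_true(all(lengths(empty) == 0L))
  # duplicate OIDs collapse in the set view, making them detectable
  mdv <- first_mdv(res$odm)
  mdv$item_defs[[2]]$oid <- mdv$item_defs[[1]]$oid
  expect_lt(length(collect_oids(mdv)$item), length(mdv$item_defs))
})
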