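# Shared fixtures and comparison helpers, built in code at test time.

tiny_dataset <- function() {
  spss_dataset(
    list(spss_variable("PID", spss_format("A", 5), label = "Patient id"),
         spss_variable("age", spss_format("F", 3), label = "Age in years"),
         spss_variable("bmi", spss_format("F", 6, 2), label = "Body mass index")),
    data.frame(PID = c("P1", "P2"), age = c(34, 57), bmi = c(22.5, NA),
               stringsAsFactors = FALSE),
    source_name = "tiny")
}

first_mdv <- function(odm) odm$studies[[1]]$metadata_versions[[1]]

item_oids_of <- function(odm)
  vapply(first_mdv(odm)$item_defs, `[[`, character(1), "oid")

# Drop the item definition with the given OID from the model, leaving the
# ItemRef (and any ItemData) dangling.
delete_itemdef <- function(odm, oid) {
  mdv <- first_mdv(odm)
  keep <- vapply(mdv$item_defs, function(d) d$oid != oid, logical(1))
  mdv$item_defs <- mdv$item_defs[keep]
  odm$studies[[1]]$metadata_versions[[1]] <- mdv
  odm
}

# Compare two datasets on the projection a mappable-format round trip
# preserves: names/labels/formats/value labels and all values (calendar
# values at 1-second tolerance). The subject-key column keeps its name and
# values but not its label (the key is excluded from item conversion, so
# its label never reaches the ODM file).
expect_roundtrip_equal <- function(rev, orig, key, seed = NULL) {
  info <- if (!is.null(seed)) sprintf("seed %d", seed)
  key_idx <- find_variable(orig, key)
  expected_names <- c(key, setdiff(
    vapply(orig$variables, `[[`, character(1), "name"), key))
  got_names <- vapply(rev$variables, `[[`, character(1), "name")
  expect_identical(got_names, expected_names, info = info)

  orig_by_name <- stats::setNames(orig$variables,
    vapply(orig$variables, `[[`, character(1), "name"))
  for (v in rev$variables) {
    o <- orig_by_name[[v$name]]
    is_key <- identical(v$name, key)
    if (!is_key) {
      expect_identical(v$label, o$label, info = paste(info, v$name))
      expect_identical(v$format$code, o$format$code, info = paste(info, v$name))
      expect_identical(v$format$width, o$format$width, info = paste(info, v$name))
      expect_identical(v$format$decimals, o$format$decimals,
                       info = paste(info, v$name))
      if (is.null(o$value_labels) || nrow(o$value_labels) == 0) {
        expect_true(is.null(v$value_labels), info = paste(info, v$name))
      } else {
        expect_equal(v$value_labels$value, o$value_labels$value,
                     info = paste(info, v$name))
        expect_identical(v$value_labels$label, o$value_labels$label,
                         info = paste(info, v$name))
      }
    }
    rcol <- rev$data[[v$name]]
    ocol <- orig$data[[v$name]]
    if (o$format$code %in% c("DATE", "TIME", "DATETIME")) {
      both <- !is.na(ocol)
      expect_identical(is.na(rcol), is.na(ocol), info = paste(info, v$name))
      if (any(both))
        expect_true(all(abs(rcol[both] - ocol[both]) <= 1),
                    info = paste(info, v$name))
    } else {
      expect_identical(rcol, ocol, info = paste(info, v$name))
    }
  }
}

# The seeded corpus mirrored across the round-trip and validator suites.
corpus_spec <- function(n = 200L) {
  lapply(seq_len(n), function(seed) list(
    seed = seed,
    n_vars = 2L + seed %% 7L,
    n_cases = seed %% 10L))
}
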