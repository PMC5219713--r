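# odmconvert

Bidirectional conversion between SPSS-style statistical datasets and
CDISC ODM 1.3.1 XML, in R.

Many clinical registries and investigator-initiated studies begin life as a
spreadsheet-based database: an SPSS file holding a flat variable dictionary
(names, labels, print formats, value labels, missing-value codes) and one
row of values per case. Migrating such a database into a regulated
electronic data capture (EDC) system requires the CDISC Operational Data
Model (ODM), an XML standard in which study metadata is a hierarchy of
OID-referenced definitions (`Study → MetaDataVersion → Protocol →
StudyEventDef → FormDef → ItemGroupDef → ItemDef → CodeList`) and patient
data is a parallel `ClinicalData` value tree keyed by per-subject
identifiers. `odmconvert` implements the mapping between the two worlds:

* **Forward** (`spss_to_odm()`): each SPSS variable becomes an `ItemDef`
  (label → `Name` and `Question`, print format → ODM `DataType` +
  `Length`/`SignificantDigits`), each set of value labels becomes a
  `CodeList` of `CodeListItem`s, and the flat variable list is inserted
  into a default protocol/event/form/item-group hierarchy, since SPSS
  stores no study structure of its own. Case rows become `SubjectData`
  trees; a designated identifier column is lifted into the `SubjectKey`
  attribute instead of being converted as an item; calendar values stored
  as seconds since the SPSS epoch (1582-10-14, proleptic Gregorian) are
  rendered as XML `date`/`time`/`dateTime` strings. Attributes ODM cannot
  carry — user-missing codes, measure, role, column width, alignment,
  national date display formats — are dropped, each with a warning in the
  conversion report, so the loss is explicit and measurable.
* **Reverse** (`odm_to_dataset()`): flattens an ODM metadata tree back into
  a variable dictionary (plus an injected subject-key column) and parses
  ISO calendar values back to epoch seconds, with declared defaults for the
  attributes ODM never stored.
* **Validation** (`check_structure()`, `check_referential_integrity()`):
  structural checks (required attributes, data-type enumeration, duplicate
  OIDs, order numbers) and OID resolution of every reference and every
  `ClinicalData` value path, returned as data rather than exceptions.

Because no SPSS installation can be assumed, the package defines a portable
plain-text dataset dialect — a JSON variable dictionary plus RFC 4180 CSV
case data — that round-trips a dataset exactly (`write_portable()` /
`read_portable()`). Binary `.sav` files are read through
`foreign::read.spss()` with documented limitations (see
`?read_sav`). Synthetic generators (`make_sample_dataset()`,
`make_random_dataset()`) produce a deterministic 16-variable / 5-case file
covering every major print-format family and seeded datasets up to
clinical-registry scale.

## Worked example

```r
library(odmconvert)

ds <- make_sample_dataset()
ds
#> <spss_dataset 'sample': 16 variables, 5 cases>
#>   PID              A5           Patient identifier
#>   sex              F1           Sex
#>   bmi              F6.2         Body mass index
#>   income           COMMA12.2    Yearly income
#>   ...

res <- spss_to_odm(ds, convert_options(include_data = TRUE,
                                       subjectkey = "PID", lang = "en"))
res$odm
#> <odm_file 'ODM.sample' (ODM 1.3.1, Snapshot): 1 study(ies), 15 item defs, 5 subjects>
res$report
#> <conversion_report: 17 warning(s), 21 OID(s) issued>
#>   dropped_attribute      4
#>   dropped_display_format 7
#>   lossy_type             4
#>   unmappable_format      2
```

Sixteen variables produce fifteen `ItemDef`s because `PID` was lifted into
the `SubjectKey` attribute. The seventeen warnings itemise exactly what the
mapping lost: the four statistical attributes set in the dictionary (the
missing/measure/role triple on `sex` and the measure on `bmi`), `sex`'s two
display attributes and the five date variables whose national display
format collapses onto the single XML date type, the four
grouped/currency/scientific numerics matched to plain `float`, and the two
week-based calendar renderings that only survive as strings. A fragment of
the serialized result:

```xml
<ItemDef OID="ratio" Name="Lab ratio" DataType="float" Length="10" SignificantDigits="3">
  <Question>
    <TranslatedText xml:lang="en">Lab ratio</TranslatedText>
  </Question>
</ItemDef>
<ItemDef OID="visit_date" Name="Date of visit" DataType="date">
  ...
```

And back again:

```r
xml <- serialize_odm(res$odm)
back <- odm_to_dataset(parse_odm(xml), subject_column_name = "PID")
back$dataset
#> <spss_dataset 'sample': 16 variables, 5 cases>
#>   PID              A8           Subject key
#>   sex              F1           Sex
#>   bmi              F6.2         Body mass index
#>   income           F12.2        Yearly income
#>   ...
```

Plain `F`, `A`, `DATE`, `TIME` and `DATETIME` variables return with their
formats intact; `COMMA12.2` comes back as the less specific `F12.2` — the
type-lossiness the conversion report announced on the way out.

## Command line

```sh
Rscript inst/cli/s2o.R convert study.json --data --subjectkey PID --lang en -o study.xml
Rscript inst/cli/s2o.R reverse study.xml --output-format portable --output study_back
Rscript inst/cli/s2o.R validate study.xml
```

Without `--output` the ODM document is printed to standard output; warnings
and summaries go to standard error. Exit codes: 0 success, 1 usage error,
2 input error, 3 validation failure.

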