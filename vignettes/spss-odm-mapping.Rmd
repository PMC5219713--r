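---
title: "Mapping SPSS-style datasets to CDISC ODM 1.3.1 and back"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping SPSS-style datasets to CDISC ODM 1.3.1 and back}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmconvert)
```

## The two data models

An SPSS-style dataset is a *flat* structure: an ordered dictionary of
variable definitions and a rectangular case table. Each variable carries a
name (at most 64 characters, starting with a letter or `@ # $`, unique
case-insensitively), an optional label, a print format (a code such as
`F`, `A`, `DATE` plus a display width and decimals), optional value labels
(permissible codes with human-readable decodes), an optional user-missing
specification, and the statistical/display attributes measure, role,
columns and align. Every numeric value — including calendar values — is a
double; dates are stored as seconds elapsed since 1582-10-14 00:00:00 in
the proleptic Gregorian calendar, times as seconds since midnight.
System-missing is a dedicated sentinel (`NA` in this package), distinct
from the empty string of a string variable.

CDISC ODM 1.3.1 is the opposite: a deeply *hierarchical* XML model in
which a `MetaDataVersion` holds flat collections of definitions
(`StudyEventDef`, `FormDef`, `ItemGroupDef`, `ItemDef`, `CodeList`) wired
together by referencing OIDs, and subject data mirrors that hierarchy down
to `ItemData` elements whose `Value` attribute carries the datum as text.

The converter's job is the structural mismatch between these models, and
its design goal is that every piece of information either maps faithfully
or is *reported* as dropped — never silently lost.

## The forward mapping

Because SPSS stores no protocol, event or form structure, the forward
direction inserts the variable list into a default hierarchy: exactly one
study, metadata version, protocol, scheduled study event, form and item
group (OIDs `S.1`, `MDV.1`, `SE.1`, `F.1`, `IG.1`; names "Default event",
"Default form", "Default item group"; `Repeating="No"`,
`Mandatory="No"`, order numbers from 1 in column order). The concrete
names, the mandatory policy and the `Scheduled` event type are fixed here
for determinism; nothing in the source dictionary constrains them.

Item OIDs are the variable names verbatim — they already satisfy ODM's OID
rules — and code lists are prefixed `CL.`; collisions (possible after a
subject-key exclusion or with pathological names) append the smallest
positive integer. The SPSS label becomes both the `ItemDef` `Name` and the
`Question` text, with the variable name as fallback when the label is
empty, since ODM requires a `Name`.

Print formats map onto ODM data types as follows:

| SPSS format | ODM DataType | carried along | lossy |
|---|---|---|---|
| `A`w | `string` (or `text`) | `Length` = w | no |
| `F`w.0 | `integer` | `Length` = w | no |
| `F`w.d | `float` | `Length` = w, `SignificantDigits` = d | no |
| `COMMA`, `DOT`, `DOLLAR`, `CC`, `E`, `PCT` | `float` | width/decimals | yes — grouping/currency/scientific rendering lost |
| `DATE`, `ADATE`, `EDATE`, `SDATE`, `JDATE` | `date` | — | yes — national display order lost |
| `TIME` | `time` | — | no |
| `DATETIME` | `datetime` | — | no |
| `DTIME`, `WKYR`, `WKDAY`, `MONTH`, `MOYR`, `QYR` | `string` (fallback) | width | yes — no XML counterpart |

ODM 1.3.1 distinguishes `string` from `text`; the converter emits `string`
by default and offers `text` through
`convert_options(string_datatype = "text")` — the choice is a matter of
taste for flat survey items, and `string` is the narrower contract.

Value labels become one `CodeList` per labelled variable, one
`CodeListItem` per pair in dictionary order, with the coded value rendered
exactly as the corresponding data values are (so `ItemData` values and
coded values always agree textually). The code-list `DataType` follows the
item's when it is one of `string`/`text`/`integer`/`float`, else falls
back to `string`.

Missing, measure and role have no ODM counterpart and are dropped with one
`dropped_attribute` warning each; columns and align likewise as
`dropped_display_format`. *Data values* matching a user-missing code are
exported verbatim: the dictionary's missing-value definition is lost, the
data are not, and the per-variable warning lets the receiving system
decide. Silently filtering values by a definition the output format cannot
even represent would be unrecoverable data loss.

### Clinical data

Each case becomes one `SubjectData` element holding a single
`StudyEventData → FormData → ItemGroupData` chain over the default
definitions, with one `ItemData` per non-missing cell; system-missing
cells simply produce no element. The subject key is, in order of
preference: the rendered values of the `subjectkey` column (matched
case-sensitively, excluded from item conversion), or an incrementing
number `"1"`, `"2"`, … Duplicate keys mean multiple rows per patient,
which a single-event hierarchy cannot express; the default is a hard
error, with an explicit `suffix` policy (`".2"`, `".3"`, …) as opt-in for
users who accept the renaming. Repeating-form reconstruction of
longitudinal rows is out of scope.

### Value rendering

Numbers are rendered without any display formatting: integers as minimal
integer literals, floats as the *shortest* decimal literal that parses
back to exactly the same IEEE double (no grouping separators, no exponent
notation below 10^15). This makes rendering injective on doubles, which is
what the round-trip tests rely on, and matches the behaviour of
transforming grouped formats "to usual decimal and integer values".
Calendar values are truncated to whole seconds and rendered from the
1582-10-14 epoch with exact integer calendar arithmetic; the test suite
pins this against base R's `Date` class (itself proleptic Gregorian) over
1000 seeded dates in 1900–2100.

Language codes for `TranslatedText` follow the IETF RFC 3066 grammar
(1–8 letter primary subtag, optional `-`-separated alphanumeric subtags)
and are validated *before* any conversion work; when no code is given the
attribute is omitted entirely rather than guessed.

## The reverse mapping

The reverse direction flattens the first metadata version in Protocol →
event → form → item-group → item reference order — a single event only,
since one dataset row can represent one visit; extra events raise an error
listing their OIDs rather than silently taking the first. An injected
subject-key column (string, width ≥ 8) precedes the items. Data types map
back to canonical formats (`integer` → `F`w.0, `float` → `F`w.d, strings →
`A`, `date` → `DATE11`, `time` → `TIME8`, `datetime` → `DATETIME20`; ODM
stores no national display format, so a canonical one must be chosen).
Attributes ODM never carried come back as declared defaults: no
missing/measure/role, `columns = 8`, alignment right for numerics and left
for strings — concrete numbers chosen once so that reverse conversion is
deterministic and its outputs load into real SPSS readers. Variable names
derive from item OIDs via sanitisation (invalid characters → `_`, `V_`
prefix for invalid start characters, truncation to 64, case-insensitive
uniqueness via numeric suffixes).

The composition of the two directions is the identity on the *mapped
projection* — name, label, format class, width, decimals, value labels and
all data values (calendar values to the second) — for datasets restricted
to the formats the table above maps losslessly. That property, over 200
seeded random datasets, is the package's central regression test; a third
conversion also reproduces the second's ODM byte for byte once the file
OID and timestamp are pinned.

## Serialization, parsing and validation

Parsing goes through xml2/libxml2, with the ODM namespace enforced,
unknown elements skipped with a warning (files from other EDC systems
remain usable), and a missing `ODMVersion` assumed `1.3.1` under a
warning. Serialization is a purpose-built text emitter whose element
ordering follows the ODM schema sequence; the `ClinicalData` table is
rendered with vectorised `sprintf`, which keeps a registry-scale document
(645 variables × 3452 cases ≈ 2.2 million `ItemData` elements, ~130 MB of
XML) at a few tens of seconds on one CPU where per-node DOM construction
would not be. Every serialized document in the test suite is re-read by
libxml2, so well-formedness is always checked by an independent XML
implementation.

Semantic validation is split in two: `check_structure()` (required
attributes, data-type enumeration, duplicate OIDs per class, strictly
increasing order numbers, non-empty subject keys) and
`check_referential_integrity()` (every `*Ref` and every OID used in
`ClinicalData` must resolve; unreferenced definitions are informational).
Both return issue tables rather than throwing, are pure, and are
insensitive to sibling order. The official ODM XSD is licensed by CDISC
and not bundled; `validate_against_xsd()` runs libxml2 schema validation
when the user supplies a local copy, and the internal validators cover the
same ground structurally without it.

## I/O backends

The portable dialect (JSON dictionary + RFC 4180 CSV, UTF-8, comma
separator, double-quote quoting, mandatory header) is the primary
serialization: it is an exact round trip on every dictionary field and
every double. Empty CSV cells mean system-missing under numeric formats
and the empty string under `A` — mirroring SPSS itself, where
system-missing is a numeric concept. CSV is read with readr, which
implements RFC 4180 edge cases (a quoted empty field as the only field of
a record) that base `read.csv` folds into blank lines.

Binary `.sav` reading delegates to `foreign::read.spss`, the installed
system-file reader. It does not expose print formats, measure, role,
columns or align, so `read_sav()` infers a format from each column's
storage class and records a per-variable warning; calendar variables are
indistinguishable from plain numerics without the stored format and come
back as raw epoch-seconds under `F`. No installed R library writes `.sav`,
so `write_sav()` refuses with a capability error pointing at the portable
dialect (after validating its input, so invalid datasets are still
rejected first).

## Synthetic data

`make_sample_dataset()` is the deterministic all-data-types file: 16
variables — a string identifier, a coded variable with value labels and a
user-missing code, plain/decimal/grouped/currency/scientific numerics,
five date display formats, a time, a timestamp and two week-based
renderings — over 5 cases with one system-missing cell. Its dimensions
(16 × 5) are the published dimensions of the evaluation sample file, so
the conversion counts (16 item definitions without a subject key, 5
subject records) are checked against those numbers.

`make_random_dataset(n_vars, n_cases, seed)` emulates registry datasets:
unique valid names, ~80% labelled variables, ~20% with value labels, ~10%
with a user-missing specification, ~5% system-missing cells, all format
codes reachable, all reproducible from the seed (the caller's RNG stream
is left untouched). `mappable_only = TRUE` restricts to round-trip-stable
formats and prepends a unique `PID` column. The test corpus runs 200 such
datasets of 2–8 variables and 0–9 cases — small enough that the whole
suite stays in minutes, large enough that every format, missing-pattern
and labelling branch is exercised many times — plus one full-scale run at
645 × 3452, the largest configuration the converter is expected to meet in
practice.

What these generators do *not* emulate: real registries' value
distributions, genuinely longitudinal data (multiple rows per patient),
non-Latin text, and dictionary pathologies such as near-64-character
names. Passing tests therefore demonstrate the conversion semantics and
scale behaviour, not robustness against arbitrary real-world `.sav`
content — the `.sav` dictionary itself arrives through `foreign` with the
limitations above.

## Known limitations

* One language per document: SPSS labels exist in a single language, so
  multi-language `TranslatedText` is out of scope.
* Multiple rows per patient are rejected (or suffixed on request), not
  restructured into repeating forms.
* AdminData, ReferenceData, Association, signatures, audit records,
  measurement units and the Define-XML/Dataset-XML dialects are not
  modelled.
* Attributes with no ODM counterpart (missing/measure/role/columns/align)
  cannot survive a round trip; a vendor extension could carry them but
  would not be portable across EDC systems.
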