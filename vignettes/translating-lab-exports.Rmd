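---
title: "Translating instrument EAV exports into EDC flat-table imports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating instrument EAV exports into EDC flat-table imports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eavflat)
```

## The problem

Longitudinal clinical studies — the motivating setting is a multi-year COPD
biomarker study with scheduled blood-draw visits and unscheduled
exacerbation events — accumulate large volumes of clinical-chemistry
results. The laboratory instruments export these as entity–attribute–value
(EAV) CSV files: one row per measurement, with the participant code, an
event token, a date, the biomarker identifier and the value. The study
database lives in an electronic data capture (EDC) system (REDCap in the
motivating case), which imports *flat* CSV tables keyed by record id and
event name, with one column per field, and whose field names usually differ
from the instrument's attribute names. `eavflat` performs the translation
automatically and conservatively, so that results enter the EDC through its
audited import paths rather than by hand or via direct database writes —
direct writes would bypass the EDC's own pre-import screening.

## The two-stage model

Translation is a composition of two total, deterministic maps:

1. **EAV → hierarchy.** Records are organised into a tree with exactly five
   levels: the study id at the root, then participants, then events
   (scheduled visits and exacerbations share this level and are
   distinguished only by token, e.g. `visit_2` vs `exacerbation_1`), then
   biomarkers, then the single value each biomarker holds at that event.
   Insertion preserves order of first appearance, which makes every
   traversal — and therefore every output file — deterministic.
2. **Hierarchy → flat table.** Each leaf `(entity, event, attribute, value)`
   whose attribute the configuration maps to a field `f` writes `value`
   into the cell at row `(entity, event_map(event))`, column `f`, of a
   template exported from the EDC. Everything not targeted by a leaf —
   header order, row order, every other cell — is preserved byte for byte.

The intermediate tree is what makes the translator configurable: either
side of it can be re-bound to a different dialect without touching the
other. The study-id root never appears in the flat output (EDC exports
carry no study column); it exists as the tree's label only.

An inverse, `unflatten()`, recovers the mapped EAV tuples from a filled
table (dates excepted — a flat table does not carry them). It exists for
round-trip verification, which the test suite exercises on hundreds of
generated studies.

## Configuration

A YAML file (schema key set is versioned via `schema_version: 1`) binds
everything the two stages need:

* **column roles** — `entity_column`, `event_columns`, `date_column`,
  `attribute_column`, `value_column`. `event_columns` is an ordered list:
  instrument files sometimes split visits and exacerbations across two
  columns, one blank per row, and the first non-empty cell wins. A file
  with one combined event column binds just that column.
* **`attribute_map`** — instrument attribute → EDC field, exact and
  case-sensitive. Case-folding could silently merge distinct assays, so a
  case mismatch surfaces as an unmapped attribute instead. Targets must be
  unique: many-to-one merging is rejected at load time because two source
  assays writing one column could only collide or silently shadow each
  other.
* **`event_map`** — optional renaming of event tokens (defaults to the
  identity, which suits instruments that already use the EDC's tokens).
* **policies** — what to do with an unmapped attribute (`error` or
  `skip_with_warning`), a missing template row (`error` or `append`, new
  rows go to the end in first-appearance order), and a duplicate
  measurement (`error` or `last_wins`). All three default to `error`: the
  output is destined for an audited clinical database, so surprises should
  stop the run unless the study explicitly opts out. A duplicate with an
  *identical* value is always deduplicated silently (and counted), since it
  carries no conflict. A template cell that already holds a different value
  is always an error — never an overwrite.

## Values are opaque strings

Values travel verbatim from the instrument file to the import file: no
numeric parsing, so `"6.50"` is never normalised to `"6.5"`, and trailing
whitespace inside a value survives. Identifiers (entity, event, attribute),
by contrast, are trimmed of surrounding whitespace because they are join
keys. Dates are opaque tokens (`150321`): the pipeline never does calendar
arithmetic, and date interpretation belongs to the EDC's own field
validation.

## Screening before import

`validate_flat()` mirrors the EDC's pre-commit screening locally. Rules
bind a field to a kind — `numeric`, `integer`, `text`, `date_string` — with
optional inclusive bounds for the numeric kinds and a `required` flag.
Numeric syntax accepts a decimal point only; comma decimals are
"incorrectly formatted" by design, since locale-dependent parsing of
clinical values is exactly the kind of silent corruption the screen exists
to catch. `date_string` accepts the compact digit tokens instruments emit
(YYMMDD, YYYYMMDD) or ISO `YYYY-MM-DD` — a shape check, not a calendar
check. Screening is advisory by default (a report, never a mutation);
the CLI's `--strict` switch turns any issue into a failing exit code.
A required-but-empty cell counts as a screened cell, so the report
invariant "no issues iff nothing rejected" holds uniformly.

## The web-API path

`import_records()` posts the table to a REDCap-compatible record-import
endpoint as one form-encoded request (`token`, `content=record`,
`format=csv`, `data=<payload>` — the de-facto convention for this API
family; the payload field set is an interface assumption documented here).
The payload is produced by the same serializer as `write_flat()`, so what
the API receives is byte-identical to what the CSV path would write.
Transport failures retry 3 times with exponential backoff; a reachable
server that rejects the batch yields a result object carrying the server's
messages verbatim (or an error under `strict`). Tokens are read from a file
or the `EAVFLAT_TOKEN` environment variable, never a bare CLI argument, and
are redacted from every log and error message. The package bundles a
minimal loopback stub implementing just this endpoint, so the client is
tested hermetically.

## The synthetic-study generator

`generate_study()` emulates the structure of the motivating study: every
participant attends `visits_per_patient` scheduled visits, and each
inter-visit interval carries an `exacerbation_rate` chance of an
unscheduled exacerbation event. Each event yields one measurement per
biomarker, drawn uniformly from that biomarker's range and formatted with
at most two decimals, matching instrument output style. Defaults — 20
participants, 4 visits, rate 0.15, and four clinical-chemistry biomarkers
with adult reference ranges (calcium 2.0–3.0 mmol/L, leukocytes 3–10
×10⁹/L, haemoglobin 115–170 g/L, monocytes 0.2–1.0 ×10⁹/L) — were chosen
once as a realistic small study slice. The generator emits a mutually
consistent EAV table, blank template, config, bounds rules, and a *ledger*
of ground-truth tuples; everything is reproducible byte-for-byte from the
seed, and the caller's RNG stream is restored afterwards.

What the generator does **not** emulate: disease effects on biomarker
levels, missing or repeated measurements, ragged instrument quirks, or
free-text contamination. Passing tests therefore demonstrate structural
correctness of the translation on clean longitudinal data, not robustness
to every real instrument's pathology — though malformed-CSV, duplicate and
conflict handling are tested separately with hand-built inputs.

## Verification strategy and numerical choices

* **Oracle equivalence.** `flatten()` is checked cell-for-cell against a
  brute-force nested-map oracle that fills the template directly from the
  raw EAV rows, bypassing the hierarchy entirely. The suite runs a few
  hundred random studies (up to ~170 records each; sizes chosen to keep a
  full run in seconds) through both routes.
* **Round trips.** Read–write–read is the identity on EAV tables and flat
  tables; `unflatten(flatten(x))` recovers the mapped tuple set exactly.
* **Determinism.** Identical inputs produce byte-identical output files;
  the CSV writer quotes minimally (only cells containing a comma, quote or
  newline), writes LF, and accepts CRLF on read — so an untouched template
  survives a read/write cycle byte-identically.
* **Degenerate inputs.** Header-only files, empty tables, empty attribute
  maps, and zero-patient specs all flow through as empty-but-well-formed
  objects rather than errors.

## Known limitations

One row per (record, event): repeating-instrument layouts with several rows
per event are not modelled. The translator emits a new import file and
never merges in place. Only the four rule kinds above are screened —
checkbox fields, branching logic and the rest of a full EDC's validation
zoo are out of scope, as is any data analysis on the translated values.
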