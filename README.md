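# eavflat

Clinical-chemistry laboratory instruments in longitudinal studies export
biomarker results as **entity–attribute–value (EAV)** CSV files: one row per
measurement, carrying the participant code, the visit or exacerbation event,
an opaque date token, the biomarker identifier and the measured value.
Electronic data capture (EDC) systems such as REDCap work the other way
round: they export and import **flat tables** — one row per (record id,
event name), one column per field — and screen incoming values before
committing them to the database. Entering instrument results by hand is slow
and error-prone, and the two dialects rarely share variable identifiers.

`eavflat` automates the translation for data managers of such studies. It
reads the instrument EAV export, organises it into a five-level hierarchy

```
study ── participant ── event (visit | exacerbation) ── biomarker ── value
```

and flattens that hierarchy into the CSV template exported from the EDC,
under a declarative YAML mapping configuration that binds source columns to
roles, maps instrument attribute names to EDC field names (e.g.
`calcium → Ncal`), and fixes what happens on unmapped attributes, missing
template rows, or conflicting duplicates. Values travel as verbatim strings
end to end — the translator never reformats a number. Before import, the
table can be screened locally against type and bounds rules (mirroring the
EDC's own pre-commit screening), and the result can be written as an import
CSV or pushed directly through a REDCap-compatible web API. A synthetic
longitudinal-study generator produces coherent EAV/template/config/rule
quadruples for testing pipelines.

## Worked example

The package ships a desk-scale reference study: two participants, events
`visit_1`, `visit_2` and `exacerbation_1`, biomarkers calcium and
leukocytes, and a blank four-row EDC template with fields `Ncal`, `leuco`,
`hb`, `mono`.

```r
library(eavflat)
ex <- example_study()
filled <- translate(ex$eav, ex$template, ex$config)
filled
#> <flat_table> 4 row(s) x 4 field column(s) [keys: patient_id, redcap_event_name]
#>   8 non-empty data cell(s)
#>   patient_id redcap_event_name Ncal leuco hb mono
#> 1     100001           visit_1  6.2   6.5
#> 2     100002           visit_1 2.45   6.5
#> 3     100001           visit_2 2.51   6.2
#> 4     100002    exacerbation_1 2.44   8.1
```

Exactly the eight mapped measurements are filled in; `hb` and `mono`, which
no attribute maps to, stay blank, as does every other template byte.
Screening the result against a calcium bound of 2.0–3.0 mmol/L flags the
one implausible cell:

```r
rules <- load_rules(system.file("extdata", "example_rules.yaml", package = "eavflat"))
validate_flat(filled, rules)
#> <validation_report> 8 cell(s) screened, 1 rejected, 1 issue(s)
#>   entity   event field    kind                   message
#> 1 100001 visit_1  Ncal numeric value 6.2 above maximum 3
```

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("exec", "eavflat", package = "eavflat")`):

```sh
eavflat translate --eav eav.csv --template template.csv \
        --config config.yaml --rules rules.yaml --out import.csv --strict
eavflat push --in import.csv --endpoint https://edc.example.org/api/ \
        --token-file ~/.edc-token
```

Exit codes: 0 success, 1 screening/rejection failure under `--strict`,
2 any other error.

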