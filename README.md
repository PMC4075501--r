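# regkit

A metadata-driven patient registry engine for R. Registry curators —
clinicians and data managers, not software developers — define reusable
**data elements** (typed fields with validation rules and permitted value
groups), compose them into the forms and sections of any number of
registries, and capture per-patient records against those definitions in
isolated, schema-less per-registry collections. Everything downstream is
derived from the definitions at run time: entry validation, record
schemas, derived values, field-level access filtering, and a canonical
YAML interchange format for whole registry definitions.

The core ideas:

* **Shared data elements.** A DE is `(code, datatype, validation)` with
  datatype one of `integer | float | string | date | file`; numeric DEs
  take inclusive `[min, max]` bounds, string DEs a full-match regex
  pattern or a permitted value group (e.g. `Size = {large, medium,
  small}`). One element serves many registries; editing it once reaches
  all of them.
* **Derived data elements.** A DDE such as `BMI = Weight / Height²` is
  declared by a closed arithmetic/conditional expression over other DE
  codes, evaluated on every read and never stored — so it is fresh by
  construction, and `NOT_COMPUTABLE` (an in-band value) when inputs are
  missing.
* **Schema-less records.** Each captured field is one key–value pair,
  keyed `form/section/code`, in a per-patient document inside a
  per-registry collection (in-memory or durable JSON-lines backend; file
  uploads as SHA-256 content-addressed blobs).
* **Field-level access control.** Workgroups bound which patients a user
  sees; `(role, registry, element-or-*, access)` rules with default deny
  and most-specific-deny semantics bound which elements, down to the
  individual field.

## Worked example

```r
library(regkit)

eng <- demo_engine()                       # DM1 demonstration registry
add_patient(eng, "dm1", "p1")
put_value(eng, "dm1", "p1", "Height", 1.8) # metres
put_value(eng, "dm1", "p1", "Weight", 81)  # kilograms
get_value(eng, "dm1", "p1", "BMI")
#> <BMI = 25 (float)>

put_value(eng, "dm1", "p1", "Weight", 90)  # derived values track inputs
get_value(eng, "dm1", "p1", "BMI")
#> <BMI = 27.777777777777775 (float)>
```

`25` is the body mass index 81 / 1.8² computed on read; after the weight
update the very next read reflects it — there is no recompute step. Access
control filters whole documents per element: the demonstration rules deny
the clinical role the genetics section, so with a CTG repeat length of 300
on record,

```r
put_value(eng, "dm1", "p1", "CTGRepeatLength", 300)
eng$assign_patient_to_workgroup("DM1Unit", "dm1", "p1")
view_document(eng, "clinical", "dm1", "p1")
#> <patient p1 in registry dm1: 3 entries>
#>   Clinical/Anthropometry/Height = 1.8
#>   Clinical/Anthropometry/Weight = 90
#>   Clinical/Anthropometry/BMI = 27.777777777777775
```

— the genetics entry exists but is omitted entirely from the clinical
view. The whole definition exports to one canonical, version-controllable
YAML file and imports back identically:

```r
text <- export_registry(eng, "dm1")
eng2 <- registry_engine()
import_registry(eng2, text)
identical(export_registry(eng2, "dm1"), text)
#> [1] TRUE
```

A command-line interface over the same engine lives at
`system.file("cli", "regkit", package = "regkit")` (subcommands for
registries, elements, PVGs, patients, files, ACL and fixtures; state under
`--data-dir`, acting user via `--as-user`).

See the vignette (`vignettes/registry-engine.Rmd`) for the full model:
validation semantics, the expression grammar and its sandbox, storage
backends, access-rule resolution, and what the synthetic fixtures do and
do not establish.

## Acceptance script

`scripts/acceptance.R` re-runs the engine end to end from a fresh start —
builds the demonstration registry, generates and loads 50 seeded synthetic
patients, verifies derived-value reads and access filtering, and
round-trips the definition through YAML — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
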