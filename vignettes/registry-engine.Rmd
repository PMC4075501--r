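---
title: "Registries as data: the regkit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registries as data: the regkit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient registries — for rare diseases especially, where thousands of
conditions each need their own instrument — are classically built as static
software: every data field is implemented in code, so every new registry and
every new measurement costs developer time. regkit takes the opposite
stance: the registry definition is *data*. Curators define typed, reusable
**data elements** (DEs) once, compose them into forms and sections across
any number of registries, and the engine derives everything else — entry
validation, record schemas, derived values, access filtering, interchange
files — from those definitions at run time. A date-of-birth element defined
once can serve ten registries, and a correction to it reaches all ten.

```{r}
library(regkit)
eng <- registry_engine()
define_element(eng, "DOB", "Date of birth", "date")
create_registry(eng, "dm1", "Myotonic Dystrophy", "1.0")
attach_element(eng, "dm1", "Demographics", "Identity", "DOB")
```

## The definition model

A **DataElement** has a globally unique code, one of exactly five datatypes
— `integer`, `float`, `string`, `date`, `file` — and datatype-specific
validation: inclusive `min`/`max` bounds for the numeric types, and for
strings either a regular-expression `pattern` or membership in a
**permitted value group** (PVG), a reusable enumeration such as
`Size = {large, medium, small}`. Patterns are anchored full-match: a
credit-card pattern `\d{4} \d{4} \d{4} \d{4}` accepts `"1234 5678 9012
3456"` and nothing longer or shorter. Dates use ISO-8601 (`YYYY-MM-DD`) as
their canonical text form, integer coercion rejects fractional text
(`"4.2"` is a type error, not a rounding), and a blank entry on a
non-required element stores *no* key rather than an empty value. None of
these three conventions is forced by the model; they are this package's
choices, fixed here so that rendering and re-validating a value is always
an exact round trip.

Validation reports **every** violated rule as a value, not an exception:

```{r}
age <- data_element("Age", datatype = "integer", min = 0, max = 120)
validate_value(age, "130")   # a range error, as data
```

Note that the rule system makes the violated-rule sets mostly singletons by
construction: rules beyond the type check are mutually exclusive per
datatype (`pattern` and `pvg_code` cannot coexist, bounds require a
parseable number first). The completeness contract — *k* independently
violated rules yield exactly *k* errors — is still tested against a
brute-force rule checker across random elements and inputs.

## Derived data elements

A **derived data element** (DDE) — body mass index from height and weight
is the canonical case — is computed, never entered and never stored. Where
the original web framework attached a JavaScript snippet to each DDE, this
package deliberately substitutes a closed expression grammar: numeric
literals, DE references, `+ - * / ^`, comparisons, and `if/else`, with
standard precedence. Evaluating arbitrary scripts over patient data is a
sandboxing liability and unportable; the documented use case needs only
arithmetic. Expression text is tokenized by R's parser, then converted
through a whitelist walker into the package's own AST; evaluation is the
package's own interpreter over an explicit context, so an expression
*cannot* reach a file, the store, or the clock — the safety property holds
by construction rather than by filtering.

Because DDE values are recomputed on every read, the freshness claim —
derived values update as soon as their inputs change — is also structural:
there is no cache to invalidate.

```{r}
add_patient(eng, "dm1", "p1")
define_element(eng, "Height", datatype = "float", min = 0.3, max = 2.5, units = "m")
define_element(eng, "Weight", datatype = "float", min = 1, max = 300, units = "kg")
define_derived(eng, "BMI", "Body mass index", "float",
               "Weight / (Height * Height)")
for (code in c("Height", "Weight", "BMI")) {
  attach_element(eng, "dm1", "Clinical", "Anthropometry", code)
}
put_value(eng, "dm1", "p1", "Height", 1.8)
put_value(eng, "dm1", "p1", "Weight", 81)
get_value(eng, "dm1", "p1", "BMI")   # 25, computed on read
```

When an input is missing or arithmetic degenerates (division by zero,
non-numeric operand), the result is the in-band `NOT_COMPUTABLE` sentinel
rather than an error, so a partially filled record still renders as a
whole. That sentinel is this package's contract for missing inputs; the
numeric model is double precision throughout, with integer-typed DDEs
rounded half-to-even at the end.

## Schema-less record storage

Patient data lives apart from definitions, mirroring the original
architecture's split between a relational metadata store and a schema-less
document store. Each captured field is one key-value pair in a per-patient
document; the key folds the form structure into a flat injective encoding,
`form/section/code` with `%`-escaping of the separator. Each registry is
isolated in its own collection — no write sequence through one registry is
observable through another, which is also what makes per-registry
permissioning simple.

Two backends implement one contract: an in-memory store, and a durable
append-logged store (one UTF-8 JSON-lines file per collection, one full
document state per line, last-writer-wins on replay; a deleted patient is a
tombstone line). A differential property test drives both backends through
identical random operation sequences — including a cold reload of the file
store — and requires identical observable behaviour. Uploaded files
(consent forms and the like) are content-addressed blobs keyed by SHA-256;
storing the same bytes twice yields the same digest, and deleting the last
referencing patient releases the blob. One value per key is stored;
longitudinal/repeating sections are out of scope.

## Access control

Access is enforced at two independent levels. **Workgroups** bound which
patients a user can see at all: a non-admin's visible set is the union of
their workgroups' patient sets, and a document outside it is a hard error,
not an empty view. **Permission rules** `(role, registry, element-or-*,
access)` gate individual elements, default deny, with the four
demonstration roles (admin, curator, genetic, clinical) as the default
vocabulary.

One design point was genuinely open: "most-specific rule wins" and
"adding a grant never removes access" conflict if grants at different
specificities can override each other (an exact `read` under a wildcard
`read_write` would demote write access). The resolution chosen: effective
access is the strongest matching **grant** not overridden by a *strictly
more specific* `none` rule. An exact `none` still beats a wildcard grant
(the fixture's clinical role is denied exactly the genetics elements while
holding a wildcard `read_write`), and adding a grant is monotone — both
properties are tested, the latter over random rule tables. A derived
element's readability is deliberately independent of its inputs': a user
may see BMI but not Weight.

## YAML interchange

`export_registry()` writes one self-contained file: registry metadata and
layout, every element in the registry's *closure* (section codes plus
transitive DDE inputs, so the file never dangles), the PVGs those elements
reference, and the registry's permission rules. Export is canonical —
fixed key order, code-sorted lists, deduplicated rules, doubles at 17
significant digits — so identical definitions give byte-identical files
fit for version control. Import is transactional (checked before applied)
and idempotent: an identical redefinition is a no-op, a conflicting one is
an error, protecting shared elements that other registries already use.
Patient records are not part of the definition file; `export_records()`
dumps a collection as JSON lines separately.

## The demonstration fixture and synthetic patients

`build_demo_bundle()` constructs a DM1-flavoured demonstration registry:
two forms, four sections, all five datatypes, the `Size` PVG, a BMI DDE
over Height and Weight, the four demo roles, and fixture rules (clinical
denied the genetics section, curator read-only). The clinical field
inventory (CTG repeat length, repeat expansion size category, insurance
number, consent upload) is representative and invented for the fixture;
its plausibility beyond the declared range constraints is not attempted —
it is a test harness, not a cohort simulator. Defaults we had to choose:
Height 0.3–2.5 m, Weight 1–300 kg, age at onset 0–120 years, CTG repeats
5–4000 (spanning normal to congenital-range alleles), dates uniform over
1940–2010.

`generate_patients(bundle, n, seed)` draws uniform values inside each
element's declared range, synthesizes pattern strings from a documented
regular-expression subset (verifying each synthesized string against the
full pattern), and uses R's Mersenne-Twister stream with the kind set
explicitly — never the session default — so a seed reproduces records
byte-for-byte across platforms. Every generated value passes validation; a
property test checks >10,000 of them.

What a green suite establishes, and what it does not: the tests prove the
engine's contracts — validation completeness, DDE freshness, collection
isolation, round-trip identity, ACL equivalence with a brute-force oracle
— on synthetic definitions and records. They say nothing about clinical
content quality, real-world form ergonomics, multi-process concurrency, or
scale beyond desk-size cohorts (the record store scans linearly and is
explicitly single-writer).

## Command line

The CLI (`inst/cli/regkit`, a thin Rscript over the library) replaces the
original web administration screens for scripted use: `registry
create|list|validate|export|import`, `pvg define|list`, `de
define|list|catalogue`, `dde define`, `patient
add|list|set|get|show|delete`, `file put|get`, `acl grant|revoke|show`,
`user add`, `workgroup assign`, `fixtures demo|patients`. State persists
under `--data-dir`; `--as-user` names the acting user and is trusted —
authentication is out of scope, authorization semantics are the library's
contribution. Definition-changing commands require an administrator-tier
role (admin, or curator for non-ACL changes); reads and writes of patient
data resolve through the same `can_access`/`view_document` path as the
library. Exit codes: 0 success, 1 domain error, 2 usage error.

## Known limitations

* No versioned migration of stored records when a definition changes;
  deleting an element is simply refused while any registry references it.
* One value per key: no repeating sections or longitudinal history.
* Single-process storage; no locking, replication, or indexing.
* The regular-expression synthesizer for fixtures covers a documented
  subset (literals, `\d \w \s`, classes with ranges, groups, alternation,
  `? + * {n} {n,m}`) and errors on anything else rather than guessing.
* String- or date-valued derived elements and cross-patient aggregate
  expressions are out of scope for the expression grammar.
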