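---
title: "Methods and design of mzqckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mzqckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzqckit)
```

## The document model and its assumptions

An mzQC report is a JSON object under a single root key `"mzQC"`. The model
in this package mirrors the format's members one-to-one (camelCase field
names are kept so serialization is transparent) and enforces its invariants
at construction time: a format version matching `digits.digits.digits` and
equal to `1.0.0`; an ISO-8601 creation timestamp with date, time, and
seconds; at least one controlled-vocabulary reference; at least one quality
element; unique metric accessions within an element; unique input-file
names within a metadata block; at least one input file for run-level and at
least two for set-level elements; and CV accessions matching
`^[A-Z]+[A-Z0-9]*:[0-9]+$`.

Three of these deserve comment because the design was genuinely open:

* **Version pinning.** Only `1.0.0` is accepted. A well-formed but
  different version is rejected with a distinct message, so that a future
  format release fails loudly rather than being silently misread.
* **Set-level cardinality.** Requiring ≥ 2 input files for a `setQuality`
  follows the intent of a "set of runs"; a set describing one run would be
  a run-level element in disguise.
* **Null metric values** are rejected outright: a metric with no value
  carries no QC information, and permitting nulls would force every
  consumer to special-case them.

Metric values come in three kinds. Classification is purely structural: a
named mapping of equal-length columns is a `table` (held as a tibble), an
unnamed sequence is a `tuple`, a single atom is a `scalar`. A mapping with
unequal column lengths is a *ragged table* and is always an error. Because
R cannot distinguish a length-one vector from a scalar, a one-element tuple
must be constructed explicitly (`mzqc_value(list(x), kind = "tuple")`); the
reader preserves the distinction from the JSON side automatically.

## Serialization choices

* **Structural, not byte-wise, round-trip equality** is the contract
  (`mzqc_equal()`): JSON object members are unordered, so key order and
  whitespace are free; list order is significant and preserved.
* **Numbers are written with 17 significant digits**, the number needed to
  reproduce an IEEE double exactly, so `read(write(doc))` is numerically
  identical, not merely close.
* **Tolerant reader, faithful writer.** Unknown members anywhere in the
  document are kept in an `extras` slot and re-emitted verbatim, for
  forward compatibility with format evolution. Whether the official schema
  permits such members is not something this package asserts; preservation
  is a deliberate tolerant-reader stance.
* **Absent optionals are omitted**, never written as `null`.
* **No remote fetching.** `read_mzqc_file()` reads local files only; a
  caller who wants a remote document fetches the text and uses
  `read_mzqc()`. This keeps the library and its tests hermetic.
* Strict reading re-validates the parsed document and reports the
  *document path* (`mzQC/runQualities/0/...`) of the first violation;
  `strict = FALSE` parses structure-only so the validators can inspect
  deliberately broken documents.

## Validation

Syntactic validation checks text against the format's structural rules and
**never throws**: unparseable JSON is itself a finding (`not-json`), and
all findings are collected rather than failing fast, because a validator's
product is a usable report. Paths use slash notation with zero-based
indices. Rule ids are stable identifiers (`required-missing`,
`invalid-version`, `ragged-table`, `duplicate-metric`, ...).

Semantic validation interprets the document against a CV store. The
severity taxonomy is this package's decision: identity-breaking problems —
unresolvable accessions, value shapes contradicting the term's declared
type (including missing required table columns), duplicate metric
accessions, duplicate input-file names — are errors and block the `valid`
verdict; advisory findings — name mismatches (the accession, not the label,
carries identity), obsolete terms, CV prefixes with no matching
`controlledVocabularies` entry — are warnings. Name comparison is
case-sensitive after trimming surrounding whitespace. Scalar type
strictness is asymmetric on purpose: where the CV declares a numeric
scalar, a text or boolean value is an error; where it declares text, a
numeric value is tolerated. Since the format's CV reference has no prefix
field, a prefix counts as "listed" when it appears as a word in any
reference's name or URI — a heuristic, documented as such.

The CV itself is parsed from OBO, offline only: `[Term]` stanzas with
`id`, `name`, `def`, `is_a`, `is_obsolete`, and value-type declarations in
`xref: value-type:...` / `xref: required-column:...` lines. Terms without a
value-type declaration are exempt from type checking. Only `is_a` is
interpreted; `[Typedef]` stanzas are skipped. The `is_a` closure must be
acyclic — a cycle is a load-time error rather than an infinite traversal.
The toy CV shipped for testing is generated from the same catalog the
metric functions use, so emission and validation cannot drift apart; users
drop in the real PSI-MS CV by passing their own OBO file.

## QC metrics

Units are fixed internally: retention times in seconds, m/z in Thomson,
injection times in milliseconds; readers of minute-denominated inputs must
convert on ingestion. Monoisotopic constants (20 residue masses, water
18.0105646863 Da, proton 1.00727646688 Da) live in one table,
`monoisotopic_mass_tables()`, for auditability.

Tunable parameters and their defaults:

* `q_threshold = 0.01` — PSMs with q-value at or below this enter the
  identification metrics, echoing the common 1% FDR filtering convention.
  The threshold applies to whatever q-value column the upstream tool
  produced; this package does not recompute FDR.
* Cleavage rule — cut after K/R, not before P (trypsin), as
  `cut_after`/`no_cut_before` parameters with those defaults.
* Peptide distinctness uses modification-stripped sequences (bracketed
  mass offsets removed); the simpler of the available conventions, chosen
  and documented rather than left ambiguous.
* ppm errors are computed at the m/z level (observed vs theoretical m/z at
  the PSM's charge), not at the neutral-mass level.

Two emission choices: the *base peak* metric is the full per-spectrum trace
(a table over retention time), which subsumes a single maximum; and an MS
level with no recorded injection times yields *no* metric for that level —
omission, not zero, since zero would be a plausible measurement. The ppm
summary tuple is `[mean, sd, median]`; with a single accepted PSM the
spread is reported as 0 rather than undefined, so the tuple never carries a
null. With zero accepted PSMs the count metrics are 0 and the distribution
metrics are omitted.

## Merging and the heatmap report

Partial documents are merged on **run identity = location of the first
input file, falling back to its name** — the format does not define a join
key, and the file location is the most stable identifier a pipeline has.
Metrics are unioned per run; software lists, input files, and CV references
are deduplicated by their natural keys; the merged document gets a fresh
creation date. When two documents carry the same metric for the same run
with *unequal* values the default is an error ("metric conflict", naming
run and accession), because a silently chosen value would make the merged
report untrustworthy; `on_conflict = "keep-first"` downgrades this to a
warning for pipelines that know their precedence.

Percentile ranking is applied **per metric across runs** (row-wise).
Ranking across the combined matrix would mix units — counts, intensities,
milliseconds — into one distribution; row-wise ranking makes every row the
answer to "where does this run sit among its peers on this metric".

Clustering uses agglomerative hierarchical clustering with average linkage
on Euclidean distances, computed over pairwise-complete entries (missing
cells are excluded and the remaining squared differences rescaled, the
standard `dist()` behaviour). Linkage and metric are configurable; the
defaults are the unexciting, widely used choices for QC heatmaps. Two
numerical details ensure determinism: rows and columns are pre-sorted by
label before clustering, so the leaf order cannot depend on input
permutation; and a row or column with no pairwise-complete overlap with any
other is an error naming it, rather than a `NA` distance propagating into
the dendrogram. The rendered heatmap maps rank 0 to the darkest shade and
rank 100 to the lightest, with a condition colour strip when group labels
are supplied; the TSV export contains exactly the ranked matrix in
clustered order.

## The synthetic experiment generator

`experiment_spec()` describes a desk-scale two-condition DDA study: 8 runs
(4 DMSO-control and 4 sulforaphane-treated replicates), a 7200 s gradient,
400 MS1 scans each triggering 5 MS2 scans, log-normal peak intensities,
normal injection times per MS level (MS1: 5 ± 1 ms, MS2: 25 ± 5 ms,
truncated at 0.1 ms), precursor mass errors drawn from N(μ = 2 ppm,
σ = 3 ppm), tryptic peptides from a 50-protein × 200-residue toy proteome
with up to three missed cleavages (probabilities 0.70/0.20/0.08/0.02 for
0–3), and half of the MS2 spectra identified at q ≤ 0.01, which yields
exactly 1000 accepted PSMs per run at the default scale. A fraction of the
unidentified spectra receive high-q decoy PSMs so the q-value filter is
actually exercised, and identified peptides occasionally carry a bracketed
methionine-oxidation offset so modification stripping is exercised too.
Every draw flows from a single integer seed, and the generator bookkeeps
its own ground truth with plain arithmetic (sums, sorts) independent of the
metric implementations.

What the generator deliberately does **not** emulate: chromatographic peak
shapes, isotope envelopes, fragment-spectrum content, retention-time
structure (scan times are uniform over the gradient), intensity
correlation between MS1 and MS2, or realistic shared-peptide structure
between proteins. Tests passing on this generator therefore demonstrate
*bookkeeping correctness* — counts, distributions, and transformations
computed exactly as defined — not robustness to the messiness of real
instrument data.

## Testing strategy and problem sizes

Unit tests pit every computation against an independently coded oracle:
per-spectrum summation loops for the TIC, sorting-based statistics for
injection times, explicit site enumeration for missed cleavages (10,000
random peptides with K/R/P-enriched sequences), the counting definition of
percentile ranks (1,000 tied vectors), breadth-first search for CV
reachability, and the generator's ground truth for all identification
counts (exact) and floating metrics (within 1e-9 relative). Serialization
is checked by structural round-trips over 100 seeded random documents. The
syntactic validator is additionally compared against a second, fully
schema-driven route: a generic JSON-Schema interpreter in the test helpers
applied to `inst/extdata/mzqc_schema_synthetic.json`, this package's own
transcription of the format's structural rules (labelled synthetic — it is
not the official schema), with two extension keywords for constraints
draft-07 cannot express (equal-length table columns, uniqueness by field).
Verdicts agree on the whole labeled fixture catalog of ≥ 20 valid and 15
invalid documents.

Test problem sizes (30–50 MS1 scans per run in most suites, the full
400-scan default in the acceptance run) were chosen as the smallest scales
at which every distributional check is still meaningful.

## Known limitations

* Only mzQC 1.0.0 is read or written.
* OBO parsing covers the subset the semantic checks need; OWL, term
  intersections, and non-`is_a` relationships are out of scope.
* The validator's rule list reconstructs the format's structural rules;
  it is not generated from the official schema.
* Real PSI-MS accessions are not bundled: the metric catalog uses the toy
  `QCX` prefix, and swapping in PSI-MS accessions is a one-table edit
  (`qc_metric_catalog()`), documented as the intended extension point.
* The merge conflict detector compares canonical values exactly; two runs
  of the same tool differing by floating-point noise are a conflict, which
  is intentional but may surprise.
* mzML support is a convenience reader over mzR plus a deliberately
  minimal writer; it is not a general mzML exporter.
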