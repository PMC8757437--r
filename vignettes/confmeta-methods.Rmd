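---
title: "confmeta: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{confmeta: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confmeta)
```

This vignette documents the data model, the metastatement language
semantics, the numerical and syntactic choices that were genuinely open,
and what the synthetic fixture generator does and does not emulate.

## The ensemble model

An SDfile is parsed into an ordered list of conformation records, each a
verbatim V2000 molfile plus a name→value metadata map. Only four fields
of each atom line are interpreted (x, y, z in columns 1–30, the element
symbol in columns 32–34); the atom, bond and property blocks are carried
verbatim, so structures that no operation touches round-trip bit-exactly.
Records are grouped by a key — the header name by default, or the string
form of any single-valued metadata field via `regroup()` — and numbered
1..k within each group in file order. A conformation number can travel
with the file through an explicit name tag, `NAME{[conf|N]}`; `{` and `[`
do not occur in common molecule-naming schemes, so tagged and plain names
cannot collide. An encoded number wins over sequential assignment, and a
duplicated (group, number) pair is an error rather than a silent renumber.

Filtering never renumbers conformations; renumbering happens only on the
explicit CLI flag `-renumber` (or by regrouping), so that pose identities
remain stable across chained invocations.

## Extended data-item notation

The body of a data item is interpreted as, in order: a dictionary when
every whitespace-separated token is a `key:value` pair; a list when there
are several plain tokens; otherwise a single value. Scalars are tried as
integer, then float, then kept as string, and mixed coercions degrade the
whole item to strings so a value never silently changes type relative to
its neighbors. Three consequences of this design are worth stating:

* A literal single *string* that would mis-detect (it contains whitespace
  or looks like a `key:value` pair) is written with an explicit
  structure-override prefix, `[single] `, which the reader strips. Plain
  SDF files never contain the prefix, so standard files are unaffected;
  our own output stays standard-compatible (other tools will read the
  body as text, which is the fallback the notation is designed around).
* Bodies wrap at 200 characters on write, breaking at token boundaries,
  and wrapped lines re-join with a space on read — long atom-wise
  dictionaries survive SDF readers that dislike very long lines.
* Because "no value" and "no metadata" are the same thing, an empty body
  parses to nothing and an empty evaluation result is never stored.

Floats are serialized with the shortest decimal representation that
round-trips to the identical double (tried at 7, 10, 15, then 17
significant digits), which is what makes parse→write→parse an identity on
numeric metadata without printing 17 digits everywhere.

## Metastatement semantics

A statement is one expression evaluated per record against the whole
ensemble. The grammar fixes: identifiers are `[A-Za-z_][A-Za-z0-9_]*`;
metadata with other characters in their names are referenced in quoted
form; `name(...)` is a function call only for the registered builtins and
otherwise slices (`glutadist(<=2.5)`) or key-indexes
(`atom_types(close_atom_nums)`) the metadata value; `name{}` extracts
dictionary keys. Comparator glyphs (≤, ≥, ≠) and their ASCII digraphs are
interchangeable, as is the Unicode minus sign. Precedence, loosest to
tightest: `|`, `&`, comparison, `+ -`, `* /`, unary minus, postfix.

Three rules that were open and are now fixed:

* **Quoted tokens resolve metadata-first.** `"name"` refers to the
  metadata `name` when the record carries it and is otherwise a string
  literal. The same rule applies to a bare name in slice-threshold
  position (`close_types(=O)`), where element symbols and SYBYL types are
  overwhelmingly literals.
* **Scope prefixes.** Unprefixed aggregates (`max`, `min`, `avg`, `sum`)
  reduce over the whole file; the `m`-prefixed forms reduce within the
  record's molecule group. Dictionary or list arguments are first reduced
  per record with the aggregate's own statistic, then across records.
  File scope as the unprefixed default is this package's documented
  choice, not asserted as anyone else's behavior.
* **Existence truthiness.** For filtering, ABSENT and empty collections
  are false and every present value — including 0 — is true. `&` requires
  both sides present, `|` either. This matches the hydroxyl-filter idiom,
  which tests for the *presence* of sliced atoms, not for numeric truth.

Arithmetic lifts elementwise: scalar against dictionary applies to every
value, dictionary against dictionary joins on common keys (inner join;
unmatched keys drop), lists combine elementwise and must agree in length.
Strings support `+` (concatenation) and `-` (removal of all matches of
the right operand as a regular expression); any other operation on a
string yields ABSENT with a warning rather than an error, so one bad
record cannot abort a whole-file statement. Division by zero likewise
yields ABSENT for that record. ABSENT propagates through every construct
except `|`.

Numeric equality in slicing is exact for integers and uses a relative
tolerance of 1e-9 for floats; ordering comparators require numeric
values, while `=` and `!=` also compare strings (needed for element and
SYBYL-type slices). Ranking (`mrank`) is 1-based ascending within the
group with ties broken by conformation number, so reruns are
deterministic; the best-30 % idiom `mrank(s) <= 0.3*mcount()` keeps
exactly 3 of 10 conformers because the cut is `<=` on the real-valued
bound.

## Interchange

CSV import matches rows to records purely by the (name, conformation)
key: a key with a `{[conf|N]}` tag attaches to that conformation only, a
plain key to every conformation of the name — so one file can carry
molecule-level and conformation-level columns side by side. Import is
order-independent and duplicate keys are an error. Export writes one row
per record with the tagged name as key and dictionaries flattened to
`key:value` cells, which is exactly the import syntax; export→import→
export is therefore byte-identical. Tab vs comma is auto-detected from
the header line (tab wins if present).

mol2 import reads only the TRIPOS MOLECULE and ATOM sections and matches
molecules *positionally*, because converters routinely mangle names;
molecule and atom counts are verified and any mismatch is an error naming
the first offending molecule. Column 6 of the ATOM lines (the SYBYL type)
becomes an atom-keyed dictionary. We read mol2, never write it.

Atom-wise geometry (`distances_to_point`, the `dist()` builtin,
`centroid`) honors an element ignore list that defaults to `{"H"}`; the
hydroxyl-proximity workflow must pass an empty list explicitly, mirroring
how hydrogens are opt-in in the source workflows. The hydroxyl test
itself is deliberately bond-blind: an O and an H each within the cutoff
count as a hydroxyl surrogate without checking that they are bonded,
reproducing the published approximation. The ensemble `centroid` is the
mean of per-record centroids (mean of means), the quantity used to
summarize top-ranked pose positions.

## Plotting

Plot functions return their data — points, OLS slope/intercept/R², bin
counts — so checks never parse images; drawing (base graphics, png at
300 dpi or pdf by filename extension) is optional. The trend line is
ordinary least squares via `stats::lm` with R² = 1 − SSres/SStot.
Histograms use equal-width bins spanning [min, max] with the right-most
edge inclusive, so the maximum lands in the last bin and counts always
sum to the contributing records; a degenerate zero-width range puts
everything in the first bin. Binning is implemented directly because
these edge conventions are part of the contract.

## The synthetic fixture

`generate_fixture()` emulates a Plants-style docking campaign at the
scale of the reference workflow: 99 molecules × 10 conformers by
default, names mangled as `<id>_entry_<5-digit>_conf_<2-digit>`, a
ranking CSV with `TOTAL_SCORE` plus filler columns, a name-correspondence
CSV, a per-molecule activity CSV and a positionally matching mol2.
Molecules are alkanol-like chains (3–6 carbons, one hydroxyl); scores are
positive with lower = better, drawn as a per-molecule base U(20, 70) plus
a per-conformer U(0, 15) spread; pIC50 is coupled to the best (minimum)
score as `10 − 0.08·best + N(0, 0.4)` and exported as nanomolar IC50. A
seeded 20 % of conformers is planted with the hydroxyl O–H pair inside
2.5 Å of the binding-site point (24.31, −3.29, 25.59); all other
conformers keep both atoms at least 1.5 Å outside the cutoff, a margin
that absorbs the 4-decimal coordinate rounding, and the assignment is
returned as a manifest for planted-truth assertions. Every oxygen is a
hydroxyl oxygen (SYBYL `O.3`) and the only hydrogen is the hydroxyl
hydrogen, which is what makes the element-based and SYBYL-type-based
filters provably equivalent on this fixture.

What the generator does *not* emulate: realistic conformer geometry,
docking energetics, protonation states, or chemically valid topologies.
Passing tests therefore demonstrate the data-logistics contracts —
parsing, typing, grouping, expression semantics, filter equivalences —
not anything about docking accuracy on real ligands.

Test problem sizes: the full-scale checks run at 99 × 10 (990 records);
property sweeps use many small seeded ensembles (2–5 molecules, 1–5
conformers) so that several thousand oracle comparisons complete in
seconds.

## Known limitations

* V3000 molfiles are not read; no chemistry perception of any kind
  (valence, aromaticity, bond-aware hydroxyl detection).
* The metastatement language has no `not` operator (the CLI offers
  `-invert`), no user-defined functions, and no nested containers
  (no lists inside dictionaries).
* PDB reference points are not supported; points of interest are literal
  coordinates.
* A metadata field named like a builtin (`max`, `dist`, ...) is shadowed
  in call position; reference it without parentheses or via the quoted
  form.
* The CLI applies handles in one fixed order; workflows needing another
  order chain invocations through intermediate files.
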