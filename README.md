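# confmeta

Conformer-ensemble and metadata management for SDF files in R.

Docking and virtual-screening projects scatter their data across formats:
3D poses in an SDfile, per-pose scores in a ranking CSV, per-compound
activities in another table, atom typing in a mol2 file. `confmeta`
packages V2000 molfiles and molecule-, conformation- and atom-level
metadata into one queryable ensemble, so that selecting, deriving and
plotting across all three levels becomes a one-liner. It is aimed at
computational chemists post-processing docking runs (pose filtering by
binding-site geometry, score normalization, activity correlation) and at
anyone who needs SDF data items that are more than flat strings.

## The data model

Each SDfile entry becomes a *conformation record*: a verbatim V2000
molfile plus a map of named metadata. Records sharing a *group key* (the
molecule name by default, or any metadata field) form a molecule group,
and each record gets a *conformation number* unique within its group, so
every structure is addressed by the pair (name, conformation). Metadata
values extend the SDF data-item notation with three structures × three
scalar types:

|            | int | float | string |
|------------|-----|-------|--------|
| single     | `42` | `174.05` | `active` |
| list       | `1 2 3` | `0.5 0.7` | `a b` |
| dictionary | `1:3 2:7` | `3:2.41 15:1.97` | `1:O.3 2:H` |

Dictionary keys are atom numbers when produced internally — e.g. atom-wise
distances to a binding-site point. Scalars are interpreted as integer,
then float, then string; a value-less field simply does not exist
("there is no metadata if there is no value").

## Metastatements

A *metastatement* is a single expression evaluated once per record against
the whole ensemble:

* `TOTAL_SCORE/mmax(TOTAL_SCORE)` — normalize each pose's score by its
  molecule group's maximum (`m`-prefixed aggregates reduce within the
  group, unprefixed over the whole file); every group then has at least
  one pose at exactly 1.0.
* `glutadist(<=2.5)` — slice a distance dictionary, keeping atoms within
  2.5 Å.
* `close_atoms{}` — extract the keys (atom numbers) of a dictionary.
* `atom_types(close_atom_nums)` — restrict a dictionary to a key set.
* `9-log10(IC50_nM)` — pIC50 from a nanomolar IC50.
* `plants_id-"_entry_\d+_conf_\d+"` — string subtraction is regular
  expression removal: mangled docking names collapse back to compound ids.
* `mrank(TOTAL_SCORE)<=0.3*mcount()` — the best 30 % of poses per
  molecule (lower score = better).

A record for which an expression has no value is simply absent from the
result; filters keep records where the statement has a value.

## Worked example

The package ships a deterministic generator of docking-style fixtures
(mangled Plants-like names, ranking/activity CSVs, a matching mol2 with
SYBYL types, and poses planted so that a known subset has a hydroxyl O–H
pair within 2.5 Å of the binding-site point):

```r
library(confmeta)
fx  <- generate_fixture(n_molecules = 10, n_confs = 5, seed = 42)
ens <- read_sdf(fx$sdf)
ens
#> sdf_ensemble: 50 records in 50 groups (grouped by name)

ens <- import_csv(ens, fx$ranking)               # per-pose TOTAL_SCORE
ens <- import_csv(ens, fx$corresponding_names)   # original compound ids
ens <- store_header_as_meta(ens, "plants_id")
ens <- rename_records(ens, "OLD_LIGAND_DESCRIPTION")
ens
#> sdf_ensemble: 50 records in 10 groups (grouped by name)

ens <- new_meta(ens, "norm_score", "TOTAL_SCORE/mmax(TOTAL_SCORE)")
r <- ens$records[[1]]
sprintf("%s conf %d: TOTAL_SCORE=%.4f norm=%.6f",
        r$molfile$name, r$conf_number,
        r$meta$TOTAL_SCORE$payload, r$meta$norm_score$payload)
#> "CHEMBLSYN1 conf 1: TOTAL_SCORE=77.4814 norm=0.952322"

# hydroxyl-proximity filter at the binding-site point
ens  <- add_distance_meta(ens, "glutadist", fx$point, ignore = character(0))
ens  <- new_meta(ens, "atom_types", "confcol(4)")
ens  <- new_meta(ens, "close_types", "atom_types(glutadist(<=2.5){})")
hits <- filter_records(ens, "close_types(=O) & close_types(=H)")
hits
#> sdf_ensemble: 12 records in 8 groups (grouped by name)
sum(fx$manifest$planted)
#> [1] 12
```

The 50 mangled names regroup into 10 molecules of 5 conformers after the
rename; normalization puts every group's best-scoring pose at 1.0; and the
geometric filter recovers exactly the 12 planted hydroxyl-proximal poses.

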