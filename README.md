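# raredx

Symptom-based differential diagnosis of rare diseases in R.

Rare diseases are individually uncommon enough that a clinician may never
have seen the one in front of them, yet collectively they affect a large
share of the population, and many share partially overlapping symptom
spectra. `raredx` implements a differential-diagnosis (DDX) engine for
this setting: given a disease–symptom knowledge base (one symptom-set per
disease, as curated resources such as ORPHANET provide) and a patient's
observed symptoms, it ranks every disease by a normalized set-difference
score, estimates when a score is statistically distinguishable from what
a random symptom set would achieve, and benchmarks the whole pipeline
under controlled symptom noise.

## The score

For a query symptom set of size `S_user` and disease *i* with `S_i`
symptoms in the knowledge base, let `n` be the size of the symmetric
difference between the two sets (symptoms in one but not the other).
The diagnostic score is

```
DS_i = 1 − n / max(S_user, S_i),        −1 ≤ DS_i ≤ 1
```

`DS_i = 1` exactly when the sets are identical and `−1` when they are
disjoint and equal-sized. Diseases are ranked by decreasing score; all
diseases tied at the maximal score form the *top-score set*, the unit
used for true/false-positive accounting in the benchmark. A score of at
least 0.5 is flagged statistically significant: under random queries
against a knowledge-base-scale store, the best score reaches 0.5 with
probability below 10⁻⁴ (estimated by Monte Carlo, reported with its
Clopper–Pearson upper bound). Equivalently, a disease with `S` symptoms
needs `ceiling(S/2)` matching submitted symptoms to reach significance.

Benchmarks perturb a baseline cohort (one patient per disease carrying
the full symptom set, which is recovered perfectly when disease sets are
distinct) with either a count of random symptom additions/deletions or
deletion of a fixed fraction of symptoms, then report precision
`p = ΣTP / (ΣTP + ΣFP)`, sensitivity `s = ΣTP / n_patients`, and
`F1 = 2ps / (p + s)`, where a patient is a true positive if its disease
is in the top-score set and the other tied diseases count as false
positives.

## Worked example

```r
library(raredx)

kb <- kb_from_sets(
  list(ORPHA231 = c("anemia", "fatigue", "splenomegaly", "jaundice"),
       ORPHA141 = c("macrocephaly", "hypotonia", "seizures"),
       ORPHA870 = c("hypotonia", "flat_facial_profile",
                    "upslanted_palpebral_fissures", "single_palmar_crease")),
  disease_names = c("Example hemoglobinopathy", "Example leukodystrophy",
                    "Example trisomy"))

rank_diseases(kb, c("hypotonia", "seizures"))
#> <raredx_diagnosis> query of 2 symptom(s); 3 diseases ranked
#> top-score set: ORPHA141 (ds = 0.6667)
#>  rank disease_id             disease_name         ds n max_size significant
#>     1   ORPHA141   Example leukodystrophy  0.6666667 1        3        TRUE
#>     2   ORPHA870          Example trisomy  0.0000000 4        4       FALSE
#>     3   ORPHA231 Example hemoglobinopathy -0.5000000 6        4       FALSE
```

The query shares 2 of the leukodystrophy's 3 symptoms, so `n = 1`
differing symptom over `max(2, 3) = 3` gives `DS = 1 − 1/3 ≈ 0.667` —
above the 0.5 significance cutoff. The trisomy shares one symptom
(`DS = 0`), the hemoglobinopathy none (`DS = −0.5`; not −1 because the
sets differ in size).

How many matching symptoms a disease needs before its score is
significant depends only on its set size:

```r
min_symptoms_for_significance(c(7, 48, 180))
#> [1]  4 24 90
```

Everything is scriptable from a shell through the bundled CLI
(`inst/exec/raredx`, a thin wrapper over `raredx_cli()`): `diagnose`,
`benchmark noise-mix|deletion`, `null`, and `synth kb|cohort`
subcommands, with seeds and knowledge-base checksums recorded in every
output so results can be reproduced byte-for-byte.

## Scope

The package deliberately stores unweighted disease–symptom associations
(no frequency classes), matches symptoms by exact id (names
case-insensitively in the CLI; no ontology expansion or fuzzy search),
and ships a synthetic knowledge-base generator rather than any
third-party data export. See the methods vignette
(`vignettes/raredx-methods.Rmd`) for the model, the generator's design,
and known limitations.
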