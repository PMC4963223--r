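---
title: "raredx: model, benchmarks and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raredx: model, benchmarks and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredx)
```

## The diagnostic model

`raredx` ranks candidate rare diseases for a patient by comparing the
patient's symptom set against each disease's curated symptom set with a
normalized Hamming-like distance. For a query of size $S_u$ and disease
$i$ with $S_i$ symptoms, with $n$ the size of the symmetric difference
between the two sets,

$$DS_i = 1 - \frac{n}{\max(S_u, S_i)}, \qquad -1 \le DS_i \le 1 .$$

The score is $1$ iff the sets are equal, $-1$ iff they are disjoint and
equal-sized, symmetric in its two arguments, and — for a query that is a
subset of a disease's set — strictly increasing in the number of
matching symptoms ($DS = k/S$ for $k$ of $S$ matching symptoms).
The model's assumptions are deliberately minimal: associations are
unweighted (no symptom-frequency classes), symptoms match by exact
identifier (no ontology-aware expansion of related phenotype terms), and
duplicate submissions collapse because both sides are sets. These
assumptions keep the score transparent and cheap — a full ranking over
thousands of diseases takes milliseconds via an inverted symptom index —
at the cost of treating all symptoms as equally informative.

Diseases are ranked by decreasing score. Set-similarity scores tie
often (any two diseases of equal size sharing the same overlap with the
query tie exactly), so the *top-score set* — every disease attaining the
maximal score — is carried through the API and is the unit the benchmark
counts on. Within the printed ranking, ties are broken by ascending
disease id purely for determinism.

A subtlety worth recording: every scoring path in the package computes
the score with the identical floating-point expression `1 - n/max`.
Because IEEE division is correctly rounded, two scores that are equal as
rationals (e.g. $2/4$ and $3/6$) are then bit-identical doubles, so tie
sets are detected by exact comparison with no tolerance anywhere.

## Significance of a score

A reported score should mean more than "best of a large database", so
the package calibrates it against a null model: queries of $m$ symptoms
drawn uniformly without replacement from the vocabulary (the minimal
model for an uninformative user). `null_distribution()` records, per
Monte Carlo trial, the *maximum* score over all diseases — the null
statistic relevant to the top prediction — and `score_pvalue()` turns it
into the raw exceedance fraction plus a one-sided 95% Clopper–Pearson
upper bound, so that claims like "below $10^{-4}$" remain honest at
finite trial counts (with zero exceedances in $10^5$ trials the bound is
$\approx 3\times10^{-5}$).

On knowledge bases at the default synthetic scale, a best score of 0.5
is effectively unreachable by random queries (the acceptance script
measures the empirical probability at $10^5$ trials), which motivates
the package-wide significance flag `ds >= 0.5`. The threshold is
inclusive, which makes it equivalent to "at least $\lceil S/2 \rceil$
matching symptoms" for a disease of size $S$
(`min_symptoms_for_significance()`); the published worked examples that
this function reproduces count the boundary case $24/48 = 0.5$ as
significant, which forces the inclusive reading.

One of the ten published example rows prints a 1-symptom score of 0.042
for a 25-symptom disease; the arithmetic value is $1/25 = 0.040$, and
every other cell of that table matches $k/S$ exactly. The package
implements the arithmetic and documents the cell as a typo rather than
fitting to it.

`min_significant_difference()` addresses the companion question — how
far apart must two scores be before the gap is meaningful — as the
$(1-\alpha)$ quantile of the null distribution of the gap between the
top two *distinct* scores of a random query. The exact construction
behind the originally reported gap values is not public, so the
procedure sits behind a single swappable operation; the quantile is
type 1 (inverse ECDF), i.e. an actually realized gap, because the gap
null is discrete.

## Benchmark design

The benchmark anchors on a cohort with one patient per disease whose
observed set is the disease's full symptom set. If all disease sets are
pairwise distinct — an invariant the knowledge-base validator checks and
the generator enforces — this cohort is recovered perfectly, so
precision, sensitivity and F1 are exactly 1 at zero noise; any
degradation is attributable to the injected noise. Two operators
perturb patients:

* **add/delete count** — $k$ sequential edits; each is a coin flip
  (default $p = 0.5$, configurable) between adding one symptom drawn
  uniformly from outside the current observed set and deleting one drawn
  uniformly from inside it. A deletion that would empty the set becomes
  an addition (queries must be non-empty); an addition with the
  vocabulary exhausted is skipped with a warning. Sequential edits mean
  a later deletion can cancel an earlier addition, which mirrors noisy
  record-taking rather than a fixed error count.
* **fraction deletion** — removes $\lfloor f \cdot |O| \rfloor$ observed
  symptoms uniformly, always retaining at least one.

`run_noise_grid()` crosses noise levels with the fraction of patients
perturbed (default 0–100% in steps of 10, with
$\mathrm{round}(pf \cdot N)$ patients chosen uniformly per cell), runs a
configurable number of replicates per cell, and emits one metrics row
per replicate. The whole grid runs inside one seeded RNG stream in
fixed order, so a seed reproduces the output table byte-for-byte.

Metrics follow the top-score-set convention: a patient whose true
disease is in the top-score set $T$ contributes one true positive and
$|T| - 1$ false positives; otherwise zero true positives and $|T|$
false positives. Then $p = \Sigma TP / (\Sigma TP + \Sigma FP)$,
$s = \Sigma TP / N$, $F1 = 2ps/(p+s)$. This is the only reading under
which noise erodes precision (through growing tie sets and overtaken
patients) while sensitivity stays comparatively high, and it implies
$p \le s$ identically, a property the tests assert. Top-10/50 rates use
the deterministic tie-broken ranking.

Under the default generator conditions the acceptance script measures
the expected shape: deletion-only noise is almost harmless (the true
disease scores $k/S > 0$ on its $k$ surviving symptoms, and even with
75% of symptoms deleted in every patient the top-score-set inclusion
stays at ~100%), while heavy mixed noise bites: at 20 edits in all
patients, per-cell sensitivity bottoms out near 0.89 and precision
declines steadily as more patients are perturbed. We record explicitly
that the engine's sensitivity under the harshest cell is *not* ≥ 0.99
on these synthetic conditions; claims of near-perfect sensitivity hold
on the mild-to-moderate part of the grid (up to ~5 edits, sensitivity
stays above 0.999).

## The synthetic knowledge-base generator

Real disease–phenotype exports cannot be redistributed here, so all
experiments run on seeded synthetic knowledge bases whose *structure*
emulates the curated resources: `synthetic_kb_spec()` defaults to 2000
diseases over a 3000-symptom vocabulary. Two distributional choices
matter:

* **Set sizes** follow a log-normal truncated to $[5, 180]$ (continuous
  inverse-CDF truncation, then rounding, so bounds are respected
  exactly). The log-scale parameters (3.5, 0.9) are a moment fit to the
  ten published example disease sizes (7–180 symptoms, median ≈ 25),
  giving the right-skewed spread such resources show. The tests verify
  the generated median and mean against the integer PMF computed
  directly from `plnorm`.
* **Symptom sharing**: a popularity weight vector is drawn once per
  knowledge base from a symmetric Dirichlet with parameter
  $1/c$, where $c$ is `sharing_concentration` ($c = 0$ means uniform);
  each disease then samples its symptoms without replacement under
  those weights. Larger $c$ concentrates probability on fewer symptoms
  and measurably increases mean pairwise set overlap (a monotonicity
  the tests check across $c \in \{0, 2, 8\}$). The default $c = 1$ is a
  moderate-reuse setting chosen once; it produces the overlapping
  symptom spectra that make ties and near-miss diseases — the hard part
  of differential diagnosis — actually occur.

Pairwise-distinct symptom sets are enforced by resampling colliding
diseases (bounded retries, then an error naming the colliding sizes).
What the generator does **not** emulate: symptom-frequency annotations,
correlated symptom co-occurrence beyond global popularity, hierarchical
phenotype structure, and any fitted correspondence to a real export's
statistics. Benchmarks on synthetic data therefore demonstrate the
engine's *mechanics* (exact no-noise recovery, noise response shape,
null calibration) and not clinical performance on real patients.

## Numerical and interface choices

* Scores never need tolerances (see above); sorting uses
  `order(-ds, disease_id)`.
* `round(pf * N)` patients perturbed per cell; `floor(f * |O|)` symptoms
  deleted per patient; both stated so runs are bit-reproducible.
* All Monte Carlo drivers take a `seed` and restore the caller's RNG
  state; lower-level noise operators consume the current stream so they
  can compose inside a seeded driver.
* TSV outputs are written in binary mode with LF endings and 15
  significant digits, with `# key=value` metadata headers (seed,
  knowledge-base MD5 checksum, grid), so identical seeds give
  byte-identical artifacts.
* The canonical interchange format is the long-format association TSV
  (header `disease_id/disease_name/symptom_id/symptom_name`); a nested
  JSON dialect is provided for convenience. Loading is order-insensitive
  and deduplicates repeated associations with a warning (set semantics);
  malformed rows are reported with their line numbers.
* Queries with symptoms absent from the vocabulary are rejected at query
  time, naming the offending ids; the CLI additionally resolves exact
  case-insensitive names. There is deliberately no fuzzy matching.
* CLI exit codes distinguish usage errors (2) from data errors (1).

## Problem sizes used by the shipped checks

The test-suite and acceptance script run at sizes chosen to exercise the
study conditions while staying desk-scale: the default 2000×3000
knowledge base for the end-to-end checks; $10^5$ trials for the null;
10 replicates per noise-grid cell (30 for the strict monotonicity check
of precision at 20 edits, where per-cell standard errors must sit well
below the few-percent step sizes); and exhaustive brute-force sweeps
(all subsets of up to 6 symptoms against up to 5 diseases) as the
oracle for ranking and metrics.

## Known limitations

* All symptoms are equally informative; a highly specific phenotype and
  a ubiquitous one count the same.
* No partial credit for ontologically related symptoms.
* The significance threshold is calibrated against uniform random
  queries; a clinician's plausible-but-wrong query is not uniform.
* Duplicate disease symptom sets make perfect recovery impossible by
  construction; the validator reports them and the benchmark refuses to
  anchor on such a store.
* Synthetic benchmarks bound what can be claimed: results transfer to a
  real knowledge base only insofar as its size and sharing structure
  resemble the generator's.
```{r}
sessionInfo()
```
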