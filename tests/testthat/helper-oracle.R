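# Brute-force oracles, independent of the package's inverted-index
# scoring path: plain set operations on character vectors.

oracle_ds <- function(q, d) {
  q <- unique(q); d <- unique(d)
  n <- length(setdiff(q, d)) + length(setdiff(d, q))
  1 - n / max(length(q), length(d))
}

# Score every disease of a named list of symptom sets for query q.
oracle_scores <- function(sets, q) {
  vapply(sets, function(d) oracle_ds(q, d), numeric(1))
}

# Full ranking by decreasing score, ties by ascending disease id.
oracle_ranking <- function(sets, q) {
  ds <- oracle_scores(sets, q)
  ids <- names(sets)
  ord <- order(-ds, ids)
  list(ids = ids[ord], ds = ds[ord],
       top_set = sort(ids[ds == max(ds)]))
}

# Cohort metrics per the benchmark's tie semantics: a patient's
# prediction is the top-score set T; TP if the true disease is in T,
# FP = |T| - TP.
oracle_metrics <- function(sets, true_ids, observed) {
  tp <- 0; n_pred <- 0
  for (i in seq_along(true_ids)) {
    ds <- oracle_scores(sets, observed[[i]])
    top <- names(sets)[ds == max(ds)]
    tp <- tp + (true_ids[i] %in% top)
    n_pred <- n_pred + length(top)
  }
  p <- tp / n_pred
  s <- tp / length(true_ids)
  list(precision = p, sensitivity = s,
       f1 = if (p + s > 0) 2 * p * s / (p + s) else 0)
}

# Random small KB as a named list of distinct non-empty symptom sets.
random_small_sets <- function(n_diseases, vocab) {
  syms <- letters[seq_len(vocab)]
  repeat {
    sets <- lapply(seq_len(n_diseases), function(i) {
      sort(sample(syms, sample.int(vocab, 1L)))
    })
    keys <- vapply(sets, paste, "", collapse = ",")
    if (!anyDuplicated(keys)) break
  }
  names(sets) <- sprintf("D%02d", seq_len(n_diseases))
  sets
}

# All non-empty subsets of a symptom-id vector (for exhaustive sweeps).
all_queries <- function(syms) {
  unlist(lapply(seq_along(syms), function(k) {
    combn(syms, k, simplify = FALSE)
  }), recursive = FALSE)
}

# Build a raredx_cohort without going through generate_cohort().
manual_cohort <- function(true_ids, observed) {
  structure(
    list(patients = data.frame(
           patient_id = sprintf("P%02d", seq_along(true_ids)),
           true_disease_id = true_ids,
           stringsAsFactors = FALSE),
         observed = observed),
    class = "raredx_cohort"
  )
}

# Canonical association table; two KBs are equal iff these are identical.
kb_assoc <- function(kb) raredx:::kb_associations(kb)

# The ten worked examples published for the scoring function: disease
# size S, the printed score for 1 matching symptom, the minimal symptom
# count k at which the disease reaches rank 1 with its printed score,
# and the printed count of symptoms needed for a significant score.
# The 25-symptom row's 1-symptom score is printed as 0.042 in the source
# table although 1/25 = 0.040; that single cell is a known typo and is
# asserted at the arithmetic value, not the printed one.
table1_rows <- function() {
  data.frame(
    disease = c("Beta-Thalassemia", "Canavan disease", "Down syndrome",
                "Fabry disease", "Goldblatt syndrome", "Turner syndrome",
                "Uncombable hair syndrome", "Williams syndrome",
                "Yunis-Varon syndrome", "Zellweger-like syndrome"),
    size = c(23L, 19L, 48L, 66L, 23L, 26L, 7L, 180L, 66L, 25L),
    score1 = c(0.043, 0.053, 0.021, 0.015, 0.043, 0.038, 0.14, 0.006,
               0.015, 0.040),
    score1_digits = c(3L, 3L, 3L, 3L, 3L, 3L, 2L, 3L, 3L, 3L),
    k_min = c(3L, 5L, 4L, 8L, 3L, 2L, 1L, 5L, 9L, 3L),
    score_min = c(0.13, 0.26, 0.083, 0.12, 0.13, 0.077, 0.14, 0.028,
                  0.14, 0.12),
    score_min_digits = c(2L, 2L, 3L, 2L, 2L, 3L, 2L, 3L, 2L, 2L),
    k_signif = c(12L, 10L, 24L, 33L, 12L, 13L, 4L, 90L, 33L, 13L),
    stringsAsFactors = FALSE
  )
}

# Seed-then-run shorthand for testing determinism of RNG-consuming calls.
with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}

# Read a metadata-commented TSV produced by the CLI.
read_tsv_skip_meta <- function(path) raredx:::read_tsv_stable(path)
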