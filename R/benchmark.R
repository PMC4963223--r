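#' Synthetic patient cohorts and noise benchmarks
#'
#' The engine is stress-tested with cohorts of synthetic patients, each
#' carrying a known true disease and an observed symptom set. The
#' baseline cohort contains one patient per disease whose observed set is
#' the disease's full symptom set; with pairwise-distinct disease sets
#' this cohort is recovered perfectly (precision = sensitivity = F1 = 1),
#' which anchors the benchmark. Noise operators then perturb observed
#' sets — mixed additions/deletions of a fixed count, or deletion of a
#' fixed fraction — and the metrics quantify the degradation.
#'
#' @name raredx_benchmark
#' @keywords internal
NULL

new_cohort <- function(patient_id, true_disease_id, observed) {
  structure(
    list(patients = data.frame(patient_id = patient_id,
                               true_disease_id = true_disease_id,
                               stringsAsFactors = FALSE),
         observed = observed),
    class = "raredx_cohort"
  )
}

#' @export
print.raredx_cohort <- function(x, ...) {
  cat("<raredx_cohort>", nrow(x$patients), "patients,",
      length(unique(x$patients$true_disease_id)), "distinct true diseases\n")
  cat("  observed symptoms per patient: min", min(lengths(x$observed)),
      "median", stats::median(lengths(x$observed)),
      "max", max(lengths(x$observed)), "\n")
  invisible(x)
}

#' Baseline cohort: one noiseless patient per disease
#'
#' Builds the benchmark's reference cohort: for every disease in the
#' knowledge base, one patient whose observed symptoms are exactly that
#' disease's symptom set. Requires pairwise-distinct disease symptom
#' sets, otherwise perfect no-noise recovery is impossible and the
#' benchmark's anchor (F1 = 1 without noise) does not hold.
#'
#' @param kb A `raredx_kb` whose diseases have pairwise-distinct,
#'   non-empty symptom sets.
#' @return A `raredx_cohort`.
#' @export
make_baseline_cohort <- function(kb) {
  generate_cohort(kb, patients_per_disease = 1L)
}

#' Add/delete symptom noise
#'
#' Applies `k` random edits to a patient's observed symptom set,
#' emulating records that mix unrelated findings with missed true ones.
#' Each edit is, with probability `add_prob`, the addition of one symptom
#' drawn uniformly from the vocabulary outside the current observed set,
#' and otherwise the deletion of one symptom drawn uniformly from the
#' current observed set. A deletion that would empty the set is converted
#' to an addition (queries must be non-empty); an addition with the
#' vocabulary exhausted is skipped with a warning. Edits are sequential,
#' so a later deletion can remove an earlier addition. Uses the current
#' RNG stream. The patient's true disease is unchanged.
#'
#' @param patient A list with `true_disease_id` and `observed` (character
#'   symptom ids), e.g. one row's worth of a `raredx_cohort`.
#' @param kb The `raredx_kb` supplying the vocabulary.
#' @param k Number of edits (0 leaves the patient unchanged).
#' @param add_prob Probability that an edit is an addition (default 0.5).
#' @return The perturbed patient (same shape as `patient`).
#' @export
apply_add_delete_noise <- function(patient, kb, k, add_prob = 0.5) {
  stopifnot(inherits(kb, "raredx_kb"), k >= 0, add_prob >= 0, add_prob <= 1)
  obs <- match(unique(patient$observed), kb$symptoms$symptom_id)
  if (anyNA(obs)) abort_data("patient has symptoms absent from the knowledge base")
  obs <- perturb_add_delete(obs, nrow(kb$symptoms), as.integer(k), add_prob)
  patient$observed <- kb$symptoms$symptom_id[sort.int(obs)]
  patient
}

# Index-space core of the add/delete noise operator.
perturb_add_delete <- function(obs, vocab_n, k, add_prob) {
  for (e in seq_len(k)) {
    add <- stats::runif(1) < add_prob
    if (!add && length(obs) == 1L) add <- TRUE  # deletion would empty the set
    if (add) {
      if (length(obs) >= vocab_n) {
        warning("vocabulary exhausted; addition edit skipped", call. = FALSE)
        next
      }
      repeat {
        s <- sample.int(vocab_n, 1L)
        if (!(s %in% obs)) break
      }
      obs <- c(obs, s)
    } else {
      obs <- obs[-sample.int(length(obs), 1L)]
    }
  }
  obs
}

#' Fractional symptom deletion
#'
#' Removes `floor(fraction * |observed|)` symptoms uniformly at random
#' from a patient's observed set, retaining at least one symptom,
#' emulating under-reported records. Uses the current RNG stream.
#'
#' @inheritParams apply_add_delete_noise
#' @param fraction Proportion of symptoms to delete, in (0, 1).
#' @return The perturbed patient.
#' @export
apply_fraction_deletion <- function(patient, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  obs <- unique(patient$observed)
  keep <- perturb_delete_fraction(seq_along(obs), fraction)
  patient$observed <- sort(obs[keep])
  patient
}

# Index-space core of fractional deletion; returns the retained elements.
perturb_delete_fraction <- function(obs, fraction) {
  n_del <- min(floor(fraction * length(obs)), length(obs) - 1L)
  if (n_del > 0L) obs <- obs[-sample.int(length(obs), n_del)]
  obs
}

#' Evaluate a cohort's differential diagnoses
#'
#' Scores every patient's observed symptoms against the knowledge base
#' and aggregates diagnostic performance. A patient's prediction is the
#' top-score set `T` (all diseases tied at the maximal score): the
#' patient contributes one true positive if the true disease is in `T`,
#' and `|T| - 1(true in T)` false positives — the extra diseases tied at
#' the top. Precision is total true positives over total predictions,
#' sensitivity is total true positives over the number of patients, and
#' F1 is their harmonic mean. Top-10/top-50 rates use the deterministic
#' ranking (score descending, disease id ascending within ties).
#'
#' @param cohort A `raredx_cohort`.
#' @param kb A `raredx_kb`; every observed symptom must be in its
#'   vocabulary.
#' @param threshold Significance cutoff recorded with the diagnosis
#'   (does not affect the metrics).
#' @return One-row data frame with columns `n_patients`, `precision`,
#'   `sensitivity`, `f1`, `top1_rate`, `top10_rate`, `top50_rate`.
#' @examples
#' kb <- kb_from_sets(list(D1 = c("a", "b"), D2 = c("b", "c"), D3 = "d"))
#' cohort <- make_baseline_cohort(kb)
#' evaluate_cohort(cohort, kb)  # perfect recovery without noise
#' @export
evaluate_cohort <- function(cohort, kb, threshold = 0.5) {
  stopifnot(inherits(cohort, "raredx_cohort"), inherits(kb, "raredx_kb"))
  np <- length(cohort$observed)
  if (np == 0L) abort_data("cohort is empty")
  lens <- lengths(cohort$observed)
  if (any(lens == 0L)) abort_data("patient with empty observed symptom set")
  all_syms <- unlist(cohort$observed, use.names = FALSE)
  sym_idx <- match(all_syms, kb$symptoms$symptom_id)
  if (anyNA(sym_idx)) {
    abort_data("patient symptom id(s) absent from the knowledge base: ",
               paste(unique(all_syms[is.na(sym_idx)]), collapse = ", "))
  }
  obs_idx <- split(sym_idx, rep.int(seq_len(np), lens))
  true_idx <- match(cohort$patients$true_disease_id, kb$diseases$disease_id)
  if (anyNA(true_idx)) abort_data("cohort references unknown disease ids")
  evaluate_idx(kb, obs_idx, true_idx)
}

# Index-space evaluation core shared by evaluate_cohort and the grid
# driver. obs_idx: list of symptom-index vectors; true_idx: disease index
# per patient.
evaluate_idx <- function(kb, obs_idx, true_idx) {
  np <- length(obs_idx)
  tp <- 0L; n_pred <- 0L; top1 <- 0L; top10 <- 0L; top50 <- 0L
  for (i in seq_len(np)) {
    sc <- score_query_idx(kb, obs_idx[[i]])
    ds <- sc$ds
    ti <- true_idx[i]
    dmax <- max(ds)
    tie <- ds == dmax
    hit <- tie[ti]
    tp <- tp + hit
    n_pred <- n_pred + sum(tie)
    top1 <- top1 + hit
    # deterministic tie-broken rank of the true disease (ids are sorted,
    # so index order is id order)
    r <- sum(ds > ds[ti]) + sum(ds == ds[ti] & seq_along(ds) < ti) + 1L
    top10 <- top10 + (r <= 10L)
    top50 <- top50 + (r <= 50L)
  }
  p <- tp / n_pred
  s <- tp / np
  data.frame(
    n_patients = np,
    precision = p,
    sensitivity = s,
    f1 = if (p + s > 0) 2 * p * s / (p + s) else 0,
    top1_rate = top1 / np,
    top10_rate = top10 / np,
    top50_rate = top50 / np
  )
}

#' Noise-experiment grids
#'
#' Builds the grid of noise conditions for [run_noise_grid()]. Mode
#' `"add_delete_count"` perturbs patients with a fixed count of mixed
#' random symptom additions/deletions (levels are edit counts); mode
#' `"delete_fraction"` deletes a fixed fraction of each perturbed
#' patient's symptoms (levels are proportions). Each noise level is
#' crossed with a grid of patient fractions — the proportion of cohort
#' patients perturbed.
#'
#' @param mode `"add_delete_count"` or `"delete_fraction"`.
#' @param levels Noise levels: edit counts (default `c(1, 2, 3, 4, 5,
#'   10, 20)`) or deletion fractions (default `c(0.25, 0.5, 0.75)`)
#'   depending on `mode`.
#' @param patient_fraction Proportions of patients perturbed (default 0
#'   to 1 in steps of 0.1).
#' @return Data frame with columns `mode`, `level`, `patient_fraction`.
#' @export
noise_grid <- function(mode = c("add_delete_count", "delete_fraction"),
                       levels = NULL,
                       patient_fraction = seq(0, 1, by = 0.1)) {
  mode <- match.arg(mode)
  if (is.null(levels)) {
    levels <- if (mode == "add_delete_count") c(1, 2, 3, 4, 5, 10, 20)
              else c(0.25, 0.5, 0.75)
  }
  if (mode == "add_delete_count" && any(levels < 1)) {
    abort_data("edit counts must be at least 1")
  }
  if (mode == "delete_fraction" && any(levels <= 0 | levels >= 1)) {
    abort_data("deletion fractions must lie strictly between 0 and 1")
  }
  if (any(patient_fraction < 0 | patient_fraction > 1)) {
    abort_data("patient fractions must lie in [0, 1]")
  }
  expand.grid(mode = mode, level = levels,
              patient_fraction = patient_fraction,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
    , c("mode", "level", "patient_fraction")]
}

#' Run a noise benchmark grid
#'
#' For every grid cell and replicate: a fresh baseline cohort (one
#' noiseless patient per disease) is built, `round(patient_fraction * N)`
#' patients are chosen uniformly and perturbed with the cell's noise
#' operator, and the cohort is evaluated with [evaluate_cohort()]'s
#' metrics. Fully reproducible from `seed`: the whole grid runs under one
#' seeded RNG stream in fixed row-major order.
#'
#' @param kb A `raredx_kb` with pairwise-distinct disease symptom sets.
#' @param grid Data frame from [noise_grid()] (columns `mode`, `level`,
#'   `patient_fraction`).
#' @param replicates Monte Carlo replicates per cell (default 10).
#' @param seed RNG seed (default 1); recorded in the output.
#' @param add_prob Probability that an add/delete edit is an addition.
#' @return Data frame with one row per (cell, replicate): `experiment`,
#'   `mode`, `k_or_fraction`, `patient_fraction`, `replicate`, `seed`,
#'   `n_patients`, `precision`, `sensitivity`, `f1`, `top1_rate`,
#'   `top10_rate`, `top50_rate`.
#' @export
run_noise_grid <- function(kb, grid, replicates = 10L, seed = 1L,
                           add_prob = 0.5) {
  stopifnot(inherits(kb, "raredx_kb"), replicates >= 1L)
  if (!all(c("mode", "level", "patient_fraction") %in% names(grid)) ||
      nrow(grid) == 0L) {
    abort_data("grid must be a non-empty data frame from noise_grid()")
  }
  rep_dup <- validate_kb(kb)
  if (nrow(rep_dup$duplicate_set_pairs) || length(rep_dup$empty_diseases)) {
    abort_data("knowledge base must have distinct, non-empty disease symptom sets")
  }
  base_obs <- kb$disease_symptoms          # baseline observed sets (indices)
  nd <- length(base_obs)
  true_idx <- seq_len(nd)
  vocab_n <- nrow(kb$symptoms)
  out <- vector("list", nrow(grid) * replicates)
  row <- 0L
  with_seed(seed, {
    for (g in seq_len(nrow(grid))) {
      mode <- grid$mode[g]
      level <- grid$level[g]
      pf <- grid$patient_fraction[g]
      n_pert <- as.integer(round(pf * nd))
      for (r in seq_len(replicates)) {
        obs <- base_obs
        if (n_pert > 0L) {
          who <- sample.int(nd, n_pert)
          for (i in who) {
            obs[[i]] <- if (mode == "add_delete_count") {
              perturb_add_delete(obs[[i]], vocab_n, as.integer(level), add_prob)
            } else {
              perturb_delete_fraction(obs[[i]], level)
            }
          }
        }
        metrics <- evaluate_idx(kb, obs, true_idx)
        row <- row + 1L
        out[[row]] <- cbind(
          data.frame(
            experiment = if (mode == "add_delete_count") "noise_mix" else "deletion",
            mode = mode, k_or_fraction = level, patient_fraction = pf,
            replicate = r, seed = seed, stringsAsFactors = FALSE),
          metrics)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a cohort of noiseless patients
#'
#' Generates `patients_per_disease` identical noiseless patients per
#' disease (observed set = the disease's full symptom set), ready for the
#' noise operators. With one patient per disease this is the baseline
#' cohort of [make_baseline_cohort()].
#'
#' @param kb A `raredx_kb` with pairwise-distinct, non-empty disease
#'   symptom sets.
#' @param patients_per_disease Number of patients per disease (default 1).
#' @return A `raredx_cohort`.
#' @export
generate_cohort <- function(kb, patients_per_disease = 1L) {
  stopifnot(inherits(kb, "raredx_kb"))
  if (patients_per_disease < 1L) {
    abort_data("patients_per_disease must be at least 1")
  }
  rep <- validate_kb(kb)
  if (nrow(rep$duplicate_set_pairs)) {
    abort_data("duplicate disease symptom sets: ",
               nrow(rep$duplicate_set_pairs),
               " pair(s); perfect no-noise recovery is not possible")
  }
  if (length(rep$empty_diseases)) {
    abort_data("disease(s) with empty symptom sets: ",
               paste(rep$empty_diseases, collapse = ", "))
  }
  nd <- nrow(kb$diseases)
  k <- as.integer(patients_per_disease)
  disease_rep <- rep(seq_len(nd), each = k)
  observed <- lapply(disease_rep, function(i) {
    kb$symptoms$symptom_id[kb$disease_symptoms[[i]]]
  })
  new_cohort(
    patient_id = sprintf("P%0*d", nchar(nd * k) + 1L, seq_along(disease_rep)),
    true_disease_id = kb$diseases$disease_id[disease_rep],
    observed = observed
  )
}

#' Write a patient cohort as TSV
#'
#' One row per observed symptom: `patient_id`, `true_disease_id`,
#' `symptom_id`, sorted, byte-stable across runs.
#'
#' @param cohort A `raredx_cohort`.
#' @param path Output path.
#' @param meta Optional character vector of metadata lines written as
#'   `# `-prefixed header comments.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, meta = character()) {
  stopifnot(inherits(cohort, "raredx_cohort"))
  lens <- lengths(cohort$observed)
  df <- data.frame(
    patient_id = rep(cohort$patients$patient_id, lens),
    true_disease_id = rep(cohort$patients$true_disease_id, lens),
    symptom_id = unlist(lapply(cohort$observed, sort), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$patient_id, df$symptom_id), , drop = FALSE]
  write_tsv_stable(df, path, meta)
  invisible(path)
}
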