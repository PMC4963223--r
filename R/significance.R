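#' Draw a random symptom query
#'
#' Samples `m` distinct symptom ids uniformly without replacement from the
#' knowledge-base vocabulary — the null model against which observed
#' diagnostic scores are calibrated. Uses the current RNG stream; seed the
#' session (or use the `seed` arguments of the higher-level Monte Carlo
#' drivers) for reproducibility.
#'
#' @param kb A `raredx_kb`.
#' @param m Query size, between 1 and the vocabulary size.
#' @return Character vector of `m` symptom ids.
#' @export
sample_random_query <- function(kb, m) {
  stopifnot(inherits(kb, "raredx_kb"))
  ns <- nrow(kb$symptoms)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > ns) {
    abort_data("query size m must be between 1 and the vocabulary size (", ns, ")")
  }
  kb$symptoms$symptom_id[sample.int(ns, m)]
}

#' Empirical null distribution of the best diagnostic score
#'
#' Monte Carlo estimate of how well a *random* symptom set scores: for
#' each trial a query of `m` symptoms is drawn uniformly without
#' replacement from the vocabulary, scored against every disease, and the
#' maximum score recorded. The best score over diseases is the relevant
#' null statistic because the user-facing claim concerns the top
#' prediction. The resulting sample calibrates significance thresholds
#' via [score_pvalue()].
#'
#' @param kb A `raredx_kb`.
#' @param m Query size.
#' @param n_trials Number of Monte Carlo trials (at least 1).
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return A `raredx_null`: list with `query_size`, `n_trials`,
#'   `best_scores` (numeric vector in \eqn{[-1, 1]}) and `seed`.
#' @export
null_distribution <- function(kb, m, n_trials, seed = NULL) {
  stopifnot(inherits(kb, "raredx_kb"))
  if (!is.numeric(n_trials) || n_trials < 1L) {
    abort_data("n_trials must be at least 1")
  }
  n_trials <- as.integer(n_trials)
  ns <- nrow(kb$symptoms)
  if (m < 1L || m > ns) {
    abort_data("query size m must be between 1 and the vocabulary size (", ns, ")")
  }
  sizes <- kb$sizes
  maxs <- pmax(sizes, m)
  # score of a zero-overlap disease (overlap only raises it); written as
  # 1 - n/max, the same arithmetic as score_breakdown, for exact ties
  ds0 <- 1 - (sizes + m) / maxs
  best0 <- max(ds0)
  inv <- kb$symptom_diseases
  nd <- length(sizes)
  best <- numeric(n_trials)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      q <- sample.int(ns, m)
      ov <- tabulate(unlist(inv[q], use.names = FALSE), nbins = nd)
      cand <- ov > 0L
      best[t] <- if (any(cand)) {
        max(best0,
            max(1 - (sizes[cand] + m - 2L * ov[cand]) / maxs[cand]))
      } else {
        best0
      }
    }
  })
  structure(list(query_size = as.integer(m), n_trials = n_trials,
                 best_scores = best, seed = seed),
            class = "raredx_null")
}

#' @export
print.raredx_null <- function(x, ...) {
  q <- stats::quantile(x$best_scores, c(0.5, 0.95, 0.99, 0.999), names = FALSE)
  cat("<raredx_null> best score over diseases,", x$n_trials,
      "random queries of size", x$query_size, "\n")
  cat(sprintf("  q50 %.4g  q95 %.4g  q99 %.4g  q99.9 %.4g\n",
              q[1], q[2], q[3], q[4]))
  invisible(x)
}

#' Empirical p-value of a diagnostic score
#'
#' Fraction of null trials whose best score is at or above `score` — the
#' probability that a random symptom set attains such a score. The raw
#' fraction is reported without smoothing; alongside it, the one-sided
#' 95% Clopper-Pearson upper confidence bound, so that claims of the form
#' "p < 1e-4" are honest at finite trial counts (with zero exceedances in
#' `n` trials the bound is about `3/n`).
#'
#' @param null A `raredx_null` from [null_distribution()].
#' @param score Score threshold being tested.
#' @return A list with `threshold`, `empirical_p`, `cp_upper95`
#'   (Clopper-Pearson one-sided 95% upper bound), `n_exceed` and
#'   `n_trials`.
#' @export
score_pvalue <- function(null, score) {
  stopifnot(inherits(null, "raredx_null"))
  n <- null$n_trials
  x <- sum(null$best_scores >= score)
  upper <- if (x >= n) 1 else stats::qbeta(0.95, x + 1, n - x)
  list(threshold = score, empirical_p = x / n, cp_upper95 = upper,
       n_exceed = x, n_trials = n)
}

#' Minimum significant difference between two scores
#'
#' Monte Carlo estimate of how far apart the two best (distinct) scores of
#' a *random* query of size `m` typically are: per trial, all diseases are
#' scored, and the gap between the maximal score and the next distinct
#' score below it is recorded (0 if all scores coincide). The returned
#' value is the `1 - alpha` quantile of those gaps: an observed gap larger
#' than it would arise from a random query with probability below `alpha`,
#' so score differences exceeding it separate two candidate diseases
#' significantly.
#'
#' @inheritParams null_distribution
#' @param alpha Significance level for the gap (default 0.001).
#' @return The `1 - alpha` empirical quantile of the top-two-gap null, a
#'   value in \eqn{[0, 2]}.
#' @export
min_significant_difference <- function(kb, m, n_trials, alpha = 0.001,
                                       seed = NULL) {
  stopifnot(inherits(kb, "raredx_kb"))
  if (nrow(kb$diseases) < 2L) {
    abort_data("at least two diseases are needed to define a score gap")
  }
  if (n_trials < 1L) abort_data("n_trials must be at least 1")
  stopifnot(alpha > 0, alpha < 1)
  ns <- nrow(kb$symptoms)
  if (m < 1L || m > ns) {
    abort_data("query size m must be between 1 and the vocabulary size (", ns, ")")
  }
  gaps <- numeric(n_trials)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      sc <- score_query_idx(kb, sample.int(ns, m))
      d1 <- max(sc$ds)
      below <- sc$ds[sc$ds < d1]
      gaps[t] <- if (length(below)) d1 - max(below) else 0
    }
  })
  # type 1 (inverse ECDF): the quantile is an order statistic, i.e. an
  # actually realized gap, appropriate for a discrete empirical null
  stats::quantile(gaps, 1 - alpha, names = FALSE, type = 1)
}
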