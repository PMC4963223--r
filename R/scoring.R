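#' Diagnostic score for one disease
#'
#' The ranking statistic of the engine is a normalized Hamming-like
#' distance between two symptom sets: with `n` the number of symptoms in
#' the symmetric difference between the query set and the disease's set,
#' and `max_size` the larger of the two set sizes,
#' \deqn{DS = 1 - n / \max(S_{query}, S_{disease}).}
#' `DS` lies in \eqn{[-1, 1]}: it is 1 exactly when the two sets are
#' equal, and \eqn{-1} exactly when they are disjoint and of equal size.
#' Both arguments are treated as sets (duplicates collapse).
#'
#' @param query Character (or atomic) vector of query symptom ids;
#'   must be non-empty.
#' @param disease Vector of the disease's symptom ids; must be non-empty.
#' @return A list with elements `n` (symmetric-difference count),
#'   `max_size`, and `ds`.
#' @examples
#' # 1 matching symptom against a disease with 23 symptoms: ds = 1/23
#' score_breakdown("s1", paste0("s", 1:23))
#' @export
score_breakdown <- function(query, disease) {
  q <- unique(query)
  d <- unique(disease)
  if (length(q) == 0L) abort_data("query symptom set is empty")
  if (length(d) == 0L) abort_data("disease symptom set is empty")
  shared <- sum(q %in% d)
  n <- (length(q) - shared) + (length(d) - shared)
  max_size <- max(length(q), length(d))
  list(n = n, max_size = max_size, ds = 1 - n / max_size)
}

# Resolve query symptom ids to vocabulary indices; collapses duplicates,
# rejects unknown ids naming the offenders.
resolve_query <- function(kb, symptoms) {
  q <- unique(as.character(symptoms))
  if (length(q) == 0L) abort_data("query symptom set is empty")
  idx <- match(q, kb$symptoms$symptom_id)
  if (anyNA(idx)) {
    abort_data("symptom id(s) absent from the knowledge base: ",
               paste(q[is.na(idx)], collapse = ", "))
  }
  idx
}

# Score a query (vocabulary indices) against every disease using the
# inverted index: overlap k per disease is a tabulation over the posting
# lists of the query's symptoms, then
#   n = S_i + m - 2k,   ds = 1 - n / max(S_i, m),
# written exactly as in score_breakdown() so both paths yield
# bit-identical doubles. Scores that are equal as rationals are equal as
# doubles (IEEE division is correctly rounded), so ties can be detected
# by exact comparison.
score_query_idx <- function(kb, sym_idx) {
  m <- length(sym_idx)
  sizes <- kb$sizes
  maxs <- pmax(sizes, m)
  ov <- tabulate(unlist(kb$symptom_diseases[sym_idx], use.names = FALSE),
                 nbins = length(sizes))
  n <- sizes + m - 2L * ov
  list(ds = 1 - n / maxs, n = n, max_size = maxs, overlap = ov)
}

#' Rank all diseases for a symptom query
#'
#' Computes the diagnostic score of every disease in the knowledge base
#' for the submitted symptom set and returns the full differential
#' diagnosis, sorted by non-increasing score with ties broken by
#' ascending disease id. The tie group at the maximal score (`top_set`)
#' is reported separately because set-similarity scores frequently tie
#' and the benchmark's true/false-positive accounting operates on that
#' set. A score at or above `threshold` is flagged statistically
#' significant (under random queries such scores arise with probability
#' below 1e-4; see [null_distribution()]).
#'
#' @param kb A `raredx_kb`.
#' @param symptoms Character vector of query symptom ids; duplicates
#'   collapse; ids absent from the vocabulary are rejected with an error
#'   naming them.
#' @param threshold Significance cutoff on the score (default 0.5,
#'   inclusive).
#' @return A `raredx_diagnosis`: list with `ranked` (data frame with
#'   columns rank, disease_id, disease_name, ds, n, max_size,
#'   significant), `top_set` (ids tied at the maximal score), `threshold`
#'   and `query`.
#' @examples
#' kb <- kb_from_sets(list(D1 = c("a", "b"), D2 = c("b", "c"), D3 = "d"))
#' rank_diseases(kb, "b")
#' @export
rank_diseases <- function(kb, symptoms, threshold = 0.5) {
  stopifnot(inherits(kb, "raredx_kb"))
  idx <- resolve_query(kb, symptoms)
  sc <- score_query_idx(kb, idx)
  ord <- order(-sc$ds, kb$diseases$disease_id)
  ds <- sc$ds[ord]
  ranked <- data.frame(
    rank = seq_along(ord),
    disease_id = kb$diseases$disease_id[ord],
    disease_name = kb$diseases$disease_name[ord],
    ds = ds,
    n = sc$n[ord],
    max_size = sc$max_size[ord],
    significant = ds >= threshold,
    stringsAsFactors = FALSE
  )
  top <- sc$ds == max(sc$ds)
  structure(
    list(ranked = ranked,
         top_set = kb$diseases$disease_id[top],
         threshold = threshold,
         query = sort(kb$symptoms$symptom_id[idx])),
    class = "raredx_diagnosis"
  )
}

#' @export
print.raredx_diagnosis <- function(x, n = 10L, ...) {
  cat("<raredx_diagnosis> query of", length(x$query), "symptom(s);",
      nrow(x$ranked), "diseases ranked\n")
  cat("top-score set:", paste(x$top_set, collapse = ", "),
      sprintf("(ds = %.4g)", x$ranked$ds[1L]), "\n")
  print(utils::head(x$ranked, n), row.names = FALSE)
  if (nrow(x$ranked) > n) cat("...", nrow(x$ranked) - n, "more\n")
  invisible(x)
}

#' Minimum matching symptoms for a significant score
#'
#' For a disease with `disease_size` symptoms, returns the smallest
#' number `k` of submitted matching symptoms (a query that is a size-`k`
#' subset of the disease's set) whose score `k / disease_size` reaches
#' the significance threshold, i.e. `ceiling(threshold * disease_size)`.
#'
#' @param disease_size Number of symptoms of the disease (vectorized,
#'   each at least 1).
#' @param threshold Significance cutoff (default 0.5, inclusive).
#' @return Integer vector of minimal matching-symptom counts.
#' @examples
#' min_symptoms_for_significance(c(7, 48, 180))  # 4, 24, 90
#' @export
min_symptoms_for_significance <- function(disease_size, threshold = 0.5) {
  if (any(disease_size < 1L)) abort_data("disease_size must be at least 1")
  stopifnot(threshold > 0, threshold <= 1)
  k <- as.integer(ceiling(threshold * disease_size))
  # guard against upward floating error in the ceiling argument
  k <- k - as.integer((k - 1L) / disease_size >= threshold)
  k
}
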