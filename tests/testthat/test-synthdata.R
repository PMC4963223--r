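test_that("generation is deterministic for a fixed spec", {
  spec <- synthetic_kb_spec(n_diseases = 10, vocab_size = 50,
                            size_min = 3, size_max = 6, seed = 7)
  kb1 <- generate_kb(spec)
  kb2 <- generate_kb(spec)
  expect_identical(kb_assoc(kb1), kb_assoc(kb2))
  # a different seed gives a different KB
  kb3 <- generate_kb(synthetic_kb_spec(n_diseases = 10, vocab_size = 50,
                                       size_min = 3, size_max = 6, seed = 8))
  expect_false(identical(kb_assoc(kb1), kb_assoc(kb3)))
  # generation restores the caller's RNG state
  set.seed(1); before <- .Random.seed
  generate_kb(spec)
  expect_identical(.Random.seed, before)
})

test_that("generated knowledge bases satisfy every invariant", {
  spec <- synthetic_kb_spec(n_diseases = 200, vocab_size = 400,
                            size_min = 4, size_max = 40, seed = 3)
  kb <- generate_kb(spec)
  rep <- validate_kb(kb)
  expect_true(rep$ok)
  expect_equal(nrow(kb$diseases), 200L)
  expect_true(all(kb$sizes >= 4L & kb$sizes <= 40L))
  expect_false(anyDuplicated(kb$diseases$disease_id) > 0)
})

test_that("symptom-set sizes follow the truncated log-normal", {
  spec <- synthetic_kb_spec(seed = 1)  # defaults: 2000 x 3000, sizes 5-180
  kb <- generate_kb(spec)
  sizes <- kb$sizes
  expect_true(all(sizes >= spec$size_min & sizes <= spec$size_max))
  # oracle: integer pmf of the rounded, truncated log-normal computed
  # directly from plnorm
  k <- spec$size_min:spec$size_max
  lo <- pmax(k - 0.5, spec$size_min)
  hi <- pmin(k + 0.5, spec$size_max)
  pmf <- stats::plnorm(hi, spec$size_log_mean, spec$size_log_sd) -
         stats::plnorm(lo, spec$size_log_mean, spec$size_log_sd)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  med_theor <- k[which(cdf >= 0.5)[1]]
  # the sample median must sit where the theoretical CDF crosses 1/2,
  # within 3 standard errors of the empirical CDF at the median
  se <- 3 * sqrt(0.25 / length(sizes))
  med_emp <- as.integer(floor(stats::median(sizes)))
  cdf_at <- function(x) if (x < k[1]) 0 else cdf[min(x, max(k)) - k[1] + 1]
  expect_gte(cdf_at(med_emp), 0.5 - se)
  expect_lte(cdf_at(med_emp - 1L), 0.5 + se)
  expect_lte(abs(med_emp - med_theor), 3L)
  # mean within 3 standard errors of the theoretical mean
  mu <- sum(k * pmf)
  sdv <- sqrt(sum((k - mu)^2 * pmf))
  expect_lt(abs(mean(sizes) - mu), 3 * sdv / sqrt(length(sizes)))
})

test_that("sharing concentration increases pairwise symptom overlap", {
  mean_overlap <- function(conc, seed) {
    spec <- synthetic_kb_spec(n_diseases = 100, vocab_size = 300,
                              size_min = 4, size_max = 20,
                              sharing_concentration = conc, seed = seed)
    kb <- generate_kb(spec)
    memb <- matrix(0L, nrow = 100, ncol = 300)
    for (i in seq_len(100)) memb[i, kb$disease_symptoms[[i]]] <- 1L
    ov <- tcrossprod(memb)
    mean(ov[upper.tri(ov)])
  }
  # average over a few seeds so the monotonicity check is not hostage to
  # a single draw of the popularity weights
  seeds <- 1:4
  m0 <- mean(vapply(seeds, function(s) mean_overlap(0, s), 0))
  m2 <- mean(vapply(seeds, function(s) mean_overlap(2, s), 0))
  m8 <- mean(vapply(seeds, function(s) mean_overlap(8, s), 0))
  expect_lt(m0, m2)
  expect_lt(m2, m8)
})

test_that("cohort generation matches the baseline cohort contract", {
  kb <- generate_kb(synthetic_kb_spec(n_diseases = 10, vocab_size = 60,
                                      size_min = 3, size_max = 8, seed = 5))
  expect_identical(generate_cohort(kb, 1), make_baseline_cohort(kb))
  c3 <- generate_cohort(kb, 3)
  expect_equal(nrow(c3$patients), 30L)
  expect_false(anyDuplicated(c3$patients$patient_id) > 0)
  # all patients are valid queries against the KB
  m <- evaluate_cohort(c3, kb)
  expect_equal(m$f1, 1)
  expect_error(generate_cohort(kb, 0), "at least 1")
})

test_that("impossible distinctness budgets error with the colliding sizes", {
  # 5 diseases of exactly 1 symptom over a 3-symptom vocabulary cannot
  # be pairwise distinct
  spec <- synthetic_kb_spec(n_diseases = 5, vocab_size = 3,
                            size_min = 1, size_max = 1,
                            size_log_mean = 0, size_log_sd = 1, seed = 2)
  expect_error(generate_kb(spec), "colliding sizes")
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(synthetic_kb_spec(size_min = 10, size_max = 5), "size_min")
  expect_error(synthetic_kb_spec(vocab_size = 10, size_max = 20), "size_min")
  expect_error(synthetic_kb_spec(n_diseases = 0), "at least 1")
  expect_error(synthetic_kb_spec(sharing_concentration = -1), "non-negative")
})
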