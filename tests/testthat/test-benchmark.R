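toy_kb <- kb_from_sets(list(D1 = c("a", "b"), D2 = c("b", "c"), D3 = "d"))

test_that("baseline cohort is one full-symptom patient per disease", {
  cohort <- make_baseline_cohort(toy_kb)
  expect_equal(nrow(cohort$patients), 3L)
  expect_identical(cohort$patients$true_disease_id, c("D1", "D2", "D3"))
  for (i in 1:3) {
    expect_identical(cohort$observed[[i]],
                     kb_disease_symptoms(toy_kb,
                                         cohort$patients$true_disease_id[i]))
  }
  m <- evaluate_cohort(cohort, toy_kb)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$f1, 1)

  dup <- kb_from_sets(list(D1 = c("a", "b"), D2 = c("a", "b")))
  expect_error(make_baseline_cohort(dup), "duplicate")
})

test_that("tie semantics: extra top-scoring diseases count as false positives", {
  # single patient, true D1, observed {b}: top set {D1, D2} -> TP 1, FP 1
  cohort <- manual_cohort("D1", list("b"))
  m <- evaluate_cohort(cohort, toy_kb)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$top1_rate, 1)

  # true disease outside the top set -> all metrics 0
  miss <- manual_cohort("D3", list("b"))
  m0 <- evaluate_cohort(miss, toy_kb)
  expect_equal(m0$precision, 0)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$f1, 0)

  expect_error(evaluate_cohort(manual_cohort("D1", list("ghost")), toy_kb),
               "ghost")
})

test_that("evaluate_cohort agrees with the brute-force metrics oracle", {
  set.seed(41)
  for (rep in 1:8) {
    sets <- random_small_sets(sample(2:5, 1), sample(4:6, 1))
    kb <- kb_from_sets(sets)
    vocab_ids <- kb$symptoms$symptom_id
    n_pat <- sample(2:6, 1)
    true_ids <- sample(names(sets), n_pat, replace = TRUE)
    observed <- lapply(seq_len(n_pat), function(i) {
      sample(vocab_ids, sample.int(length(vocab_ids), 1))
    })
    m <- evaluate_cohort(manual_cohort(true_ids, observed), kb)
    orc <- oracle_metrics(sets, true_ids, observed)
    expect_equal(m$precision, orc$precision)
    expect_equal(m$sensitivity, orc$sensitivity)
    expect_equal(m$f1, orc$f1)
    # structural invariants
    expect_lte(m$precision, m$sensitivity)
    expect_lte(m$top1_rate, m$top10_rate)
    expect_lte(m$top10_rate, m$top50_rate)
  }
})

test_that("add/delete noise edits sequentially with a non-empty floor", {
  pat <- list(true_disease_id = "D1", observed = c("a", "b"))
  expect_identical(apply_add_delete_noise(pat, toy_kb, 0), pat)

  # a deletion that would empty the set becomes an addition
  single <- list(true_disease_id = "D3", observed = "d")
  set.seed(8)
  out <- apply_add_delete_noise(single, toy_kb, 1, add_prob = 0)
  expect_length(out$observed, 2L)
  expect_true("d" %in% out$observed)
  expect_identical(out$true_disease_id, "D3")

  # additions draw from the vocabulary outside the observed set
  set.seed(8)
  grown <- apply_add_delete_noise(pat, toy_kb, 2, add_prob = 1)
  expect_length(grown$observed, 4L)
  expect_true(all(grown$observed %in% toy_kb$symptoms$symptom_id))
  expect_false(anyDuplicated(grown$observed) > 0)

  # vocabulary exhausted -> skipped edit with warning
  full <- list(true_disease_id = "D1",
               observed = toy_kb$symptoms$symptom_id)
  expect_warning(out2 <- apply_add_delete_noise(full, toy_kb, 1, add_prob = 1),
                 "exhausted")
  expect_length(out2$observed, 4L)

  # determinism under a fixed seed
  set.seed(99); a <- apply_add_delete_noise(pat, toy_kb, 5)
  set.seed(99); b <- apply_add_delete_noise(pat, toy_kb, 5)
  expect_identical(a, b)
})

test_that("fractional deletion removes floor(f*n) keeping at least one", {
  pat48 <- list(true_disease_id = "X", observed = paste0("s", 1:48))
  set.seed(2)
  expect_length(apply_fraction_deletion(pat48, 0.5)$observed, 24L)
  pat2 <- list(true_disease_id = "X", observed = c("a", "b"))
  set.seed(2)
  expect_length(apply_fraction_deletion(pat2, 0.75)$observed, 1L)
  # deleted symptoms come from the observed set; survivors are a subset
  set.seed(3)
  out <- apply_fraction_deletion(pat48, 0.25)
  expect_true(all(out$observed %in% pat48$observed))
  expect_length(out$observed, 36L)
  set.seed(11); a <- apply_fraction_deletion(pat48, 0.5)
  set.seed(11); b <- apply_fraction_deletion(pat48, 0.5)
  expect_identical(a, b)
})

test_that("noise grids validate their arguments", {
  g <- noise_grid("add_delete_count")
  expect_identical(sort(unique(g$level)), c(1, 2, 3, 4, 5, 10, 20))
  expect_equal(nrow(g), 7 * 11)
  expect_error(noise_grid("add_delete_count", levels = 0), "at least 1")
  expect_error(noise_grid("delete_fraction", levels = 1), "between 0 and 1")
  expect_error(noise_grid("add_delete_count", patient_fraction = 2), "0, 1")
})

test_that("an unperturbed grid cell scores perfectly in every replicate", {
  kb <- generate_kb(synthetic_kb_spec(n_diseases = 30, vocab_size = 120,
                                      size_min = 3, size_max = 10, seed = 6))
  g <- noise_grid("add_delete_count", levels = c(1, 20),
                  patient_fraction = 0)
  res <- run_noise_grid(kb, g, replicates = 3, seed = 5)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$precision == 1))
  expect_true(all(res$sensitivity == 1))
  expect_true(all(res$f1 == 1))
})

test_that("noise grids are reproducible and respect p <= s", {
  kb <- generate_kb(synthetic_kb_spec(n_diseases = 40, vocab_size = 150,
                                      size_min = 3, size_max = 12, seed = 2))
  g <- rbind(noise_grid("add_delete_count", levels = c(2, 10),
                        patient_fraction = c(0.5, 1)),
             noise_grid("delete_fraction", levels = 0.5,
                        patient_fraction = 1))
  r1 <- run_noise_grid(kb, g, replicates = 2, seed = 123)
  r2 <- run_noise_grid(kb, g, replicates = 2, seed = 123)
  expect_identical(r1, r2)
  expect_true(all(r1$precision <= r1$sensitivity))
  expect_true(all(r1$top1_rate <= r1$top10_rate))
  expect_true(all(r1$top10_rate <= r1$top50_rate))
  expect_true(all(r1$sensitivity >= 0 & r1$sensitivity <= 1))
  expect_identical(
    names(r1),
    c("experiment", "mode", "k_or_fraction", "patient_fraction", "replicate",
      "seed", "n_patients", "precision", "sensitivity", "f1", "top1_rate",
      "top10_rate", "top50_rate"))
})

test_that("deletion-only noise keeps the true disease's score positive", {
  # with only deletions, the true disease retains k of its S symptoms and
  # scores k/S > 0; verify against brute force on a small KB
  set.seed(19)
  sets <- list(D1 = letters[1:6], D2 = letters[5:10], D3 = letters[c(1, 7, 11)])
  kb <- kb_from_sets(sets)
  for (i in 1:20) {
    id <- sample(names(sets), 1)
    pat <- list(true_disease_id = id, observed = sets[[id]])
    out <- apply_fraction_deletion(pat, 0.5)
    b <- score_breakdown(out$observed, sets[[id]])
    k <- length(out$observed); S <- length(sets[[id]])
    expect_equal(b$ds, k / S)
    expect_gt(b$ds, 0)
  }
})
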