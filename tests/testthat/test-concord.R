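test_that("candidate translation composes the two maps with provenance", {
  cand <- data.frame(probeset_id = c("A", "B"),
                     direction = c("up", "down"),
                     discovery_log2fc = c(1.4, -1.2),
                     stringsAsFactors = FALSE)
  fwd <- data.frame(source_id = c("A", "A"), target_id = c("G1", "G2"),
                    stringsAsFactors = FALSE)
  rev <- data.frame(source_id = c("G1", "G1", "G2"),
                    target_id = c("X1", "X2", "X1"),
                    stringsAsFactors = FALSE)
  tr <- translate_candidates(cand, fwd, rev)
  # A -> {G1, G2} -> {X1, X2}; X1 reachable twice but emitted once
  expect_setequal(tr$translated$probeset_id, c("X1", "X2"))
  expect_true(all(tr$translated$source_id == "A"))
  expect_true(all(tr$translated$direction == "up"))
  # B has no symbol mapping: reported unmapped, absent from output
  expect_equal(tr$unmapped, "B")
})

test_that("empty candidate list translates to empty output", {
  cand <- data.frame(probeset_id = character(0), direction = character(0))
  tr <- translate_candidates(cand,
                             data.frame(source_id = "A", target_id = "G"),
                             data.frame(source_id = "G", target_id = "X"))
  expect_equal(nrow(tr$translated), 0L)
  expect_length(tr$unmapped, 0)
})

test_that("perfect zero-noise concordance validates every candidate", {
  cfg <- small_config(n_de_up = 20, n_de_down = 20, n_onoff_on = 0,
                      n_onoff_off = 0, within_class_sd = 0)
  paired <- simulate_paired_cohorts(cfg, validation_fraction_concordant = 1)
  ctr <- neoplasia_contrast()
  de <- run_contrast(paired$discovery$matrix, paired$discovery$phenotypes,
                     ctr)
  cand <- candidate_list(de)
  expect_equal(nrow(cand), 40L)
  rep1 <- validate_candidates(cand, paired$validation$matrix,
                              paired$validation$phenotypes, ctr)
  expect_equal(rep1$by_direction$fraction_validated, c(1, 1))
  expect_equal(sum(rep1$by_direction$n_validated), 40L)
})

test_that("partially concordant truth validates in exact proportion", {
  cfg <- small_config(n_de_up = 50, n_de_down = 50, n_onoff_on = 0,
                      n_onoff_off = 0, n_probesets = 400,
                      within_class_sd = 0)
  paired <- simulate_paired_cohorts(cfg, validation_fraction_concordant = 0.8)
  ctr <- neoplasia_contrast()
  de <- run_contrast(paired$discovery$matrix, paired$discovery$phenotypes,
                     ctr)
  cand <- candidate_list(de)
  expect_equal(nrow(cand), 100L)
  rep1 <- validate_candidates(cand, paired$validation$matrix,
                              paired$validation$phenotypes, ctr)
  expect_equal(sum(rep1$by_direction$n_validated), 80L)
})

test_that("an all-null validation cohort rarely validates anything", {
  # false-validation rate at alpha = 0.05 over replicates
  rates <- vapply(1:30, function(r) {
    cfg <- small_config(n_de_up = 10, n_de_down = 10, n_onoff_on = 0,
                        n_onoff_off = 0, n_probesets = 100, seed = 300L + r)
    paired <- simulate_paired_cohorts(cfg, validation_fraction_concordant = 0)
    ctr <- neoplasia_contrast()
    de <- run_contrast(paired$discovery$matrix,
                       paired$discovery$phenotypes, ctr)
    cand <- candidate_list(de)
    if (!nrow(cand)) return(0)
    rep1 <- validate_candidates(cand, paired$validation$matrix,
                                paired$validation$phenotypes, ctr)
    sum(rep1$by_direction$n_validated) / nrow(cand)
  }, numeric(1))
  expect_lt(mean(rates), 0.05 + 2 * sd(rates) / sqrt(length(rates)) + 0.02)
})

test_that("direction mismatches never validate and alpha is monotone", {
  cfg <- small_config(n_de_up = 20, n_de_down = 20, n_onoff_on = 0,
                      n_onoff_off = 0, within_class_sd = 0)
  paired <- simulate_paired_cohorts(cfg, 1)
  ctr <- neoplasia_contrast()
  de <- run_contrast(paired$discovery$matrix, paired$discovery$phenotypes,
                     ctr)
  cand <- candidate_list(de)
  flipped <- cand
  flipped$direction <- ifelse(cand$direction == "up", "down", "up")
  rep_flip <- validate_candidates(flipped, paired$validation$matrix,
                                  paired$validation$phenotypes, ctr)
  expect_equal(sum(rep_flip$by_direction$n_validated), 0L)

  # lowering alpha never increases the validated count (noisy cohort)
  noisy <- simulate_paired_cohorts(small_config(seed = 77L), 0.8)
  de_n <- run_contrast(noisy$discovery$matrix, noisy$discovery$phenotypes,
                       ctr)
  cand_n <- candidate_list(de_n, require_fc2 = FALSE)
  counts <- vapply(c(0.10, 0.05, 0.01, 0.001), function(a) {
    sum(validate_candidates(cand_n, noisy$validation$matrix,
                            noisy$validation$phenotypes, ctr,
                            alpha = a)$by_direction$n_validated)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidates absent from the validation platform are excluded", {
  cfg <- small_config(n_de_up = 10, n_de_down = 10, n_onoff_on = 0,
                      n_onoff_off = 0, within_class_sd = 0)
  paired <- simulate_paired_cohorts(cfg, 1)
  ctr <- neoplasia_contrast()
  de <- run_contrast(paired$discovery$matrix, paired$discovery$phenotypes,
                     ctr)
  cand <- candidate_list(de)
  cand$probeset_id[1] <- "not_on_chip"
  expect_message(
    rep1 <- validate_candidates(cand, paired$validation$matrix,
                                paired$validation$phenotypes, ctr),
    "absent")
  expect_equal(rep1$missing, "not_on_chip")
  expect_equal(sum(rep1$by_direction$n_candidates), 19L)
})

test_that("concordance summaries tabulate reports consistently", {
  cfg <- small_config(n_de_up = 10, n_de_down = 5, n_onoff_on = 0,
                      n_onoff_off = 0, within_class_sd = 0)
  paired <- simulate_paired_cohorts(cfg, 1)
  ctr <- neoplasia_contrast()
  de <- run_contrast(paired$discovery$matrix, paired$discovery$phenotypes,
                     ctr)
  rep1 <- validate_candidates(candidate_list(de), paired$validation$matrix,
                              paired$validation$phenotypes, ctr)
  tab <- concordance_summary(rep1)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_candidates, rep1$by_direction$n_candidates)
  expect_true(all(tab$n_validated_fc2 <= tab$n_validated))
  expect_true(all(tab$n_validated <= tab$n_candidates))

  empty <- concordance_summary(list())
  expect_equal(nrow(empty), 0L)
})
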