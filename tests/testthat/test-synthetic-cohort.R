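zero_confounders <- c(narcan_no_response = 0, detailed_denial = 0,
                      history_only = 0, behavioral_health_focus = 0,
                      unnamed_product = 0)

test_that("zero prevalence and zero confounders yield a keyword-free cohort", {
  cfg <- cohort_config(n = 120, prevalence = 0, confounder_rates = zero_confounders,
                       seed = 3)
  gen <- generate_cohort(cfg)
  expect_true(all(gen$cohort$label == "negative"))
  expect_equal(sum(featurize_flags(gen$cohort)), 0)
  expect_true(all(vapply(gen$truth$planted, nrow, integer(1)) == 0L))
})

test_that("certain narrative signal puts both term kinds in every positive narrative", {
  cfg <- cohort_config(n = 200, field_signal = c(chief_narrative = 1),
                       confounder_rates = zero_confounders, seed = 17)
  gen <- generate_cohort(cfg)
  ts <- default_term_sets()
  op <- count_term_matches(gen$cohort$chief_narrative, ts$opioid)
  ov <- count_term_matches(gen$cohort$chief_narrative, ts$overdose)
  pos <- gen$truth$labels == 1L
  expect_true(any(pos) && any(!pos))
  expect_true(all(op[pos] >= 1 & ov[pos] >= 1))
  expect_true(all(op[!pos] == 0 & ov[!pos] == 0))
})

test_that("labels are the seeded Bernoulli draw and reruns reproduce them exactly", {
  cfg <- cohort_config(n = 1000, prevalence = 0.15, seed = 77)
  gen <- generate_cohort(cfg)
  expected <- emsflags:::with_rng(77, stats::rbinom(1000, 1L, 0.15))
  expect_identical(gen$truth$labels, expected)
  gen2 <- generate_cohort(cfg)
  expect_identical(gen$truth$labels, gen2$truth$labels)
  expect_same_records(gen$cohort, gen2$cohort)
})

test_that("flag featurization reproduces the generation truth exactly (oracle linkage)", {
  for (seed in c(2, 29, 300)) {
    gen <- generate_cohort(cohort_config(n = 400, seed = seed))
    expect_equal(unname(featurize_flags(gen$cohort)),
                 unname(truth_flag_counts(gen$truth)) * 1.0)
  }
})

test_that("every planted term is findable verbatim in its field", {
  gen <- generate_cohort(cohort_config(n = 250, seed = 41))
  for (i in seq_len(250)) {
    p <- gen$truth$planted[[i]]
    for (j in seq_len(nrow(p))) {
      expect_true(grepl(p$term[j], gen$cohort[[p$field[j]]][i],
                        ignore.case = TRUE, fixed = FALSE))
    }
  }
})

test_that("identical configs emit byte-identical CSV", {
  cfg <- cohort_config(n = 150, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_encounters(generate_cohort(cfg)$cohort, f1)
  write_encounters(generate_cohort(cfg)$cohort, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("confounders inject the documented patterns", {
  cfg <- cohort_config(n = 800, prevalence = 0.3,
                       confounder_rates = c(narcan_no_response = 0.5,
                                            detailed_denial = 0.5,
                                            history_only = 0.5,
                                            behavioral_health_focus = 0.5,
                                            unnamed_product = 0),
                       seed = 63)
  gen <- generate_cohort(cfg)
  ts <- default_term_sets()
  conf <- gen$truth$confounders
  lab <- gen$truth$labels
  narc <- vapply(conf, function(x) "narcan_no_response" %in% x, logical(1))
  expect_gt(sum(narc), 0)
  expect_true(all(lab[narc] == 0L))
  expect_true(all(grepl("narcan", gen$cohort$chief_narrative[narc],
                        ignore.case = TRUE)))
  den <- vapply(conf, function(x) "detailed_denial" %in% x, logical(1))
  expect_gt(sum(den), 0)
  expect_true(all(count_term_matches(gen$cohort$chief_narrative[den],
                                     ts$opioid) >= 3))
  hist <- vapply(conf, function(x) "history_only" %in% x, logical(1)) &
    !narc & !den
  expect_gt(sum(hist), 0)
  # history-only negatives carry opioid terms outside the narrative fields
  hist_fields <- count_term_matches(gen$cohort$medical_history[hist], ts$opioid) +
    count_term_matches(gen$cohort$medication_list[hist], ts$opioid)
  expect_true(all(hist_fields >= 1))
  expect_true(all(count_term_matches(gen$cohort$chief_narrative[hist], ts$opioid) == 0))
  bh <- vapply(conf, function(x) "behavioral_health_focus" %in% x, logical(1))
  expect_gt(sum(bh), 0)
  expect_true(all(lab[bh] == 1L))
  # suppressed narrative: no planted narrative terms recorded in truth
  for (i in which(bh)) {
    expect_false("chief_narrative" %in% gen$truth$planted[[i]]$field)
  }
})

test_that("unnamed-product positives lose their opioid terms", {
  cfg <- cohort_config(n = 600, prevalence = 0.3,
                       confounder_rates = c(narcan_no_response = 0,
                                            detailed_denial = 0, history_only = 0,
                                            behavioral_health_focus = 0,
                                            unnamed_product = 1),
                       seed = 12)
  gen <- generate_cohort(cfg)
  ts <- default_term_sets()
  pos <- gen$truth$labels == 1L
  total_opioid <- rowSums(featurize_flags(gen$cohort)[, paste0("opioid__", ems_text_fields())])
  expect_true(all(total_opioid[pos] == 0))
  expect_true(any(grepl("unknown pain pills", gen$cohort$chief_narrative[pos])))
})

test_that("configs validate probabilities and filler collisions", {
  expect_error(cohort_config(prevalence = 1.5))
  expect_error(cohort_config(confounder_rates = c(narcan_no_response = 0.1)),
               "confounder_rates")
  expect_error(cohort_config(filler_vocab = c("patient", "narcan")), "collides")
  expect_error(cohort_config(filler_vocab = c("patient", "Overdose")), "collides")
})

test_that("scenario grids vary one axis with offset seeds", {
  base <- cohort_config(n = 50, seed = 100)
  grid <- grid_of_scenarios(base, "prevalence", c(0.05, 0.15, 0.30))
  expect_length(grid, 3)
  expect_equal(vapply(grid, `[[`, numeric(1), "prevalence"), c(0.05, 0.15, 0.30))
  expect_length(unique(vapply(grid, `[[`, integer(1), "seed")), 3)
  expect_equal(grid[[2]]$n, base$n)
  grid2 <- grid_of_scenarios(base, "narcan_no_response", c(0, 0.1))
  expect_length(grid2, 2)
  expect_equal(grid2[[2]]$confounder_rates[["narcan_no_response"]], 0.1)
  expect_length(grid_of_scenarios(base, "prevalence", numeric()), 0)
  expect_error(grid_of_scenarios(base, "nonsense", 1), "unknown")
})
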