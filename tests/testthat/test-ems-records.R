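test_that("CSV reading preserves rows, order and fills missing text fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,county,chief_narrative,label,extra",
    "A1,Travis,pt found unresponsive,1,x",
    "A2,ElPaso,,0,y",
    "A3,Travis,narcan administered,OOD,z"), path)
  expect_warning(coh <- read_encounters(path), "empty strings")
  expect_s3_class(coh, "ems_cohort")
  expect_equal(coh$record_id, c("A1", "A2", "A3"))
  expect_equal(coh$chief_narrative[2], "")
  expect_equal(coh$call_nature, rep("", 3))       # absent column -> empty strings
  expect_equal(coh$label, c("positive", "negative", "positive"))
  expect_equal(coh$extra, c("x", "y", "z"))       # pass-through metadata
})

test_that("duplicate record ids and unparseable labels are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,label", "A1,1", "A1,0"), path)
  expect_error(suppressWarnings(read_encounters(path)), "A1")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,label", "B1,1", "B2,maybe"), path2)
  expect_error(suppressWarnings(read_encounters(path2)), "row 2")
})

test_that("read/write round-trips cohorts in both formats", {
  gen <- generate_cohort(cohort_config(n = 40, seed = 31))
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_encounters(gen$cohort, path, fmt)
    back <- read_encounters(path, fmt)
    expect_same_records(back, gen$cohort)
  }
})

test_that("cohort summaries reproduce printed per-county and share arithmetic", {
  counties <- c(Travis = 1635, ElPaso = 747, Williamson = 576)
  pos_by_county <- c(Travis = 289, ElPaso = 99, Williamson = 50)
  rows <- do.call(rbind, lapply(names(counties), function(cty) {
    n <- counties[[cty]]; p <- pos_by_county[[cty]]
    data.frame(record_id = paste0(cty, seq_len(n)), county = cty,
               label = rep(c("positive", "negative"), c(p, n - p)),
               stringsAsFactors = FALSE)
  }))
  # positives' demographics with the documented counts
  pos_idx <- which(rows$label == "positive")
  stopifnot(length(pos_idx) == 438)
  rows$ethnicity <- NA_character_
  rows$ethnicity[pos_idx] <- rep(
    c("White", "Hispanic or Latino", "Black or African American", "Asian",
      "unknown or unassigned"), c(241, 113, 24, 1, 59))
  rows$gender <- NA_character_
  rows$gender[pos_idx] <- rep(c("male", "female"), c(315, 123))
  coh <- as_cohort(rows)
  s <- summarize_cohort(coh)
  expect_equal(s$n_total, 2958)
  expect_equal(s$n_positive, 438)
  expect_equal(unname(s$n_by_county[c("Travis", "ElPaso", "Williamson")]),
               c(1635, 747, 576))
  eth <- s$positive_share_by_ethnicity
  expect_equal(eth$percent_display[eth$category == "White"], 55.0)
  gen <- s$positive_share_by_gender
  expect_equal(gen$percent_display[gen$category == "male"], 71.9)
  # permutation invariance
  perm <- coh[sample(nrow(coh)), ]
  class(perm) <- class(coh)
  s2 <- summarize_cohort(perm)
  expect_equal(sort(s2$n_by_county), sort(s$n_by_county))
  expect_equal(s2$n_positive, s$n_positive)
})

test_that("empty cohort summarizes to zeros, not an error", {
  coh <- as_cohort(data.frame(record_id = character()))
  s <- summarize_cohort(coh)
  expect_equal(s$n_total, 0)
  expect_equal(s$n_positive, 0)
  expect_equal(length(s$n_by_county), 0L)
  expect_equal(nrow(s$positive_share_by_ethnicity), 0L)
})

test_that("train/test split is an exact deterministic partition", {
  gen <- generate_cohort(cohort_config(n = 123, seed = 5))
  coh <- gen$cohort
  for (frac in c(0.1, 0.2, 0.33, 0.5)) {
    for (seed in c(1, 99)) {
      parts <- split_train_test(coh, frac, seed)
      expect_equal(nrow(parts$train) + nrow(parts$test), nrow(coh))
      expect_length(intersect(parts$train$record_id, parts$test$record_id), 0)
      expect_setequal(c(parts$train$record_id, parts$test$record_id),
                      coh$record_id)
    }
  }
  p1 <- split_train_test(coh, 0.2, seed = 7)
  p2 <- split_train_test(coh, 0.2, seed = 7)
  expect_identical(p1$test$record_id, p2$test$record_id)
  small <- coh[1:10, ]; class(small) <- class(coh)
  expect_equal(nrow(split_train_test(small, 0.2, seed = 1)$test), 2)
})

test_that("stratified 80/20 split of a 438/2520 cohort reserves 592 records", {
  df <- data.frame(record_id = sprintf("r%04d", 1:2958),
                   label = rep(c("positive", "negative"), c(438, 2520)),
                   stringsAsFactors = FALSE)
  coh <- as_cohort(df)
  parts <- split_train_test(coh, 0.2, seed = 3, stratify_on_label = TRUE)
  expect_equal(nrow(parts$test), 592)  # round(.2*438) + round(.2*2520)
  expect_equal(sum(parts$test$label == "positive"), 88)
  unlab <- as_cohort(data.frame(record_id = c("u1", "u2")))
  expect_error(split_train_test(unlab, 0.2, 1, stratify_on_label = TRUE),
               "unlabeled")
})

test_that("JSON reports round-trip with stable structure and NaN as null", {
  s <- summarize_cohort(tiny_cohort())
  path <- withr::local_tempfile(fileext = ".json")
  write_report(s, path)
  back <- read_report(path)
  expect_equal(back$n_total, s$n_total)
  expect_equal(back$n_positive, s$n_positive)
  expect_equal(sort(unlist(back$n_by_county)), sort(s$n_by_county))
  expect_equal(back$positive_share_by_ethnicity$percent,
               s$positive_share_by_ethnicity$percent, tolerance = 1e-12)
  # a nested roc analysis serializes its CI as a [lo, hi] pair
  roc <- delong_ci(c(0.9, 0.8, 0.2, 0.1, 0.4, 0.7), c(1, 1, 0, 0, 0, 1))
  write_report(list(roc = unclass(roc)), path)
  expect_equal(read_report(path)$roc$ci, roc$ci, tolerance = 1e-12)
  # NaN-valued fields become null -> NA on read
  write_report(list(x = NaN, y = 1), path)
  expect_match(paste(readLines(path), collapse = ""), "\"x\": null")
  back <- read_report(path)
  expect_true(is.null(back$x) || is.na(back$x))  # unknown, not a number
  expect_equal(back$y, 1)
})
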