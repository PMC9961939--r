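# Daily feature construction: aggregation arithmetic, the coverage filter,
# imputation rules, normalization, and the no-leakage property.

t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

feat_adm <- function(ids, los_days = 3) {
  data.frame(admission_id = ids, patient_id = ids, age_years = 50, sex = "F",
             admitted_at = t0, discharged_at = t0 + los_days * 86400,
             died_in_icu = FALSE)
}

feat_ep <- function(ids, onset = 0L) {
  data.frame(admission_id = ids, onset_day = onset, included = TRUE,
             exclusion_reason = "none", septic_shock = FALSE)
}

feat_ev <- function(id, var, hours, values, class = "vital") {
  data.frame(admission_id = id, variable_name = var, timestamp = t0 + hours * 3600,
             numeric_value = values, variable_class = class)
}

test_that("within-day aggregation computes mean/max/min/population-sd and drug sums", {
  ev <- rbind(feat_ev("a1", "heart_rate", c(1, 2), c(60, 80)),
              feat_ev("a1", "hydrocortisone", c(3, 9), c(50, 50), "drug_bolus"),
              feat_ev("a1", "norepinephrine", 4, 0.2, "drug_rate"))
  spec <- default_feature_spec(c("heart_rate", "norepinephrine"),
                               c("vital", "drug_rate"))
  raw <- bin_and_aggregate(ev, feat_ep("a1"), feat_adm("a1"), spec = spec)
  d0 <- raw$table[raw$table$day_index == 0, ]
  expect_equal(d0$heart_rate__mean, 70)
  expect_equal(d0$heart_rate__max, 80)
  expect_equal(d0$heart_rate__min, 60)
  expect_equal(d0$heart_rate__sd, 10)       # population convention, n = 2
  expect_equal(d0$norepinephrine__sum, 0.2)
  # corticosteroids are excluded from the state by construction
  expect_false(any(grepl("hydrocortisone", raw$feature_cols)))
  # a day with no observation is missing, and sd of one observation is 0
  ev2 <- feat_ev("a1", "heart_rate", 30, 75)   # day 1 only
  raw2 <- bin_and_aggregate(ev2, feat_ep("a1"), feat_adm("a1"), spec = spec)
  expect_true(is.na(raw2$table$heart_rate__mean[raw2$table$day_index == 0]))
  expect_equal(raw2$table$heart_rate__sd[raw2$table$day_index == 1], 0)
})

test_that("days are counted from sepsis onset", {
  ev <- feat_ev("a1", "heart_rate", c(2, 26, 50), c(60, 70, 80))
  spec <- default_feature_spec("heart_rate", "vital")
  raw <- bin_and_aggregate(ev, feat_ep("a1", onset = 1L), feat_adm("a1"),
                           spec = spec)
  # day 0 of the episode is ICU day 1; the pre-onset observation is dropped
  expect_equal(raw$table$day_index, c(0L, 1L))
  expect_equal(raw$table$heart_rate__mean, c(70, 80))
})

cov_table <- function(n_obs, n_days = 100) {
  data.frame(admission_id = rep("a1", n_days), day_index = seq_len(n_days) - 1L,
             sparse__mean = c(rep(1, n_obs), rep(NA_real_, n_days - n_obs)),
             dense__mean = 1)
}

test_that("the coverage filter keeps variables observed in more than the threshold", {
  out1 <- filter_coverage(cov_table(1), "a1", threshold = 0.02)   # 1% -> dropped
  expect_equal(out1$dropped, "sparse__mean")
  out3 <- filter_coverage(cov_table(3), "a1", threshold = 0.02)   # 3% -> kept
  expect_equal(out3$dropped, character(0))
  # boundary: exactly 2% is NOT more than 2%
  out2 <- filter_coverage(cov_table(2), "a1", threshold = 0.02)
  expect_equal(out2$dropped, "sparse__mean")
  # threshold 0 keeps anything observed at least once
  out0 <- filter_coverage(cov_table(1), "a1", threshold = 0)
  expect_equal(out0$dropped, character(0))
  expect_error(filter_coverage(cov_table(1), "a1", threshold = 1), "threshold")
  expect_error(filter_coverage(cov_table(1), "a1", threshold = -0.1), "threshold")
})

imp_spec <- default_feature_spec(c("lab_x", "drug_y"), c("lab", "drug_bolus"))

test_that("imputation forward-fills labs within admissions and zero-fills drugs", {
  tab <- data.frame(admission_id = rep(c("a1", "a2"), c(4, 2)),
                    day_index = c(0:3, 0:1),
                    lab_x__mean = c(5, NA, NA, 7, NA, 3),
                    drug_y__sum = c(NA, 100, NA, 2, NA, 1))
  out <- impute_daily(tab, imp_spec, train_ids = c("a1", "a2"))
  expect_equal(out$table$lab_x__mean[1:4], c(5, 5, 5, 7))
  expect_equal(out$table$drug_y__sum[1:4], c(0, 100, 0, 2))
  # leading gap of a2 filled with the training median, never a1's last value
  expect_equal(out$table$lab_x__mean[5], median(c(5, 7, 3)))
  expect_equal(out$imputed_fraction, 6 / 12)   # six missing cells of twelve
  # a fully observed table is untouched
  full <- data.frame(admission_id = "a1", day_index = 0:1,
                     lab_x__mean = c(1, 2), drug_y__sum = c(0, 3))
  out_full <- impute_daily(full, imp_spec, train_ids = "a1")
  expect_equal(out_full$imputed_fraction, 0)
  expect_equal(out_full$table, data.table::as.data.table(full))
})

test_that("imputation is idempotent", {
  tab <- data.frame(admission_id = "a1", day_index = 0:3,
                    lab_x__mean = c(NA, 4, NA, 6), drug_y__sum = c(1, NA, NA, 2))
  once <- impute_daily(tab, imp_spec, train_ids = "a1")
  twice <- impute_daily(once$table, imp_spec, medians = once$medians)
  expect_equal(twice$table, once$table)
  expect_equal(twice$imputed_fraction, 0)
})

test_that("normalization maps the fitted range onto [-1, 1] and clips beyond it", {
  tab <- data.frame(admission_id = rep(c("tr", "te"), c(3, 2)),
                    day_index = c(0:2, 0:1),
                    x__mean = c(10, 20, 30, 5, 40),
                    const__mean = 1)
  out <- normalize_daily(tab, train_ids = "tr")
  expect_equal(out$table$x__mean[1:3], c(-1, 0, 1))   # endpoints and midpoint
  expect_equal(out$table$x__mean[4:5], c(-1, 1))      # clipped test values
  expect_equal(out$table$const__mean, rep(0, 5))      # constant variable -> 0
  # round trip for unclipped values
  expect_equal(denormalize(out$table$x__mean[2], out$bounds$low[["x__mean"]],
                           out$bounds$high[["x__mean"]]), 20, tolerance = 1e-9)
})

test_that("every daily state lies in [-1,1] with a stable feature order on real output", {
  co <- small_cohort()
  sofa <- suppressWarnings(compute_sofa_daily(co$events, co$admissions))
  ep <- identify_sepsis(sofa, detect_suspected_infection(co$events),
                        co$admissions)
  splits <- split_admissions(ep$admission_id[ep$included], seed = 3)
  tr_ids <- splits$admission_id[splits$split == "train"]
  ds <- build_daily_states(co$events, ep, co$admissions, tr_ids)
  M <- as.matrix(ds$states[, ds$feature_names, with = FALSE])
  expect_true(all(M >= -1 & M <= 1))
  expect_identical(ds$feature_names, sort(ds$feature_names))
  # the rare laboratory value fails the 2% coverage rule and is dropped
  expect_true(any(grepl("csf_protein", ds$fit$dropped)))
  # refitting via the frozen fit reproduces the transform exactly
  ds2 <- build_daily_states(co$events, ep, co$admissions, tr_ids, fit = ds$fit)
  expect_equal(ds2$states, ds$states)
})

test_that("validation and test data never influence the fitted transform", {
  co <- small_cohort()
  sofa <- suppressWarnings(compute_sofa_daily(co$events, co$admissions))
  ep <- identify_sepsis(sofa, detect_suspected_infection(co$events),
                        co$admissions)
  splits <- split_admissions(ep$admission_id[ep$included], seed = 3)
  tr_ids <- splits$admission_id[splits$split == "train"]
  ds <- build_daily_states(co$events, ep, co$admissions, tr_ids)
  # corrupt every non-training admission's measurements grossly
  ev2 <- data.table::as.data.table(co$events)
  tampered <- !(ev2$admission_id %in% tr_ids)
  ev2$numeric_value[tampered] <- ev2$numeric_value[tampered] * 10 + 500
  ds2 <- build_daily_states(ev2, ep, co$admissions, tr_ids)
  expect_identical(ds2$fit$kept, ds$fit$kept)
  expect_identical(ds2$fit$bounds, ds$fit$bounds)
  expect_identical(ds2$fit$medians, ds$fit$medians)
  # training rows themselves are bit-identical
  tr_rows <- ds$states[ds$states$admission_id %in% tr_ids, ]
  tr_rows2 <- ds2$states[ds2$states$admission_id %in% tr_ids, ]
  expect_identical(tr_rows2, tr_rows)
})
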