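# Sepsis-3 cohort extraction: SOFA grid fixtures, suspected-infection
# pairing windows, inclusion/exclusion and onset rules, septic shock.

mk_adm <- function(ids, los_hours = 72, age = 60) {
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  data.frame(admission_id = ids, patient_id = paste0("p", ids),
             age_years = rep_len(age, length(ids)), sex = "M",
             admitted_at = t0,
             discharged_at = t0 + rep_len(los_hours, length(ids)) * 3600,
             died_in_icu = FALSE)
}

mk_events <- function(id, var, hours, values, class = "lab") {
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  data.frame(admission_id = id, variable_name = var,
             timestamp = t0 + hours * 3600, numeric_value = values,
             variable_class = class)
}

test_that("SOFA subscores follow the Sepsis-3 grid on single-derangement fixtures", {
  adm <- mk_adm("a1", los_hours = 24)
  # platelets 90 -> coagulation 2, everything else normal
  ev <- rbind(mk_events("a1", "platelets", 2, 90),
              mk_events("a1", "map", 3, 80, "vital"),
              mk_events("a1", "creatinine", 4, 0.8),
              mk_events("a1", "bilirubin", 5, 0.5),
              mk_events("a1", "gcs", 6, 15),
              mk_events("a1", "pf_ratio", 7, 420))
  s <- compute_sofa_daily(ev, adm)
  expect_equal(s$coagulation, 2L)
  expect_equal(s$total, 2L)
  # MAP 65 without vasopressors -> cardiovascular 1
  ev2 <- mk_events("a1", "map", 2, 65, "vital")
  s2 <- compute_sofa_daily(ev2, adm)
  expect_equal(s2$cardiovascular, 1L)
  expect_equal(s2$total, 1L)
  # low-dose norepinephrine -> 3; high dose -> 4
  ev3 <- rbind(ev2, mk_events("a1", "norepinephrine", 3, 0.05, "drug_rate"))
  expect_equal(compute_sofa_daily(ev3, adm)$cardiovascular, 3L)
  ev4 <- rbind(ev2, mk_events("a1", "norepinephrine", 3, 0.3, "drug_rate"))
  expect_equal(compute_sofa_daily(ev4, adm)$cardiovascular, 4L)
  # hypoxemia scores 3-4 only under ventilation
  ev5 <- rbind(mk_events("a1", "pf_ratio", 2, 150),
               mk_events("a1", "ventilated", 2, 1, "ventilation"))
  expect_equal(compute_sofa_daily(ev5, adm)$respiration, 3L)
  expect_equal(compute_sofa_daily(mk_events("a1", "pf_ratio", 2, 150),
                                  adm)$respiration, 2L)
})

test_that("missing inputs score zero and zero-event admissions warn", {
  adm <- mk_adm(c("a1", "a2"), los_hours = 48)
  ev <- mk_events("a1", "platelets", 2, 200)
  expect_warning(s <- compute_sofa_daily(ev, adm), "no events")
  expect_equal(nrow(s), 4L)  # two admissions x two days
  expect_true(all(s$total[s$admission_id == "a2"] == 0))
})

test_that("the worst value within each 24 h window determines the subscore", {
  adm <- mk_adm("a1", los_hours = 24)
  ev <- mk_events("a1", "platelets", c(1, 5, 9), c(160, 45, 120))
  expect_equal(compute_sofa_daily(ev, adm)$coagulation, 3L)  # min 45 -> 3
})

test_that("suspected infection requires a culture/antibiotic pair within the window", {
  adm <- mk_adm("a1", los_hours = 24 * 12)
  culture <- mk_events("a1", "blood_culture", 24, 1, "culture")
  # antibiotic one day after the culture: suspicion at the culture time
  abx <- mk_events("a1", "abx_ceftriaxone", 48, 2000, "drug_bolus")
  susp <- detect_suspected_infection(rbind(culture, abx))
  expect_equal(nrow(susp), 1L)
  expect_equal(susp$suspected_at, culture$timestamp)
  # antibiotics alone never suffice
  expect_equal(nrow(detect_suspected_infection(abx)), 0L)
  # antibiotic 10 days after the culture falls outside +72 h
  late <- mk_events("a1", "abx_ceftriaxone", 24 * 10 + 24, 2000, "drug_bolus")
  expect_equal(nrow(detect_suspected_infection(rbind(culture, late))), 0L)
  # ... unless the window is widened explicitly
  expect_equal(nrow(detect_suspected_infection(rbind(culture, late),
                                               window_after_h = 300)), 1L)
  # antibiotic shortly before the culture pairs too, suspicion at the antibiotic
  pre <- mk_events("a1", "abx_ceftriaxone", 12, 2000, "drug_bolus")
  susp_pre <- detect_suspected_infection(rbind(culture, pre))
  expect_equal(susp_pre$suspected_at, pre$timestamp)
})

sofa_path_table <- function(totals, id = "a1") {
  data.frame(admission_id = id, day_index = seq_along(totals) - 1L,
             respiration = 0L, coagulation = 0L, liver = 0L,
             cardiovascular = 0L, cns = 0L, renal = 0L, total = totals)
}

suspicion_for <- function(id) {
  data.frame(admission_id = id,
             suspected_at = as.POSIXct("2020-01-01 06:00:00", tz = "UTC"))
}

test_that("inclusion, exclusion order and onset follow the operationalized rules", {
  # under-18 excluded even with overt organ dysfunction and infection
  adm <- mk_adm("a1", los_hours = 72, age = 17)
  ep <- identify_sepsis(sofa_path_table(c(10, 10, 10)), suspicion_for("a1"), adm)
  expect_false(ep$included)
  expect_equal(ep$exclusion_reason, "age_lt_18")
  # a 20 h stay is excluded
  adm2 <- mk_adm("a1", los_hours = 20)
  ep2 <- identify_sepsis(sofa_path_table(10), suspicion_for("a1"), adm2)
  expect_equal(ep2$exclusion_reason, "los_lt_24h")
  # SOFA path 1,1,3 with suspicion: rise of 2 over the running minimum on day 2
  adm3 <- mk_adm("a1", los_hours = 72)
  ep3 <- identify_sepsis(sofa_path_table(c(1, 1, 3)), suspicion_for("a1"), adm3)
  expect_true(ep3$included)
  expect_equal(ep3$onset_day, 2L)
  # SOFA >= 2 at admission: onset day 0
  ep4 <- identify_sepsis(sofa_path_table(c(2, 1, 1)), suspicion_for("a1"), adm3)
  expect_equal(ep4$onset_day, 0L)
  # no suspicion -> no sepsis, whatever the SOFA
  ep5 <- identify_sepsis(sofa_path_table(c(5, 9, 9)),
                         suspicion_for("zzz")[0, ], adm3)
  expect_equal(ep5$exclusion_reason, "no_sepsis")
  # a dip then partial recovery: 4,1,2 rises 1 over the minimum -> no onset
  ep6 <- identify_sepsis(sofa_path_table(c(4, 1, 2)), suspicion_for("a1"),
                         mk_adm("a1", los_hours = 72, age = 50))
  expect_equal(ep6$onset_day, 0L)  # qualifies at admission already
  ep7 <- identify_sepsis(sofa_path_table(c(1, 0, 1)), suspicion_for("a1"), adm3)
  expect_equal(ep7$exclusion_reason, "no_sepsis")
})

test_that("unknown admission ids in the SOFA table are an error", {
  adm <- mk_adm("a1")
  expect_error(identify_sepsis(sofa_path_table(c(3), id = "ghost"),
                               suspicion_for("ghost"), adm), "absent")
})

test_that("septic shock needs both a vasopressor and lactate above 2 mmol/L", {
  adm <- mk_adm("a1", los_hours = 48)
  ep <- identify_sepsis(sofa_path_table(c(4, 4)), suspicion_for("a1"), adm)
  vaso <- mk_events("a1", "norepinephrine", 3, 0.1, "drug_rate")
  lac_lo <- mk_events("a1", "lactate", 4, 1.8)
  lac_hi <- mk_events("a1", "lactate", 4, 2.5)
  expect_false(flag_septic_shock(ep, rbind(vaso, lac_lo))$septic_shock)
  expect_true(flag_septic_shock(ep, rbind(vaso, lac_hi))$septic_shock)
  expect_false(flag_septic_shock(ep, mk_events("a1", "lactate", 4, 5))$septic_shock)
})

test_that("adding a vasopressor event never revokes septic shock", {
  adm <- mk_adm("a1", los_hours = 48)
  ep <- identify_sepsis(sofa_path_table(c(4, 4)), suspicion_for("a1"), adm)
  base <- rbind(mk_events("a1", "norepinephrine", 3, 0.1, "drug_rate"),
                mk_events("a1", "lactate", 4, 2.5))
  was <- flag_septic_shock(ep, base)$septic_shock
  for (extra_dose in c(0.01, 0.5, 5)) {
    more <- rbind(base, mk_events("a1", "dopamine", 10, extra_dose, "drug_rate"))
    expect_true(flag_septic_shock(ep, more)$septic_shock >= was)
  }
})

test_that("cohort extraction recovers the generator's ground-truth septic labels", {
  co <- small_cohort()
  sofa <- suppressWarnings(compute_sofa_daily(co$events, co$admissions))
  susp <- detect_suspected_infection(co$events)
  ep <- identify_sepsis(sofa, susp, co$admissions)
  truth <- unique(co$ground_truth[, c("admission_id", "true_septic")])
  los_h <- as.numeric(difftime(co$admissions$discharged_at,
                               co$admissions$admitted_at, units = "hours"))
  eligible <- co$admissions$admission_id[co$admissions$age_years >= 18 &
                                         los_h >= 24]
  m <- merge(ep, truth, by = "admission_id")
  m <- m[m$admission_id %in% eligible, ]
  sens <- mean(m$included[m$true_septic])
  spec <- mean(!m$included[!m$true_septic])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("every included episode has at least one full 24 h window", {
  co <- small_cohort()
  sofa <- suppressWarnings(compute_sofa_daily(co$events, co$admissions))
  ep <- identify_sepsis(sofa, detect_suspected_infection(co$events),
                        co$admissions)
  los_h <- as.numeric(difftime(co$admissions$discharged_at,
                               co$admissions$admitted_at, units = "hours"))
  names(los_h) <- co$admissions$admission_id
  expect_true(all(los_h[ep$admission_id[ep$included]] >= 24))
})

test_that("the cohort summary recomputes percentages from counts", {
  co <- small_cohort()
  sofa <- suppressWarnings(compute_sofa_daily(co$events, co$admissions))
  ep <- identify_sepsis(sofa, detect_suspected_infection(co$events),
                        co$admissions)
  ep <- flag_septic_shock(ep, co$events)
  tab <- summarize_cohort(co$admissions, ep, sofa)
  expect_equal(tab$total$n, tab$survivors$n + tab$non_survivors$n)
  expect_equal(tab$total$male_pct,
               round(100 * tab$total$male / tab$total$n, 1))
  expect_equal(sum(unlist(tab$total$age_bands)), tab$total$n)
  expect_equal(tab$septic_shock$n,
               tab$septic_shock$survivors + tab$septic_shock$non_survivors)
})
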