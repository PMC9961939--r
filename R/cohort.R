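# Sepsis-3 cohort extraction: daily SOFA scoring, suspected-infection
# detection, inclusion/exclusion rules, onset, and septic-shock flagging.

#' Daily SOFA scores from raw events
#'
#' Scores each consecutive 24 h window from ICU admission with the six SOFA
#' organ subscores, using the worst (most abnormal) value of each input
#' within the window. Missing inputs score 0 for that subscore, so no
#' pre-admission baseline is assumed.
#'
#' @param events event table (`admission_id`, `variable_name`, `timestamp`,
#'   `numeric_value`, `variable_class`)
#' @param admissions admission table with `admission_id`, `admitted_at`,
#'   `discharged_at`
#' @return `data.table` with one row per admission-day: the six subscores and
#'   their `total`
#' @export
compute_sofa_daily <- function(events, admissions) {
  adm <- data.table::as.data.table(admissions)
  ev <- data.table::as.data.table(events)
  adm[, n_days := pmax(1L, as.integer(ceiling(
    as.numeric(difftime(discharged_at, admitted_at, units = "hours")) / 24)))]
  grid <- adm[, .(day_index = seq_len(n_days) - 1L), by = admission_id]
  if (nrow(ev)) {
    ev <- merge(ev, adm[, .(admission_id, admitted_at)], by = "admission_id")
    ev[, day_index := as.integer(floor(as.numeric(
      difftime(timestamp, admitted_at, units = "hours")) / 24))]
    worst <- function(var, fn) {
      sub <- ev[variable_name == var]
      x <- if (nrow(sub)) sub[, .(value = fn(numeric_value)),
                              by = .(admission_id, day_index)]
           else data.table::data.table(admission_id = character(),
                                       day_index = integer(),
                                       value = numeric())
      data.table::setnames(x, "value", var)
    }
    pieces <- list(
      worst("pf_ratio", min), worst("platelets", min), worst("bilirubin", max),
      worst("map", min), worst("gcs", min), worst("creatinine", max),
      worst("ventilated", max),
      worst("norepinephrine", max), worst("epinephrine", max),
      worst("dopamine", max), worst("dobutamine", max),
      {
        u <- ev[variable_name == "urine_output",
                .(urine_output = sum(numeric_value)), by = .(admission_id, day_index)]
        u
      })
    for (p in pieces) grid <- merge(grid, p, by = c("admission_id", "day_index"),
                                    all.x = TRUE)
  }
  for (col in c("pf_ratio", "platelets", "bilirubin", "map", "gcs", "creatinine",
                "ventilated", "norepinephrine", "epinephrine", "dopamine",
                "dobutamine", "urine_output"))
    if (!col %in% names(grid)) grid[, (col) := NA_real_]
  no_events <- setdiff(adm$admission_id, unique(ev$admission_id))
  if (length(no_events))
    warnf("%d admission(s) have no events; their SOFA days score 0",
          length(no_events))
  grid[, respiration := sofa_respiration(pf_ratio, ventilated)]
  grid[, coagulation := sofa_coagulation(platelets)]
  grid[, liver := sofa_liver(bilirubin)]
  grid[, cardiovascular := sofa_cardio(map, norepinephrine, epinephrine,
                                       dopamine, dobutamine)]
  grid[, cns := sofa_cns(gcs)]
  grid[, renal := sofa_renal(creatinine, urine_output)]
  grid[, total := respiration + coagulation + liver + cardiovascular + cns + renal]
  data.table::setorder(grid, admission_id, day_index)
  grid[, .(admission_id, day_index, respiration, coagulation, liver,
           cardiovascular, cns, renal, total)]
}

#' Detect suspected infection
#'
#' Flags suspected infection where a culture sample and an antibiotic
#' administration pair up in time: antibiotics given from `window_before_h`
#' hours before to `window_after_h` hours after a culture. The suspicion time
#' is the earlier event of the pair.
#'
#' @param events event table; cultures have `variable_class == "culture"`,
#'   antibiotics are `drug_bolus` events whose name starts with `abx_`
#' @param window_before_h,window_after_h pairing window around the culture
#' @return `data.table` (`admission_id`, `suspected_at`); empty if no pairs
#' @export
detect_suspected_infection <- function(events, window_before_h = 24,
                                       window_after_h = 72) {
  ev <- data.table::as.data.table(events)
  cultures <- ev[variable_class == "culture",
                 .(admission_id, culture_t = timestamp)]
  abx <- ev[startsWith(variable_name, antibiotic_prefix()),
            .(admission_id, abx_t = timestamp)]
  if (!nrow(cultures) || !nrow(abx))
    return(data.table::data.table(admission_id = character(),
                                  suspected_at = as.POSIXct(character(), tz = "UTC")))
  pairs <- merge(cultures, abx, by = "admission_id", allow.cartesian = TRUE)
  pairs <- pairs[abx_t >= culture_t - window_before_h * 3600 &
                 abx_t <= culture_t + window_after_h * 3600]
  if (!nrow(pairs))
    return(data.table::data.table(admission_id = character(),
                                  suspected_at = as.POSIXct(character(), tz = "UTC")))
  pairs[, suspected_at := pmin(culture_t, abx_t)]
  out <- pairs[, .(suspected_at = min(suspected_at)), by = admission_id]
  data.table::setorder(out, admission_id)
  out[]
}

#' Identify septic episodes (operationalized Sepsis-3)
#'
#' An admission is included iff suspected infection is present and either the
#' day-0 SOFA total is at least 2 or the total rises by at least 2 points
#' above its running minimum on some later day; the patient must be an adult
#' and stay at least 24 h. Onset is the first day the qualifying SOFA
#' condition holds; the episode then runs until ICU discharge or death.
#' Exclusion reasons are assessed in the order age, length of stay, sepsis.
#'
#' @param sofa daily SOFA table from [compute_sofa_daily()]
#' @param suspicions output of [detect_suspected_infection()]
#' @param admissions admission table with `age_years`, `admitted_at`,
#'   `discharged_at`
#' @return `data.table` (`admission_id`, `onset_day`, `included`,
#'   `exclusion_reason`, `septic_shock` placeholder `NA`)
#' @export
identify_sepsis <- function(sofa, suspicions, admissions) {
  adm <- data.table::as.data.table(admissions)
  sofa <- data.table::as.data.table(sofa)
  if (length(setdiff(unique(sofa$admission_id), adm$admission_id)))
    stopf("SOFA table contains admission ids absent from the admission table")
  onset <- sofa[order(admission_id, day_index), {
    q0 <- total[1] >= 2
    onset <- if (q0) 0L else {
      rise <- if (.N > 1)
        vapply(2:.N, function(d) total[d] - min(total[1:(d - 1)]) >= 2, logical(1))
      else logical(0)
      if (any(rise)) which(rise)[1] else NA_integer_
    }
    .(onset_day = onset)
  }, by = admission_id]
  out <- merge(adm[, .(admission_id, age_years, admitted_at, discharged_at)],
               onset, by = "admission_id", all.x = TRUE)
  out[, suspected := admission_id %in% suspicions$admission_id]
  out[, los_hours := as.numeric(difftime(discharged_at, admitted_at,
                                         units = "hours"))]
  out[, exclusion_reason := data.table::fifelse(age_years < 18, "age_lt_18",
                            data.table::fifelse(los_hours < 24, "los_lt_24h",
                            data.table::fifelse(!suspected | is.na(onset_day),
                                                "no_sepsis", "none")))]
  out[, included := exclusion_reason == "none"]
  out[, onset_day := data.table::fifelse(included, onset_day, NA_integer_)]
  out[, septic_shock := NA]
  data.table::setorder(out, admission_id)
  out[, .(admission_id, onset_day, included, exclusion_reason, septic_shock)]
}

#' Flag septic shock
#'
#' An included episode meets the (operationalized) septic-shock criterion iff
#' any vasopressor was administered and any lactate value exceeded 2 mmol/L
#' during the ICU stay.
#'
#' @param episodes output of [identify_sepsis()]
#' @param events event table
#' @return the episode table with `septic_shock` filled for included episodes
#' @export
flag_septic_shock <- function(episodes, events) {
  ev <- data.table::as.data.table(events)
  ep <- data.table::copy(data.table::as.data.table(episodes))
  vaso <- unique(ev[variable_name %in% vasopressor_variables() &
                    numeric_value > 0, admission_id])
  hilac <- unique(ev[variable_name == "lactate" & numeric_value > 2, admission_id])
  ep[, septic_shock := data.table::fifelse(
        included, admission_id %in% vaso & admission_id %in% hilac, NA)]
  ep[]
}

#' Cohort summary table
#'
#' Counts and percentages in the layout of a clinical baseline table:
#' admissions by survival status, sex, age bands, highest and onset SOFA
#' medians (IQR), and septic shock.
#'
#' @param admissions admission table (with `died_in_icu`, `sex`, `age_years`)
#' @param episodes episode table; only included episodes are summarized
#' @param sofa daily SOFA table
#' @return nested list of counts, percentages and medians
#' @export
summarize_cohort <- function(admissions, episodes, sofa) {
  adm <- data.table::as.data.table(admissions)
  ep <- data.table::as.data.table(episodes)[included == TRUE]
  adm <- adm[admission_id %in% ep$admission_id]
  sofa <- data.table::as.data.table(sofa)[admission_id %in% ep$admission_id]
  n <- nrow(adm)
  surv <- adm[died_in_icu == FALSE]
  nonsurv <- adm[died_in_icu == TRUE]
  bands <- c(18, 40, 50, 60, 70, 80, Inf)
  band_lab <- c("18-39", "40-49", "50-59", "60-69", "70-79", ">80")
  count_block <- function(a) {
    nb <- as.integer(table(cut(a$age_years, bands, right = FALSE,
                               labels = band_lab)))
    list(n = nrow(a),
         male = sum(a$sex == "M"),
         male_pct = fmt_pct(sum(a$sex == "M"), max(nrow(a), 1L)),
         age_bands = stats::setNames(as.list(nb), band_lab))
  }
  onset <- merge(sofa, ep[, .(admission_id, onset_day)], by = "admission_id")
  sofa_stats <- function(ids) {
    s <- onset[admission_id %in% ids]
    if (!nrow(s)) return(list(highest_median = NA, onset_median = NA))
    hi <- s[, .(v = max(total)), by = admission_id]$v
    at <- s[day_index == onset_day]$total
    list(highest_median = stats::median(hi), highest_iqr = stats::IQR(hi),
         onset_median = stats::median(at), onset_iqr = stats::IQR(at))
  }
  shock_ids <- ep[septic_shock == TRUE, admission_id]
  list(total = count_block(adm), survivors = count_block(surv),
       non_survivors = count_block(nonsurv),
       sofa_total = sofa_stats(adm$admission_id),
       sofa_survivors = sofa_stats(surv$admission_id),
       sofa_non_survivors = sofa_stats(nonsurv$admission_id),
       septic_shock = list(
         n = length(shock_ids),
         pct = fmt_pct(length(shock_ids), max(n, 1L)),
         survivors = sum(shock_ids %in% surv$admission_id),
         survivors_pct = fmt_pct(sum(shock_ids %in% surv$admission_id),
                                 max(nrow(surv), 1L)),
         non_survivors = sum(shock_ids %in% nonsurv$admission_id),
         non_survivors_pct = fmt_pct(sum(shock_ids %in% nonsurv$admission_id),
                                     max(nrow(nonsurv), 1L))))
}
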