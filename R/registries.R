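# Clinical registries: glucocorticoid potency factors, the SOFA scoring grid,
# and the per-variable feature specification used for daily aggregation.

#' Glucocorticoid potency registry
#'
#' Relative glucocorticoid potencies used to convert a dose of a systemic
#' corticosteroid into its hydrocortisone-equivalent dose (mg equivalent per
#' mg administered). Defaults follow the standard equivalence table
#' (hydrocortisone 20 mg = cortisone 25 mg = prednis(ol)one 5 mg =
#' methylprednisolone 4 mg = dexamethasone 0.75 mg).
#'
#' @return named numeric vector of potency factors
#' @export
steroid_potency <- function() {
  c(hydrocortisone     = 1,
    cortisone          = 0.8,
    prednisolone       = 4,
    prednisone         = 4,
    methylprednisolone = 5,
    dexamethasone      = 26.7)
}

# ---- SOFA subscores -------------------------------------------------------
# Standard Sepsis-3 SOFA thresholds, encoded once. All functions are
# vectorized and treat a missing input as "normal" (subscore 0), so absent
# measurements never raise the score.

sofa_respiration <- function(pf_ratio, ventilated) {
  pf <- ifelse(is.na(pf_ratio), Inf, pf_ratio)
  v  <- !is.na(ventilated) & ventilated > 0
  ifelse(pf < 100 & v, 4L,
  ifelse(pf < 200 & v, 3L,
  ifelse(pf < 300, 2L,
  ifelse(pf < 400, 1L, 0L))))
}

sofa_coagulation <- function(platelets) {
  p <- ifelse(is.na(platelets), Inf, platelets)
  ifelse(p < 20, 4L, ifelse(p < 50, 3L, ifelse(p < 100, 2L, ifelse(p < 150, 1L, 0L))))
}

sofa_liver <- function(bilirubin) {
  b <- ifelse(is.na(bilirubin), -Inf, bilirubin)
  ifelse(b >= 12, 4L, ifelse(b >= 6, 3L, ifelse(b >= 2, 2L, ifelse(b >= 1.2, 1L, 0L))))
}

sofa_cardio <- function(map, norepinephrine = NA_real_, epinephrine = NA_real_,
                        dopamine = NA_real_, dobutamine = NA_real_) {
  z <- function(x) ifelse(is.na(x), 0, x)
  ne <- z(norepinephrine); ep <- z(epinephrine); da <- z(dopamine); db <- z(dobutamine)
  m  <- ifelse(is.na(map), Inf, map)
  ifelse(da > 15 | ep > 0.1 | ne > 0.1, 4L,
  ifelse(da > 5 | (ep > 0 & ep <= 0.1) | (ne > 0 & ne <= 0.1), 3L,
  ifelse((da > 0 & da <= 5) | db > 0, 2L,
  ifelse(m < 70, 1L, 0L))))
}

sofa_cns <- function(gcs) {
  g <- ifelse(is.na(gcs), 15, gcs)
  ifelse(g < 6, 4L, ifelse(g <= 9, 3L, ifelse(g <= 12, 2L, ifelse(g <= 14, 1L, 0L))))
}

sofa_renal <- function(creatinine, urine_output = NA_real_) {
  cr <- ifelse(is.na(creatinine), -Inf, creatinine)
  uo <- ifelse(is.na(urine_output), Inf, urine_output)
  ifelse(cr >= 5 | uo < 200, 4L,
  ifelse(cr >= 3.5 | uo < 500, 3L,
  ifelse(cr >= 2, 2L,
  ifelse(cr >= 1.2, 1L, 0L))))
}

# Variable-name registries used to route raw events to SOFA inputs.
vasopressor_variables <- function() c("norepinephrine", "epinephrine", "dopamine", "dobutamine")
antibiotic_prefix <- function() "abx_"

# ---- Feature specification ------------------------------------------------

#' Default per-variable feature specification
#'
#' Maps each raw variable to its daily aggregation set and imputation rule:
#' measurement-class variables (vitals, laboratory values, ventilation) get
#' within-day summary statistics and forward-fill imputation; drug-class
#' variables get the 24 h cumulative sum and zero-fill. Corticosteroid
#' compounds are excluded: they define the action, not the state.
#'
#' @param variables character vector of variable names
#' @param classes matching vector of variable classes
#'   (`vital`, `lab`, `drug_rate`, `drug_bolus`, `culture`, `ventilation`)
#' @return a `data.table` with columns `variable_name`, `variable_class`,
#'   `aggregations` (comma-separated), `impute_rule`
#' @export
default_feature_spec <- function(variables, classes) {
  stopifnot(length(variables) == length(classes))
  dt <- data.table::data.table(variable_name = variables, variable_class = classes)
  dt <- unique(dt)
  dt <- dt[!(variable_name %in% names(steroid_potency()))]
  dt <- dt[variable_class != "culture"]
  dt[, aggregations := data.table::fifelse(
        variable_class %in% c("vital", "lab"), "mean,max,min,sd",
        data.table::fifelse(variable_class == "ventilation", "max", "sum"))]
  dt[, impute_rule := data.table::fifelse(
        variable_class %in% c("drug_rate", "drug_bolus"), "zero_fill", "forward_fill")]
  dt[]
}
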