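# Daily state-matrix construction: 24 h binning and aggregation, coverage
# filtering, imputation, and min-max normalization to [-1, 1]. All fitting
# (coverage, medians, bounds) uses the training split only; validation and
# test data are transformed with the frozen fit.

#' Bin events into daily aggregates
#'
#' Aggregates each variable over consecutive 24 h windows counted from sepsis
#' onset (day 0 = onset day). Measurement-class variables get within-day
#' mean, max, min and population sd (sd of a single observation is 0);
#' drug-class variables get the 24 h cumulative sum; the ventilation flag its
#' daily max. Days with no observation of a variable are missing.
#'
#' @param events event table
#' @param episodes episode table from [identify_sepsis()]; only included
#'   episodes are binned
#' @param admissions admission table (`admitted_at`, `discharged_at`)
#' @param spec feature specification ([default_feature_spec()]); derived from
#'   the events when `NULL`
#' @return list: `table` (wide `data.table`, one row per admission-day,
#'   feature columns named `variable__stat`), `spec`, `feature_cols`
#' @export
bin_and_aggregate <- function(events, episodes, admissions, spec = NULL) {
  ev <- data.table::as.data.table(events)
  ep <- data.table::as.data.table(episodes)[included == TRUE]
  adm <- data.table::as.data.table(admissions)
  if (is.null(spec))
    spec <- default_feature_spec(ev$variable_name, ev$variable_class)
  ev <- merge(ev, adm[, .(admission_id, admitted_at)], by = "admission_id")
  ev <- merge(ev, ep[, .(admission_id, onset_day)], by = "admission_id")
  ev[, day_index := as.integer(floor(as.numeric(
    difftime(timestamp, admitted_at, units = "hours")) / 24)) - onset_day]
  ev <- ev[day_index >= 0]
  ev <- ev[variable_name %in% spec$variable_name]
  # full day grid per episode: onset through last ICU day
  adm[, n_days := pmax(1L, as.integer(ceiling(as.numeric(
    difftime(discharged_at, admitted_at, units = "hours")) / 24)))]
  grid <- merge(ep[, .(admission_id, onset_day)],
                adm[, .(admission_id, n_days)], by = "admission_id")
  grid <- grid[, .(day_index = seq_len(max(n_days - onset_day, 1L)) - 1L),
               by = admission_id]
  stopifnot(!anyDuplicated(grid, by = c("admission_id", "day_index")))
  long <- merge(ev, spec[, .(variable_name, aggregations)], by = "variable_name")
  agg_one <- function(stat) {
    fn <- switch(stat, mean = mean, max = max, min = min, sd = sd_pop,
                 sum = sum)
    x <- long[grepl(stat, aggregations, fixed = TRUE),
              .(value = fn(numeric_value)),
              by = .(admission_id, day_index, variable_name)]
    if (!nrow(x)) return(NULL)
    x[, col := paste0(variable_name, "__", stat)]
    x[, .(admission_id, day_index, col, value)]
  }
  cells <- data.table::rbindlist(
    Filter(Negate(is.null), lapply(c("mean", "max", "min", "sd", "sum"), agg_one)))
  feature_cols <- sort(unlist(lapply(seq_len(nrow(spec)), function(i)
    paste0(spec$variable_name[i], "__",
           strsplit(spec$aggregations[i], ",")[[1]]))))
  wide <- if (nrow(cells)) {
    data.table::dcast(cells, admission_id + day_index ~ col,
                      value.var = "value")
  } else grid[0]
  out <- merge(grid, wide, by = c("admission_id", "day_index"), all.x = TRUE)
  for (col in setdiff(feature_cols, names(out))) out[, (col) := NA_real_]
  data.table::setcolorder(out, c("admission_id", "day_index", feature_cols))
  data.table::setorder(out, admission_id, day_index)
  list(table = out[], spec = spec, feature_cols = feature_cols)
}

#' Drop sparsely observed variables
#'
#' Removes feature columns whose observed fraction on the *training* rows
#' does not exceed `threshold` (default: variables present in more than 2% of
#' training admission-days are kept).
#'
#' @param table wide daily table from [bin_and_aggregate()]
#' @param train_ids admission ids of the training split; coverage is computed
#'   on these rows only
#' @param threshold coverage fraction in `[0, 1)`
#' @return list: `table` (reduced), `kept`, `dropped`, `coverage` (named
#'   observed fractions)
#' @export
filter_coverage <- function(table, train_ids, threshold = 0.02) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stopf("coverage threshold must lie in [0, 1)")
  dt <- data.table::as.data.table(table)
  cols <- setdiff(names(dt), c("admission_id", "day_index"))
  tr <- dt[admission_id %in% train_ids]
  if (!nrow(tr)) stopf("no training rows found for coverage computation")
  coverage <- vapply(cols, function(cl) mean(!is.na(tr[[cl]])), numeric(1))
  kept <- names(coverage)[coverage > threshold]
  dropped <- setdiff(cols, kept)
  list(table = dt[, c("admission_id", "day_index", kept), with = FALSE],
       kept = kept, dropped = dropped, coverage = coverage)
}

impute_rule_for <- function(cols, spec) {
  base <- sub("__[a-z]+$", "", cols)
  rule <- spec$impute_rule[match(base, spec$variable_name)]
  rule[is.na(rule)] <- "forward_fill"
  stats::setNames(rule, cols)
}

#' Impute missing daily values
#'
#' Measurement columns are forward-filled within each admission (never across
#' admissions); remaining leading gaps are filled with the training-split
#' median of the observed values. Drug columns are zero-filled (no record
#' means no dose).
#'
#' @param table wide daily table (coverage-filtered)
#' @param spec feature specification
#' @param train_ids training-split admission ids (median fitting)
#' @param medians optional pre-fitted medians (reuse at inference); when
#'   supplied, `train_ids` is ignored
#' @return list: `table` (complete), `medians`, `imputed_fraction`,
#'   `observed_mask` (logical matrix, pre-imputation availability)
#' @export
impute_daily <- function(table, spec, train_ids = NULL, medians = NULL) {
  dt <- data.table::copy(data.table::as.data.table(table))
  data.table::setorder(dt, admission_id, day_index)
  cols <- setdiff(names(dt), c("admission_id", "day_index"))
  rules <- impute_rule_for(cols, spec)
  mask <- !is.na(as.matrix(dt[, cols, with = FALSE]))
  colnames(mask) <- cols
  if (is.null(medians)) {
    if (is.null(train_ids)) stopf("either train_ids or medians must be given")
    tr <- dt[admission_id %in% train_ids]
    medians <- vapply(cols, function(cl) {
      v <- tr[[cl]][!is.na(tr[[cl]])]
      if (length(v)) stats::median(v) else 0
    }, numeric(1))
  }
  n_missing <- sum(!mask)
  for (cl in cols) {
    if (rules[[cl]] == "zero_fill") {
      data.table::set(dt, which(is.na(dt[[cl]])), cl, 0)
    } else {
      dt[, (cl) := data.table::nafill(get(cl), type = "locf"),
         by = admission_id]
      data.table::set(dt, which(is.na(dt[[cl]])), cl, medians[[cl]])
    }
  }
  list(table = dt[], medians = medians,
       imputed_fraction = n_missing / max(length(mask), 1L),
       observed_mask = mask)
}

#' Normalize daily features to [-1, 1]
#'
#' Min-max rescaling `x -> 2 (x - low) / (high - low) - 1` with bounds fitted
#' on the training split; out-of-range validation/test values are clipped to
#' the interval, and constant training variables map to 0.
#'
#' @param table complete (imputed) wide daily table
#' @param train_ids training-split admission ids (bound fitting)
#' @param bounds optional pre-fitted bounds list (`low`, `high`) for reuse
#' @return list: `table` (normalized), `bounds`
#' @export
normalize_daily <- function(table, train_ids = NULL, bounds = NULL) {
  dt <- data.table::copy(data.table::as.data.table(table))
  cols <- setdiff(names(dt), c("admission_id", "day_index"))
  if (is.null(bounds)) {
    if (is.null(train_ids)) stopf("either train_ids or bounds must be given")
    tr <- dt[admission_id %in% train_ids]
    bounds <- list(low = vapply(cols, function(cl) min(tr[[cl]]), numeric(1)),
                   high = vapply(cols, function(cl) max(tr[[cl]]), numeric(1)))
  }
  for (cl in cols) {
    lo <- bounds$low[[cl]]; hi <- bounds$high[[cl]]
    v <- if (hi > lo) clip(2 * (dt[[cl]] - lo) / (hi - lo) - 1, -1, 1)
         else rep(0, nrow(dt))
    data.table::set(dt, j = cl, value = v)
  }
  list(table = dt[], bounds = bounds)
}

#' Invert the normalization for in-range values
#' @param x normalized values
#' @param low,high fitted bounds of the variable
#' @return values on the original scale
#' @export
denormalize <- function(x, low, high) low + (x + 1) * (high - low) / 2

#' Build daily state vectors end to end
#'
#' Chains [bin_and_aggregate()], [filter_coverage()], [impute_daily()] and
#' [normalize_daily()] with a leakage-free fit: every fitted quantity
#' (coverage decisions, imputation medians, normalization bounds) is computed
#' on the training split and frozen into the returned `fit` object, which can
#' be passed back in to transform new data identically.
#'
#' @param events,episodes,admissions as in [bin_and_aggregate()]
#' @param train_ids training-split admission ids
#' @param coverage_threshold see [filter_coverage()]
#' @param fit optional frozen fit from a previous call
#' @return list: `states` (normalized wide table), `observed_mask`,
#'   `feature_names`, `imputed_fraction`, `fit`
#' @export
build_daily_states <- function(events, episodes, admissions, train_ids,
                               coverage_threshold = 0.02, fit = NULL) {
  raw <- bin_and_aggregate(events, episodes, admissions,
                           spec = fit$spec %||% NULL)
  if (is.null(fit)) {
    cov <- filter_coverage(raw$table, train_ids, coverage_threshold)
    imp <- impute_daily(cov$table, raw$spec, train_ids = train_ids)
    nrm <- normalize_daily(imp$table, train_ids = train_ids)
    fit <- list(spec = raw$spec, kept = cov$kept, dropped = cov$dropped,
                coverage = cov$coverage, medians = imp$medians,
                bounds = nrm$bounds)
  } else {
    tab <- raw$table[, c("admission_id", "day_index", fit$kept), with = FALSE]
    imp <- impute_daily(tab, fit$spec, medians = fit$medians)
    nrm <- normalize_daily(imp$table, bounds = fit$bounds)
  }
  list(states = nrm$table, observed_mask = imp$observed_mask,
       feature_names = fit$kept, imputed_fraction = imp$imputed_fraction,
       fit = fit)
}

#' Serialize a feature fit to JSON
#' @param fit fit object from [build_daily_states()]
#' @param path output path (`feature_spec.json`)
#' @return invisibly, `path`
#' @export
write_feature_fit <- function(fit, path) {
  out <- list(spec = fit$spec, kept = fit$kept, dropped = fit$dropped,
              coverage = as.list(fit$coverage),
              medians = as.list(fit$medians),
              bounds = list(low = as.list(fit$bounds$low),
                            high = as.list(fit$bounds$high)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
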