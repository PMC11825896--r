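# Cohort construction: inclusion/exclusion filtering, windowed outcome
# indicators, median/mode imputation, and standardization of continuous
# variables.

default_filter_thresholds <- function() {
  list(esi_levels = c(2L, 3L), tail_days = 45, troponin_max = 0.10,
       systolic_bp_min = 80, respiration_rate_max = 30,
       pulse_oximetry_min = 88, heart_rate_max = 120,
       cellulitis_temp_max = 100.3)
}

#' Apply the cohort definition filters
#'
#' Retains visits that satisfy all of: a recorded disposition of admission
#' or discharge to residence/SNF/IRF (eloped, against-medical-advice and
#' transfers excluded); ESI acuity 2 or 3; a visit date at least 45 days
#' before the end of the sample period (adequate outcome follow-up);
#' troponin absent or <= 0.10 ng/mL; no recorded severe vital-sign
#' abnormality (systolic BP < 80 mmHg, respiration rate > 30/min, pulse
#' oximetry < 88%, heart rate > 120/min each exclude — all cutoffs strict);
#' no stroke / myocardial infarction / femur-fracture flag; and not a
#' cellulitis presentation with temperature above 100.3 F.
#'
#' A missing screening vital is treated as "no recorded abnormality" and
#' does not exclude. Each excluded visit is counted once, under the first
#' failing rule in the fixed order: disposition, acuity, 45-day tail,
#' troponin, vitals, diagnosis flags, cellulitis/fever. Discharges to SNF or
#' IRF are mapped to `decision = "discharge"` in the returned table.
#'
#' @param data Visit table (see [generate_cohort()] for the column layout).
#' @param sample_end_date End of the sample period (`Date` or string).
#' @param thresholds Optional list overriding the default cutoffs.
#' @return A list with `data` (retained rows) and `report`
#'   (class `ed_filter_report`: `n_input`, `n_retained`, per-rule exclusion
#'   counts, retained visit ids).
#' @export
apply_cohort_filters <- function(data, sample_end_date,
                                 thresholds = default_filter_thresholds()) {
  if (any(is.na(data$visit_date))) stop("visit_date must not be missing")
  sample_end_date <- as.Date(sample_end_date)
  th <- modifyList(default_filter_thresholds(), thresholds)
  n <- nrow(data)
  ok_dest <- c("hospital", "home", "snf", "irf")

  fail <- list(
    disposition = is.na(data$decision) |
      !(data$disposition_destination %in% ok_dest),
    acuity = is.na(data$acuity) | !(data$acuity %in% th$esi_levels),
    tail_45d = as.Date(data$visit_date) > sample_end_date - th$tail_days,
    troponin = !is.na(data$troponin) & data$troponin > th$troponin_max,
    vitals = (!is.na(data$systolic_bp) &
                data$systolic_bp < th$systolic_bp_min) |
      (!is.na(data$respiration_rate) &
         data$respiration_rate > th$respiration_rate_max) |
      (!is.na(data$pulse_oximetry) &
         data$pulse_oximetry < th$pulse_oximetry_min) |
      (!is.na(data$heart_rate) & data$heart_rate > th$heart_rate_max),
    diagnosis_flags = isTRUE_vec(data$flag_stroke) |
      isTRUE_vec(data$flag_mi) | isTRUE_vec(data$flag_femur_fracture),
    cellulitis_fever = data$presentation == "cellulitis" &
      !is.na(data$temperature) & data$temperature > th$cellulitis_temp_max)

  first_fail <- rep(NA_character_, n)
  for (rule in names(fail)) {
    hit <- is.na(first_fail) & fail[[rule]]
    first_fail[hit] <- rule
  }
  keep <- is.na(first_fail)
  out <- data[keep, , drop = FALSE]
  out$decision[out$disposition_destination %in% c("snf", "irf")] <- "discharge"

  report <- structure(
    list(n_input = n, n_retained = sum(keep),
         exclusions = vapply(names(fail),
                             function(r) sum(first_fail == r, na.rm = TRUE),
                             integer(1)),
         retained_ids = out$visit_id),
    class = "ed_filter_report")
  list(data = out, report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.ed_filter_report <- function(x, ...) {
  cat("Cohort filter report:", x$n_input, "visits in,", x$n_retained,
      "retained\n")
  for (r in names(x$exclusions))
    cat(sprintf("  excluded by %-17s %d\n", paste0(r, ":"),
                x$exclusions[[r]]))
  invisible(x)
}

#' Derive the nine windowed outcome indicators
#'
#' For each outcome family (revisit, readmission, mortality) and window (3,
#' 9, 30 days), the indicator is 1 iff the event offset is present and at
#' most the window length (boundary inclusive). Event offsets are measured
#' from final discharge (hospital discharge for admitted visits, ED
#' discharge otherwise); an absent event gives 0 in every window.
#'
#' @param data Table with `revisit_days`, `readmission_days`,
#'   `mortality_days` columns (`NA` = no event).
#' @param windows Window lengths in days.
#' @return A data.frame of binary columns `y_<family>_<window>`.
#' @export
derive_outcome_matrix <- function(data, windows = ed_windows) {
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (fam in ed_outcome_families) {
    d <- data[[paste0(fam, "_days")]]
    if (any(!is.na(d) & d < 0)) stop("negative event offset for ", fam)
    for (w in windows)
      out[[paste0("y_", fam, "_", w)]] <- as.integer(!is.na(d) & d <= w)
  }
  out
}

ed_impute_continuous <- c("age", "hcc", "temperature", "blood_pressure",
                          "respiration_rate", "heart_rate")
ed_impute_categorical <- c("female", "insurance", "diabetes", "chf",
                           "hypertension", "acuity")

#' Median / mode imputation of missing analysis variables
#'
#' Continuous variables are filled with the median of their observed values;
#' categorical (including binary) variables with the most frequent observed
#' category, ties broken by lexicographically smallest. Observed values are
#' never altered.
#'
#' @param data Visit table.
#' @param continuous,categorical Column names to impute.
#' @return A list with `data` and `log` (per-column fill value and count).
#' @export
impute_missing <- function(data, continuous = ed_impute_continuous,
                           categorical = ed_impute_categorical) {
  log <- list()
  for (nm in intersect(continuous, names(data))) {
    miss <- is.na(data[[nm]])
    if (all(miss)) stop("column ", nm, " is entirely missing")
    if (!any(miss)) next
    fill <- median(data[[nm]][!miss])
    data[[nm]][miss] <- fill
    log[[nm]] <- list(fill = fill, n_filled = sum(miss))
  }
  for (nm in intersect(categorical, names(data))) {
    miss <- is.na(data[[nm]])
    if (all(miss)) stop("column ", nm, " is entirely missing")
    if (!any(miss)) next
    tab <- table(as.character(data[[nm]][!miss]))
    top <- sort(names(tab)[tab == max(tab)])[1]
    fill <- if (is.numeric(data[[nm]])) as.numeric(top) else
      if (is.integer(data[[nm]])) as.integer(top) else top
    data[[nm]][miss] <- fill
    log[[nm]] <- list(fill = fill, n_filled = sum(miss))
  }
  list(data = data, log = log)
}

ed_standardize_cols <- c("age", "hcc", "temperature", "blood_pressure",
                         "respiration_rate", "heart_rate")

#' Standardize continuous variables
#'
#' Replaces each named column by `(x - mean) / sd` using the post-imputation
#' sample mean and standard deviation (denominator `n - 1`). The returned
#' scaling table supports the inverse transform and application to new data.
#'
#' @param data Imputed visit table.
#' @param columns Columns to standardize.
#' @return List with `data` and `scaling` (data.frame: column, center,
#'   scale).
#' @export
standardize_continuous <- function(data, columns = ed_standardize_cols) {
  columns <- intersect(columns, names(data))
  scaling <- data.frame(column = columns, center = NA_real_,
                        scale = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    x <- data[[columns[i]]]
    if (any(is.na(x))) stop("standardize_continuous expects imputed data (",
                            columns[i], " has missing values)")
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) stop("column ", columns[i],
                                      " has zero standard deviation")
    scaling$center[i] <- m; scaling$scale[i] <- s
    data[[columns[i]]] <- (x - m) / s
  }
  list(data = data, scaling = scaling)
}

#' @rdname standardize_continuous
#' @param scaling A scaling table from [standardize_continuous()].
#' @param inverse Apply the inverse (de-standardizing) transform?
#' @export
apply_scaling <- function(data, scaling, inverse = FALSE) {
  for (i in seq_len(nrow(scaling))) {
    nm <- scaling$column[i]
    if (!nm %in% names(data)) next
    data[[nm]] <- if (inverse)
      data[[nm]] * scaling$scale[i] + scaling$center[i]
    else (data[[nm]] - scaling$center[i]) / scaling$scale[i]
  }
  data
}

#' Encode a model-ready design from a preprocessed cohort
#'
#' Dummy-codes insurance with Medicare as the reference level, encodes
#' acuity as an ESI = 2 indicator, sex as a female indicator, and assembles
#' the fixed-order baseline and proxy matrices, admission indicator,
#' treatment time and the nine outcome indicators used by the latent model.
#'
#' @param data Filtered, imputed, standardized visit table.
#' @return An object of class `ed_design`: list of `baseline` (n x 9
#'   matrix), `proxies` (n x 5 matrix, acuity2 first), `admitted` (0/1),
#'   `time`, `outcomes` (n x 9 binary matrix), `presentation`, `visit_id`.
#' @export
encode_design <- function(data) {
  known_ins <- c("medicare", "medicaid", "commercial", "selfpay")
  if (any(!data$insurance %in% known_ins))
    stop("unknown insurance category: ",
         paste(setdiff(unique(data$insurance), known_ins), collapse = ", "))
  if (any(!data$acuity %in% 1:5)) stop("acuity must be an ESI level 1-5")
  if (any(is.na(data$decision))) stop("decision must not be missing")
  baseline <- cbind(age = data$age,
                    female = as.numeric(data$female),
                    ins_medicaid = as.numeric(data$insurance == "medicaid"),
                    ins_commercial = as.numeric(data$insurance == "commercial"),
                    ins_selfpay = as.numeric(data$insurance == "selfpay"),
                    diabetes = as.numeric(data$diabetes),
                    chf = as.numeric(data$chf),
                    hypertension = as.numeric(data$hypertension),
                    hcc = data$hcc)
  proxies <- cbind(acuity2 = as.numeric(data$acuity == 2),
                   temperature = data$temperature,
                   blood_pressure = data$blood_pressure,
                   respiration_rate = data$respiration_rate,
                   heart_rate = data$heart_rate)
  ycols <- intersect(ed_outcome_cols, names(data))
  outcomes <- if (length(ycols) == length(ed_outcome_cols))
    as.matrix(data[, ed_outcome_cols]) else
      as.matrix(derive_outcome_matrix(data))
  if (any(data$treatment_time <= 0)) stop("treatment_time must be > 0")
  structure(list(baseline = baseline, proxies = proxies,
                 admitted = as.numeric(data$decision == "admit"),
                 time = data$treatment_time, outcomes = outcomes,
                 presentation = data$presentation, visit_id = data$visit_id,
                 n = nrow(data)),
            class = "ed_design")
}

subset_design <- function(design, idx) {
  structure(list(baseline = design$baseline[idx, , drop = FALSE],
                 proxies = design$proxies[idx, , drop = FALSE],
                 admitted = design$admitted[idx], time = design$time[idx],
                 outcomes = design$outcomes[idx, , drop = FALSE],
                 presentation = design$presentation[idx],
                 visit_id = design$visit_id[idx], n = sum(
                   if (is.logical(idx)) idx else length(idx))),
            class = "ed_design")
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: filters, derives outcome indicators, imputes,
#' standardizes and encodes in one call.
#'
#' @inheritParams apply_cohort_filters
#' @return List: `design`, `data` (processed table), `filter_report`,
#'   `imputation_log`, `scaling`.
#' @export
preprocess_cohort <- function(data, sample_end_date,
                              thresholds = default_filter_thresholds()) {
  flt <- apply_cohort_filters(data, sample_end_date, thresholds)
  d <- flt$data
  d <- cbind(d, derive_outcome_matrix(d))
  imp <- impute_missing(d)
  std <- standardize_continuous(imp$data)
  list(design = encode_design(std$data), data = std$data,
       filter_report = flt$report, imputation_log = imp$log,
       scaling = std$scaling)
}
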