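## derived_measures: clinical indices and classification flags.

#' Classification thresholds
#'
#' Defaults: steatosis when liver fat exceeds 5.6% (strict), prediabetes
#' when fasting glucose >= 5.6 mmol/L or HbA1c >= 39 mmol/mol, HOMA-IR
#' denominator 22.5.
#'
#' @param nafld_liver_fat_pct,prediabetes_glucose,prediabetes_hba1c,homa_denominator
#'   strictly positive thresholds.
#' @return list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(nafld_liver_fat_pct = 5.6,
                                      prediabetes_glucose = 5.6,
                                      prediabetes_hba1c = 39,
                                      homa_denominator = 22.5) {
  vals <- c(nafld_liver_fat_pct, prediabetes_glucose, prediabetes_hba1c,
            homa_denominator)
  if (any(vals <= 0)) stop_config("all thresholds must be > 0")
  structure(list(nafld_liver_fat_pct = nafld_liver_fat_pct,
                 prediabetes_glucose = prediabetes_glucose,
                 prediabetes_hba1c = prediabetes_hba1c,
                 homa_denominator = homa_denominator),
            class = "classification_thresholds")
}

#' HOMA-IR insulin-resistance index
#'
#' `insulin * glucose / 22.5` with fasting insulin in mE/L and fasting
#' glucose in mmol/L.
#'
#' @param insulin,glucose non-negative; vectorized.
#' @param denominator HOMA constant.
#' @return dimensionless index.
#' @export
homa_ir <- function(insulin, glucose, denominator = 22.5) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE))
    stop_config("insulin and glucose must be non-negative")
  insulin * glucose / denominator
}

#' FIB-4 liver-fibrosis index
#'
#' `mode = "standard"` is the usual definition
#' `age * ASAT / (platelets * sqrt(ALAT))` with aminotransferases in U/L.
#' `mode = "as_printed"` omits the square root:
#' `age * ASAT / (platelets * ALAT)`, in which case the aminotransferase
#' units cancel. `convert_ukat` multiplies both aminotransferases by 60
#' (1 ukat/L = 60 U/L) before applying the formula.
#'
#' @param age years; `asat`, `alat` aminotransferases; `platelets` 10^9/L.
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @param convert_ukat treat `asat`/`alat` as ukat/L and convert to U/L.
#' @return index value.
#' @export
fib4 <- function(age, asat, alat, platelets,
                 mode = c("standard", "as_printed"), convert_ukat = FALSE) {
  mode <- match.arg(mode)
  if (any(c(age, asat, alat, platelets) <= 0, na.rm = TRUE))
    stop_config("all FIB-4 inputs must be > 0")
  if (convert_ukat) {
    asat <- asat * 60
    alat <- alat * 60
  }
  denom <- switch(mode, standard = platelets * sqrt(alat),
                  as_printed = platelets * alat)
  if (any(denom == 0, na.rm = TRUE)) stop_config("zero denominator in FIB-4")
  age * asat / denom
}

#' Body-mass index
#'
#' @param weight kg; `height` metres (> 0).
#' @return kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(height <= 0, na.rm = TRUE)) stop_config("height must be > 0")
  weight / height^2
}

#' Classify steatosis and prediabetes status
#'
#' Steatosis flag is strict (`liver_fat > threshold`, "exceeding");
#' prediabetes uses `>=` on either glucose or HbA1c.
#'
#' @param liver_fat percent in \[0, 100\]; `glucose` mmol/L; `hba1c`
#'   mmol/mol; all vectorized.
#' @param thresholds a [classification_thresholds()].
#' @return data frame with logical columns `nafld`, `prediabetes`.
#' @export
classify_status <- function(liver_fat, glucose, hba1c,
                            thresholds = classification_thresholds()) {
  if (any(liver_fat < 0 | liver_fat > 100, na.rm = TRUE))
    stop_config("liver fat outside [0, 100]%%")
  if (any(glucose < 0, na.rm = TRUE) || any(hba1c < 0, na.rm = TRUE))
    stop_config("glucose and HbA1c must be non-negative")
  data.frame(
    nafld = liver_fat > thresholds$nafld_liver_fat_pct,
    prediabetes = glucose >= thresholds$prediabetes_glucose |
      hba1c >= thresholds$prediabetes_hba1c)
}

#' Per-arm steatosis remission rates
#'
#' Remission = flagged at baseline and not flagged at month 12, among
#' subjects flagged at baseline with complete data at both visits.
#'
#' @param table trial table with `liver_fat_m0` / `liver_fat_m12`.
#' @param thresholds a [classification_thresholds()].
#' @return data frame with one row per arm: `arm`, `n_baseline` (flagged
#'   completers), `n_remit`, `rate_percent` (NA when the denominator is 0).
#' @export
remission_rates <- function(table, thresholds = classification_thresholds()) {
  assert_cols(table, c("arm", "liver_fat_m0", "liver_fat_m12"))
  thr <- thresholds$nafld_liver_fat_pct
  complete <- !is.na(table$liver_fat_m0) & !is.na(table$liver_fat_m12)
  base <- complete & table$liver_fat_m0 > thr
  remit <- base & table$liver_fat_m12 <= thr
  arms <- intersect(ARM_LEVELS, unique(as.character(table$arm)))
  out <- do.call(rbind, lapply(arms, function(a) {
    den <- sum(base & table$arm == a)
    num <- sum(remit & table$arm == a)
    data.frame(arm = a, n_baseline = den, n_remit = num,
               rate_percent = if (den > 0) 100 * num / den else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
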