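#' Body surface area by the Mosteller formula
#'
#' `BSA = sqrt(height_cm * weight_kg / 3600)` in m^2. Vectorized.
#'
#' @param height_cm height in cm, > 0.
#' @param weight_kg weight in kg, > 0.
#' @return BSA in m^2.
#' @export
#' @examples
#' bsa_mosteller(170, 72)
bsa_mosteller <- function(height_cm, weight_kg) {
  if (any(!is.na(height_cm) & height_cm <= 0) ||
      any(!is.na(weight_kg) & weight_kg <= 0))
    stop("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Aortic size index
#'
#' Aortic diameter (mm) divided by body surface area (m^2). Vectorized.
#'
#' @param diameter_mm aortic diameter, mm.
#' @param bsa_m2 body surface area, m^2, > 0.
#' @return ASI in mm/m^2.
#' @export
aortic_size_index <- function(diameter_mm, bsa_m2) {
  if (any(!is.na(bsa_m2) & bsa_m2 <= 0)) stop("BSA must be positive")
  diameter_mm / bsa_m2
}

# One comorbidity flag from a measured criterion and a medication criterion;
# missing inputs yield NA ("undetermined"), never a silent FALSE.
flag_or <- function(...) {
  crit <- list(...)
  any_true <- Reduce(`|`, lapply(crit, function(x) !is.na(x) & x))
  any_na <- Reduce(`|`, lapply(crit, is.na))
  ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
}

#' Classify comorbidities from a patient table
#'
#' Applies the study definitions with strict inequalities:
#' hypertension: SBP > 140 mmHg, DBP > 90 mmHg, or antihypertensive
#' medication; diabetes: HbA1c > 6.5 % (NGSP) or antidiabetic medication;
#' dyslipidemia: LDL > 140 mg/dL or lipid-lowering medication; chronic
#' kidney disease: eGFR < 60 mL/min/1.73 m^2; hyperuricemia: uric acid
#' > 7.0 mg/dL or urate-lowering medication. A flag whose inputs are partly
#' missing and whose observed inputs are all negative is `NA`
#' (undetermined).
#'
#' @param records data frame with any of the columns `sbp`, `dbp`,
#'   `antihypertensive`, `hba1c`, `antidiabetic`, `ldl`, `lipid_lowering`,
#'   `egfr`, `uric_acid`, `urate_lowering`. Missing columns are treated as
#'   all-`NA`.
#' @return `records` with logical columns `hypertension`, `diabetes`,
#'   `dyslipidemia`, `ckd`, `hyperuricemia` appended.
#' @export
classify_comorbidities <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  col <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  records$hypertension <- flag_or(col("sbp") > 140, col("dbp") > 90,
                                  col("antihypertensive"))
  records$diabetes <- flag_or(col("hba1c") > 6.5, col("antidiabetic"))
  records$dyslipidemia <- flag_or(col("ldl") > 140, col("lipid_lowering"))
  records$ckd <- flag_or(col("egfr") < 60)
  records$hyperuricemia <- flag_or(col("uric_acid") > 7.0,
                                   col("urate_lowering"))
  records
}

#' Classify aortic dilatation
#'
#' Normal below 35 mm, advanced enlargement at or above 50 mm, mild in
#' between (the mild band is the complement of the two published cutoffs).
#'
#' @param diameter_mm aortic diameter, mm, > 0. Vectorized; `NA` passes
#'   through.
#' @return Factor with levels `none`, `mild`, `severe`.
#' @export
classify_dilatation <- function(diameter_mm) {
  if (any(!is.na(diameter_mm) & diameter_mm <= 0))
    stop("diameter must be positive")
  out <- ifelse(is.na(diameter_mm), NA_character_,
                ifelse(diameter_mm < 35, "none",
                       ifelse(diameter_mm >= 50, "severe", "mild")))
  factor(out, levels = c("none", "mild", "severe"))
}

#' Derive all clinical quantities for a patient table
#'
#' Adds Mosteller BSA, aortic size index, dilatation category and the
#' comorbidity flags to a patient table in one pass. Requires `height`
#' (cm) and `weight` (kg) for BSA and `aortic_diameter` (mm) for ASI and
#' dilatation; rows with missing inputs get `NA` derived values.
#'
#' @param records patient data frame.
#' @return The table with `bsa`, `asi`, `dilatation` and comorbidity columns
#'   appended.
#' @export
derive_clinical <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  col <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA_real_, n)
  records$bsa <- bsa_mosteller(col("height"), col("weight"))
  records$asi <- aortic_size_index(col("aortic_diameter"), records$bsa)
  records$dilatation <- classify_dilatation(col("aortic_diameter"))
  classify_comorbidities(records)
}
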