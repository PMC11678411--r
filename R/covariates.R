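#' Body-size metrics: BMI, ideal, adjusted and lean body weight
#'
#' BMI = WT / (height in m)^2. Ideal body weight by the Devine formula
#' (male: 50 + 2.3 kg per inch over 60 in; female: 45.5 + 2.3 per inch over
#' 60 in); for heights below 60 inches the height term is clamped at 0 with
#' a warning, since Devine extrapolates poorly there. Adjusted body weight
#' ABW = IBW + 0.4 (WT - IBW). Lean body weight by the Janmahasatian
#' formula: male 9270 WT / (6680 + 216 BMI); female
#' 9270 WT / (8780 + 244 BMI).
#'
#' @param wt actual body weight, kg
#' @param height height, cm
#' @param sex `"male"` or `"female"` (vectorised)
#' @return data.frame with columns BMI, IBW, ABW, LBW (kg, kg/m2)
#' @examples
#' derive_body_size(80, 180, "male")
#' @export
derive_body_size <- function(wt, height, sex) {
  stopifnot(all(wt > 0), all(height > 0))
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  n <- max(length(wt), length(height), length(sex))
  wt <- rep_len(wt, n); height <- rep_len(height, n); sex <- rep_len(sex, n)
  male <- sex == "male"
  bmi <- wt / (height / 100)^2
  inches_over <- height / 2.54 - 60
  if (any(inches_over < 0)) {
    warning("height below 60 inches: Devine height term clamped at 0")
    inches_over <- pmax(inches_over, 0)
  }
  ibw <- ifelse(male, 50, 45.5) + 2.3 * inches_over
  abw <- ibw + 0.4 * (wt - ibw)
  lbw <- ifelse(male,
                9270 * wt / (6680 + 216 * bmi),
                9270 * wt / (8780 + 244 * bmi))
  data.frame(BMI = bmi, IBW = ibw, ABW = abw, LBW = lbw)
}

#' Renal function: MDRD eGFR and Cockcroft-Gault creatinine clearance
#'
#' eGFR (mL/min/1.73 m2) by the 4-variable IDMS-traceable MDRD equation:
#' 175 SCr^-1.154 age^-0.203, times 0.742 if female and 1.212 if black.
#' CrCl (mL/min) by Cockcroft-Gault: (140 - age) W / (72 SCr), times 0.85
#' if female, where the weight factor W is actual body weight unless
#' WT >= 1.3 IBW, in which case ideal body weight is used instead.
#'
#' @param scr serum creatinine, mg/dL (> 0)
#' @param age years (>= 18)
#' @param sex `"male"` / `"female"`
#' @param race race token; `"black"` activates the MDRD race factor
#' @param wt actual body weight, kg
#' @param ibw ideal body weight, kg (see [derive_body_size()])
#' @return data.frame with columns EGFR, CRCL
#' @examples
#' derive_renal(1.0, 40, "male", "white", wt = 72, ibw = 70)
#' @export
derive_renal <- function(scr, age, sex, race = "white", wt, ibw) {
  if (any(scr <= 0)) {
    stop_gabapk("serum creatinine must be positive", class = "gabapk_domain_error")
  }
  n <- max(length(scr), length(age), length(sex), length(race),
           length(wt), length(ibw))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  race <- rep_len(race, n); wt <- rep_len(wt, n); ibw <- rep_len(ibw, n)
  female <- sex == "female"
  egfr <- 175 * scr^-1.154 * age^-0.203 *
    ifelse(female, 0.742, 1) * ifelse(race == "black", 1.212, 1)
  w <- ifelse(wt >= 1.3 * ibw, ibw, wt)
  crcl <- (140 - age) * w / (72 * scr) * ifelse(female, 0.85, 1)
  data.frame(EGFR = egfr, CRCL = crcl)
}

#' Acute kidney injury flag from a serum creatinine series
#'
#' AKI is flagged when serum creatinine rose by more than 0.3 mg/dL over
#' the 48 h preceding the reference time: the value at the reference time
#' minus the minimum value observed within the preceding 48 h must exceed
#' 0.3. With no earlier measurement inside that window the change cannot
#' be demonstrated and the flag is `FALSE`.
#'
#' @param times measurement times, hours (relative to any origin)
#' @param scr serum creatinine values, mg/dL, same length as `times`
#' @param reference_time time at which AKI status is assessed (default: the
#'   last measurement time)
#' @return logical scalar
#' @examples
#' flag_aki(c(-48, 0), c(1.0, 1.4))   # TRUE: rose by 0.4
#' flag_aki(c(-48, 0), c(1.0, 1.25))  # FALSE: 0.25 is not > 0.3
#' @export
flag_aki <- function(times, scr, reference_time = max(times)) {
  stopifnot(length(times) == length(scr), length(times) >= 1)
  at_ref <- scr[which.min(abs(times - reference_time))]
  window <- times < reference_time & times >= reference_time - 48
  if (!any(window)) return(FALSE)
  (at_ref - min(scr[window])) > 0.3
}

.metabolic_levels <- c("non-diabetic and non-obese",
                       "diabetic but not obese",
                       "obese but metabolically healthy",
                       "both diabetic and obese")

#' Combined obesity/diabetes category
#'
#' Obesity is BMI >= 30 kg/m2 (boundary inclusive). The four categories
#' cross obesity with a type 2 diabetes diagnosis.
#'
#' @param bmi body mass index, kg/m2
#' @param diabetes logical, type 2 diabetes diagnosis
#' @return data.frame with columns OBESE (logical) and METCAT (factor with
#'   the four combined levels)
#' @export
classify_metabolic <- function(bmi, diabetes) {
  stopifnot(all(bmi > 0))
  n <- max(length(bmi), length(diabetes))
  bmi <- rep_len(bmi, n); diabetes <- rep_len(as.logical(diabetes), n)
  obese <- bmi >= 30
  cat <- ifelse(obese & diabetes, .metabolic_levels[4],
         ifelse(obese, .metabolic_levels[3],
         ifelse(diabetes, .metabolic_levels[2], .metabolic_levels[1])))
  data.frame(OBESE = obese,
             METCAT = factor(cat, levels = .metabolic_levels))
}

#' Append every derived clinical covariate to a dataset
#'
#' Computes BMI, IBW, ABW, LBW ([derive_body_size()]), eGFR and CrCl
#' ([derive_renal()]), the obesity flag and the combined metabolic category
#' ([classify_metabolic()]) from each subject's raw covariates and stores
#' them in the covariate record. An AKI column already present (e.g. drawn
#' by the synthetic cohort generator or chart-reviewed) is kept; otherwise
#' AKI is set to `FALSE` since a single creatinine value cannot show a
#' 48 h rise.
#'
#' @param dataset a [pk_dataset()] whose subjects carry AGE, SEX, RACE, WT,
#'   HT, SCR, FPG, DM
#' @return the dataset with derived columns added to every covariate record
#' @export
derive_covariates <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  dataset$subjects <- lapply(dataset$subjects, function(s) {
    cov <- s$covariates
    body <- derive_body_size(cov$WT, cov$HT, cov$SEX)
    renal <- derive_renal(cov$SCR, cov$AGE, cov$SEX, cov$RACE,
                          wt = cov$WT, ibw = body$IBW)
    met <- classify_metabolic(body$BMI, cov$DM)
    cov$BMI <- body$BMI; cov$IBW <- body$IBW
    cov$ABW <- body$ABW; cov$LBW <- body$LBW
    cov$EGFR <- renal$EGFR; cov$CRCL <- renal$CRCL
    cov$OBESE <- met$OBESE
    cov$METCAT <- as.character(met$METCAT)
    if (is.null(cov$AKI)) cov$AKI <- FALSE
    s$covariates <- cov
    s
  })
  dataset
}
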