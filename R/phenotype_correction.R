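#' Correction constants for the 100 kg endpoint
#'
#' Sex-specific constants of the national swine genetic evaluation
#' correction system used to standardise growth measurements to a 100 kg
#' live weight: the correction-factor coefficients for age (kg/day scale)
#' and the numerator/slope pairs for ultrasonic backfat.
#'
#' @format A list with elements `cf_coeff` (male/female age coefficients),
#'   `bf_num` and `bf_slope` (male/female backfat constants, slope per kg).
#' @export
correction_constants <- list(
  cf_coeff = c(male = 1.826, female = 1.715),
  bf_num   = c(male = 12.402, female = 13.705),
  bf_slope = c(male = 0.106, female = 0.119)
)

check_sex <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("unknown sex label(s): ",
         paste(unique(sex[!sex %in% c("male", "female")]), collapse = ", "))
  }
  sex
}

#' Growth-rate correction factor
#'
#' CF = (measured weight / measured age) x sex coefficient, in kg/day.
#' The coefficient is 1.826 for males and 1.715 for females.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param measured_weight live weight at measurement, kg.
#' @param measured_age age at measurement, days.
#' @return Correction factor in kg/day.
#' @export
correction_factor <- function(sex, measured_weight, measured_age) {
  sex <- check_sex(sex)
  if (any(measured_weight <= 0) || any(measured_age <= 0)) {
    stop("measured weight and age must be positive")
  }
  unname((measured_weight / measured_age) * correction_constants$cf_coeff[sex])
}

#' Age corrected to 100 kg live weight (AGE100)
#'
#' AGE100 = measured age + (100 - measured weight) / CF, with CF from
#' [correction_factor()]. At exactly 100 kg the corrected age equals the
#' measured age; a heavier pig at the same age gets a smaller AGE100.
#'
#' @inheritParams correction_factor
#' @param measured_age age at measurement, days.
#' @return AGE100 in days.
#' @export
correct_age100 <- function(sex, measured_age, measured_weight) {
  cf <- correction_factor(sex, measured_weight, measured_age)
  unname(measured_age + (100 - measured_weight) / cf)
}

#' Backfat corrected to 100 kg live weight (BF100)
#'
#' BF100 = measured backfat x num / (num + slope x (weight - 100)), with
#' (num, slope) = (12.402, 0.106) for males and (13.705, 0.119) for
#' females. At exactly 100 kg the corrected backfat equals the measured
#' backfat.
#'
#' @inheritParams correction_factor
#' @param measured_backfat ultrasonic backfat at measurement, mm.
#' @return BF100 in mm.
#' @export
correct_bf100 <- function(sex, measured_backfat, measured_weight) {
  sex <- check_sex(sex)
  if (any(measured_backfat <= 0)) stop("measured backfat must be positive")
  num <- correction_constants$bf_num[sex]
  slope <- correction_constants$bf_slope[sex]
  denom <- num + slope * (measured_weight - 100)
  if (any(denom <= 0)) {
    stop("backfat correction denominator non-positive at weight(s): ",
         paste(measured_weight[denom <= 0], collapse = ", "))
  }
  unname(measured_backfat * num / denom)
}

#' Apply 100 kg endpoint corrections to a phenotype table
#'
#' Populates the `age100` and `bf100` columns from the raw measurement
#' columns; raw columns are left untouched.
#'
#' @param table a `pheno_table` from [read_phenotypes()] (or any data.frame
#'   with the same raw columns).
#' @return The table with `age100` (days) and `bf100` (mm) columns added.
#' @export
apply_corrections <- function(table) {
  required <- c("id", "sex", "measured_age", "measured_weight",
                "measured_backfat")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0L) {
    table$age100 <- numeric(0)
    table$bf100 <- numeric(0)
    return(table)
  }
  age100 <- tryCatch(
    correct_age100(table$sex, table$measured_age, table$measured_weight),
    error = function(e) stop("AGE100 correction failed: ", conditionMessage(e)))
  bf100 <- tryCatch(
    correct_bf100(table$sex, table$measured_backfat, table$measured_weight),
    error = function(e) stop("BF100 correction failed: ", conditionMessage(e)))
  table$age100 <- age100
  table$bf100 <- bf100
  table
}
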