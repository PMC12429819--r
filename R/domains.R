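#' Variable domains of the OHCA cohort table
#'
#' Level order is semantic: the first level of every categorical variable is
#' the reference level of the association model, and mode ties in the
#' imputers are broken towards the earlier level.
#'
#' @format A named list mapping each categorical variable to its character
#'   level vector.
#' @export
cohort_domains <- list(
  gender          = c("female", "male"),
  witness_type    = c("not_witnessed", "family", "healthcare", "lay"),
  arrest_location = c("home", "public"),
  call_time       = c("t00_05", "t06_18", "t19_23"),
  first_rhythm    = c("non_shockable", "shockable", "unknown")
)

#' Column order of the cohort CSV dialect
#' @export
cohort_columns <- c(
  "case_id", "age", "gender", "witness_type", "arrest_location",
  "call_time", "first_rhythm", "alert_issued", "bcpr"
)

# variables eligible for amputation and the covariates that drive them
amputable_vars <- c("age", "witness_type", "call_time")
fully_observed_vars <- c("gender", "arrest_location", "first_rhythm")

#' Model terms of the BCPR association model, in fixed order
#'
#' Dummy coding is against the reference levels female, not_witnessed,
#' t00_05, home and non_shockable.
#' @export
model_terms <- c(
  "alert_issued", "male", "age",
  "witness_family", "witness_healthcare", "witness_lay",
  "calltime_06_18", "calltime_19_23",
  "location_public",
  "rhythm_shockable", "rhythm_unknown"
)

AGE_MIN <- 18
AGE_MAX <- 110

#' Validate a cohort table
#'
#' Checks column set and order, categorical domains, the adult age range
#' \[18, 110\], binary exposure/outcome coding and `case_id` uniqueness.
#'
#' @param table A data frame in the cohort layout (see [cohort_columns]).
#' @param allow_missing Logical; if `TRUE`, `NA` is permitted in the three
#'   amputable variables (age, witness type, call time) only.
#' @param allow_mxi Logical; if `TRUE`, the extra level `"missing"` is
#'   permitted in witness type and call time and an `age_missing` indicator
#'   column may be present (missingness-indicator output).
#' @return The table, invisibly, with categorical columns as factors.
#' @export
validate_cohort <- function(table, allow_missing = FALSE, allow_mxi = FALSE) {
  stopifnot(is.data.frame(table))
  base_cols <- cohort_columns
  extra <- setdiff(names(table), c(base_cols, if (allow_mxi) "age_missing"))
  if (length(extra)) stop("unexpected columns: ", paste(extra, collapse = ", "))
  miss_cols <- setdiff(base_cols, names(table))
  if (length(miss_cols)) stop("missing columns: ", paste(miss_cols, collapse = ", "))

  if (anyDuplicated(table$case_id)) stop("case_id values are not unique")
  if (!is.numeric(table$age)) stop("age must be numeric")
  age_chk <- table$age
  if (allow_mxi && "age_missing" %in% names(table)) {
    age_chk[table$age_missing == 1L] <- NA  # sentinel fill 0 is exempt from range check
  }
  age_obs <- age_chk[!is.na(age_chk)]
  if (length(age_obs) && (min(age_obs) < AGE_MIN || max(age_obs) > AGE_MAX)) {
    stop("age outside the adult range [", AGE_MIN, ", ", AGE_MAX, "]")
  }
  for (v in c("alert_issued", "bcpr")) {
    if (!all(table[[v]] %in% c(0L, 1L))) stop(v, " must be coded 0/1")
  }
  for (v in names(cohort_domains)) {
    lv <- cohort_domains[[v]]
    if (allow_mxi && v %in% c("witness_type", "call_time")) lv <- c(lv, "missing")
    x <- as.character(table[[v]])
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      stop("variable ", v, ": value(s) outside domain at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    if (!allow_missing && anyNA(x)) {
      stop("variable ", v, " contains missing values in a complete cohort")
    }
    table[[v]] <- factor(x, levels = lv)
  }
  if (!allow_missing && anyNA(table$age)) {
    stop("age contains missing values in a complete cohort")
  }
  if (allow_missing) {
    for (v in setdiff(names(cohort_domains), amputable_vars)) {
      if (anyNA(table[[v]])) stop("variable ", v, " must be fully observed")
    }
  }
  invisible(table)
}

#' Coerce a data frame to the canonical cohort layout
#'
#' Orders the columns, converts categoricals to factors with the declared
#' level order and validates. Used by the generators and the CSV reader.
#' @inheritParams validate_cohort
#' @return A data frame of class `ohca_cohort`.
#' @export
as_cohort <- function(table, allow_missing = FALSE, allow_mxi = FALSE) {
  keep <- c(cohort_columns, if (allow_mxi && "age_missing" %in% names(table)) "age_missing")
  table <- table[, keep, drop = FALSE]
  table <- validate_cohort(table, allow_missing = allow_missing, allow_mxi = allow_mxi)
  table <- as.data.frame(table)
  rownames(table) <- NULL
  class(table) <- c("ohca_cohort", "data.frame")
  table
}

# which cells are missing among the amputable variables
missing_pattern_of <- function(table) {
  pat <- rep("none", nrow(table))
  pat[is.na(table$age)] <- "age"
  pat[is.na(table$witness_type)] <- "witness_type"
  pat[is.na(table$call_time)] <- "call_time"
  pat
}
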