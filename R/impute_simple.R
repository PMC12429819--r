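#' Imputed cohort container
#'
#' Bundles an imputed table with its method tag, the provenance
#' missingness mask, and (for the missingness-indicator method) the names
#' of the extra model terms it contributes.
#'
#' @param table Cohort table after imputation.
#' @param method One of `"mm"`, `"mxi"`, `"mf"`, `"knn"`.
#' @param mask Missingness mask of the input (see [missingness_mask()]).
#' @param extra_terms Character vector of extra design terms (MxI only).
#' @return A list of class `imputed_cohort`.
#' @export
imputed_cohort <- function(table, method, mask, extra_terms = character()) {
  structure(list(table = table, method = method, mask = mask,
                 extra_terms = extra_terms),
            class = "imputed_cohort")
}

#' @export
print.imputed_cohort <- function(x, ...) {
  cat(sprintf("Imputed cohort [%s]: %d rows, %d imputed cells",
              x$method, nrow(x$table), sum(x$mask$pattern != "none")))
  if (length(x$extra_terms)) {
    cat(", extra terms: ", paste(x$extra_terms, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

# most frequent observed level; ties towards the earlier domain level
mode_level <- function(f) {
  tab <- table(f[!is.na(f)])
  if (sum(tab) == 0) stop("no observed values to take a mode over")
  names(tab)[which.max(tab)]
}

#' Mean/mode single imputation
#'
#' Continuous gaps are filled with the arithmetic mean of the observed
#' values; categorical gaps with the most frequent observed level (ties
#' towards the earlier level in the declared domain order).
#'
#' @param table Cohort table with missing cells.
#' @return An [imputed_cohort] with method `"mm"`.
#' @export
impute_mean_mode <- function(table) {
  table <- as_cohort(table, allow_missing = TRUE)
  mask <- missingness_mask(table)
  out <- table
  if (anyNA(out$age)) {
    if (all(is.na(out$age))) stop("cannot impute fully missing column: age")
    out$age[is.na(out$age)] <- mean(out$age, na.rm = TRUE)
  }
  for (v in c("witness_type", "call_time")) {
    if (anyNA(out[[v]])) {
      if (all(is.na(out[[v]]))) stop("cannot impute fully missing column: ", v)
      out[[v]][is.na(out[[v]])] <- mode_level(out[[v]])
    }
  }
  imputed_cohort(as_cohort(out), "mm", mask)
}

#' Missingness-indicator single imputation
#'
#' Continuous age gaps are filled with 0 and a binary `age_missing`
#' indicator column is added; categorical gaps become an explicit extra
#' level `"missing"` (algebraically identical to fill-plus-indicator in
#' the design matrix). Indicators equal the missingness mask exactly.
#'
#' @param table Cohort table with missing cells.
#' @return An [imputed_cohort] with method `"mxi"`; its table may carry an
#'   `age_missing` column and extended factor levels.
#' @export
impute_missingness_indicator <- function(table) {
  table <- as_cohort(table, allow_missing = TRUE)
  mask <- missingness_mask(table)
  out <- table
  extra <- character()
  if (anyNA(out$age)) {
    out$age_missing <- as.integer(is.na(out$age))
    out$age[is.na(out$age)] <- 0
    extra <- c(extra, "age_missing")
  }
  if (anyNA(out$witness_type)) {
    lv <- c(levels(out$witness_type), "missing")
    x <- as.character(out$witness_type)
    x[is.na(x)] <- "missing"
    out$witness_type <- factor(x, levels = lv)
    extra <- c(extra, "witness_missing")
  }
  if (anyNA(out$call_time)) {
    lv <- c(levels(out$call_time), "missing")
    x <- as.character(out$call_time)
    x[is.na(x)] <- "missing"
    out$call_time <- factor(x, levels = lv)
    extra <- c(extra, "calltime_missing")
  }
  out <- as_cohort(out, allow_mxi = TRUE)
  imputed_cohort(out, "mxi", mask, extra_terms = extra)
}
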