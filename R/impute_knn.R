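# variables entering the Gower distance / imputation models, in table order
knn_vars <- function(use_outcome = TRUE) {
  c("age", "gender", "witness_type", "arrest_location", "call_time",
    "first_rhythm", "alert_issued", if (use_outcome) "bcpr")
}

#' Gower distance between two cohort rows
#'
#' Mixed-type dissimilarity in \[0, 1\]: range-scaled absolute difference
#' for continuous age, 0/1 mismatch for nominal variables, and
#' rank-scaled-to-\[0, 1\] absolute difference for the ordinal call time.
#' Only variables observed in both rows enter; the result is the mean over
#' those variables.
#'
#' @param row_a,row_b Single-row cohort tables (or named lists) holding the
#'   variables in `variables`.
#' @param numeric_ranges Named vector of positive ranges for continuous
#'   variables (at least `age`).
#' @param variables Character vector of variables to compare.
#' @return A single number in \[0, 1\].
#' @export
gower_distance <- function(row_a, row_b,
                           numeric_ranges = c(age = diff(c(AGE_MIN, AGE_MAX))),
                           variables = knn_vars()) {
  acc <- 0; used <- 0L
  for (v in variables) {
    a <- row_a[[v]]; b <- row_b[[v]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) next
    if (v == "age") {
      rg <- numeric_ranges[["age"]]
      if (!isTRUE(rg > 0)) stop("numeric range for age must be positive")
      acc <- acc + abs(as.numeric(a) - as.numeric(b)) / rg
    } else if (v == "call_time") {
      k <- length(cohort_domains$call_time)
      ra <- match(as.character(a), cohort_domains$call_time)
      rb <- match(as.character(b), cohort_domains$call_time)
      acc <- acc + abs(ra - rb) / (k - 1)
    } else {
      acc <- acc + as.numeric(as.character(a) != as.character(b))
    }
    used <- used + 1L
  }
  if (used == 0L) stop("rows share no usable variable")
  acc / used
}

# numeric encoding of a cohort for the distance/forest kernels:
# categorical -> level codes, call_time kept ordinal, age raw
encode_cohort <- function(table, vars) {
  cols <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.factor(x)) as.numeric(x) else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vars
  X
}

#' Gower-distance k-nearest-neighbour imputation
#'
#' For each missing cell, the `k` rows closest in Gower distance among
#' those observing the target variable donate their median (continuous) or
#' mode (categorical; ties towards the earlier domain level). Distance
#' ties are broken towards the smaller `case_id`. The method is
#' deterministic given the table.
#'
#' @param table Cohort table with missing cells.
#' @param k Number of donor neighbours (default 5). If fewer donors
#'   observe a variable, all of them are used with a warning; zero donors
#'   is an error.
#' @param use_outcome Include the outcome `bcpr` in the distance? Default
#'   `TRUE` so imputation preserves covariate-outcome association.
#' @return An [imputed_cohort] with method `"knn"`.
#' @export
impute_knn <- function(table, k = 5L, use_outcome = TRUE) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  k <- as.integer(k)
  table <- as_cohort(table, allow_missing = TRUE)
  mask <- missingness_mask(table)
  vars <- knn_vars(use_outcome)
  X <- encode_cohort(table, vars)

  for (v in amputable_vars) {
    n_gap <- sum(is.na(table[[v]]))
    if (n_gap == 0L) next
    n_donor <- sum(!is.na(table[[v]]))
    if (n_donor == 0L) stop("no donors observe variable ", v)
    if (n_donor < k) {
      warning("variable ", v, ": only ", n_donor,
              " donors available (k = ", k, "); using all of them")
    }
  }

  dist_cat <- !(vars %in% c("age", "call_time"))
  agg_cat <- vars != "age"
  ranges <- vapply(seq_along(vars), function(j) {
    if (dist_cat[j]) return(1)
    if (vars[j] == "call_time") {
      return(length(cohort_domains$call_time) - 1)  # rank scale over the domain
    }
    x <- X[, j]
    r <- diff(range(x, na.rm = TRUE))
    if (r > 0) r else 1
  }, numeric(1))

  filled <- gower_knn_impute_cpp(X, dist_cat, ranges, agg_cat,
                                 as.integer(table$case_id), k)
  out <- decode_fill(table, filled, vars)
  imputed_cohort(out, "knn", mask)
}

# write imputed codes back into the factor/numeric columns
decode_fill <- function(table, filled, vars) {
  out <- table
  for (v in intersect(amputable_vars, vars)) {
    gap <- is.na(out[[v]])
    if (!any(gap)) next
    j <- match(v, vars)
    if (v == "age") {
      out$age[gap] <- filled[gap, j]
    } else {
      lv <- levels(out[[v]])
      out[[v]][gap] <- lv[as.integer(round(filled[gap, j]))]
    }
  }
  as_cohort(out)
}
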