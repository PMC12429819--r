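#' Write a cohort table as CSV
#'
#' Fixed dialect: header
#' `case_id,age,gender,witness_type,arrest_location,call_time,first_rhythm,alert_issued,bcpr`,
#' lowercase category tokens, empty fields for missing cells, LF line
#' endings, UTF-8. Age is written with 17 significant digits so that the
#' read-write cycle is exact on doubles.
#'
#' @param table Cohort table (missing cells allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  cols <- cohort_columns
  m <- vapply(cols, function(v) {
    x <- table[[v]]
    out <- if (v == "age") {
      ifelse(is.na(x), "", sprintf("%.17g", x))
    } else if (v %in% c("case_id", "alert_issued", "bcpr")) {
      as.character(x)
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
    out
  }, character(nrow(table)))
  if (nrow(table) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1, paste, collapse = ","))
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Strict reader for the dialect written by [write_cohort_csv()]: the
#' header must match exactly, categories must be the declared lowercase
#' tokens, age must be numeric; violations are reported with their row
#' number. Empty fields become missing cells.
#'
#' @param path CSV path.
#' @inheritParams validate_cohort
#' @return An `ohca_cohort`.
#' @export
read_cohort_csv <- function(path, allow_missing = TRUE, allow_mxi = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(header, paste(cohort_columns, collapse = ","))) {
    stop("bad header: expected '", paste(cohort_columns, collapse = ","), "'")
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        check.names = FALSE)
  df[df == ""] <- NA
  age_num <- suppressWarnings(as.numeric(df$age))
  bad_age <- which(!is.na(df$age) & is.na(age_num))
  if (length(bad_age)) {
    stop("non-numeric age at row ", bad_age[1])
  }
  df$age <- age_num
  for (v in c("case_id", "alert_issued", "bcpr")) {
    x <- suppressWarnings(as.integer(df[[v]]))
    bad <- which(is.na(x) != is.na(df[[v]]))
    if (length(bad)) stop("non-integer ", v, " at row ", bad[1])
    df[[v]] <- x
  }
  for (v in names(cohort_domains)) {
    lv <- cohort_domains[[v]]
    if (allow_mxi && v %in% c("witness_type", "call_time")) lv <- c(lv, "missing")
    bad <- which(!is.na(df[[v]]) & !(df[[v]] %in% lv))
    if (length(bad)) {
      stop("variable ", v, ": value '", df[[v]][bad[1]],
           "' outside domain at row ", bad[1])
    }
  }
  if (allow_mxi && any(!is.na(df$age) & df$age == 0)) {
    # sentinel fill: a zero age marks a missingness-indicator row
    df$age_missing <- as.integer(!is.na(df$age) & df$age == 0)
  }
  as_cohort(df, allow_missing = allow_missing, allow_mxi = allow_mxi)
}

#' Write / read a missingness mask CSV (`case_id,pattern`)
#'
#' @param mask Data frame with columns `case_id`, `pattern`.
#' @param path File path.
#' @return `path` (writer) or the mask data frame (reader).
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(all(c("case_id", "pattern") %in% names(mask)))
  lines <- c("case_id,pattern", paste(mask$case_id, mask$pattern, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "character"))
  ok <- c("none", amputable_vars)
  bad <- which(!(df$pattern %in% ok))
  if (length(bad)) stop("unknown pattern '", df$pattern[bad[1]], "' at row ", bad[1])
  df
}

#' Serialize a fit as flat JSON
#'
#' One key per term holding beta, SE and the 95% CI bounds, plus the
#' model-level log-likelihood, AIC, RMSE, sample size and convergence
#' flag.
#'
#' @param fit An `ohca_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ohca_fit"))
  cf <- fit$coefficients
  terms <- lapply(seq_len(nrow(cf)), function(i) {
    list(beta = cf$beta[i], se = cf$se[i],
         ci_low = cf$ci_low[i], ci_high = cf$ci_high[i])
  })
  names(terms) <- cf$term
  rec <- list(method = if (is.null(fit$method)) NA else fit$method,
              terms = terms, loglik = fit$loglik, aic = fit$aic,
              rmse = fit$rmse, n_used = fit$n_used,
              converged = fit$converged)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
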