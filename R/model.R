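#' Drop incomplete cases
#'
#' Retains exactly the rows with no missing cell, preserving order: the
#' complete-case path of the analysis.
#'
#' @param table A cohort table, possibly with missing cells.
#' @return The complete rows as an `ohca_cohort`.
#' @export
complete_case_filter <- function(table) {
  keep <- stats::complete.cases(table[, cohort_columns])
  if (!any(keep)) stop("no complete cases remain after filtering")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ohca_cohort", "data.frame")
  out
}

#' Build the design matrix of the BCPR association model
#'
#' Dummy-codes the cohort covariates against the reference levels (female,
#' not witnessed, 00:00-05:59 call, home, non-shockable) in the fixed
#' [model_terms] order. For missingness-indicator input the extra
#' `age_missing`, `witness_missing` and `calltime_missing` columns are
#' appended after the base terms when present.
#'
#' @param table A cohort table; complete, or a missingness-indicator table
#'   (extended `"missing"` levels / `age_missing` column).
#' @param intercept Prepend an intercept column of ones?
#' @return Numeric matrix with one named column per term.
#' @export
design_matrix <- function(table, intercept = TRUE) {
  wt <- as.character(table$witness_type)
  ct <- as.character(table$call_time)
  cols <- list(
    alert_issued       = as.numeric(table$alert_issued),
    male               = as.numeric(table$gender == "male"),
    age                = as.numeric(table$age),
    witness_family     = as.numeric(wt == "family"),
    witness_healthcare = as.numeric(wt == "healthcare"),
    witness_lay        = as.numeric(wt == "lay"),
    calltime_06_18     = as.numeric(ct == "t06_18"),
    calltime_19_23     = as.numeric(ct == "t19_23"),
    location_public    = as.numeric(table$arrest_location == "public"),
    rhythm_shockable   = as.numeric(table$first_rhythm == "shockable"),
    rhythm_unknown     = as.numeric(table$first_rhythm == "unknown")
  )
  if ("age_missing" %in% names(table)) {
    cols$age_missing <- as.numeric(table$age_missing)
  }
  if (any(wt == "missing", na.rm = TRUE)) {
    cols$witness_missing <- as.numeric(wt == "missing")
  }
  if (any(ct == "missing", na.rm = TRUE)) {
    cols$calltime_missing <- as.numeric(ct == "missing")
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    stop("design matrix contains missing values; impute or apply ",
         "complete_case_filter() first")
  }
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors from the
#' inverse Fisher information. Convergence is declared when the largest
#' absolute score component falls below `tol`; runaway coefficients
#' (|beta| > 15 with a non-vanishing gradient) are flagged as separation
#' and returned unconverged.
#'
#' @param X Design matrix including the intercept column.
#' @param y 0/1 outcome vector.
#' @param tol Score (gradient) infinity-norm tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `ohca_fit`: `coefficients` data frame (term,
#'   beta, se, ci_low, ci_high), `loglik`, `aic`, `rmse`, `n_used`,
#'   `converged`, `fitted`, and `n_iter`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot fit")
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (it > max_iter) break
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    qr_wx <- qr(X * sw)
    beta_new <- qr.coef(qr_wx, z * sw)
    if (anyNA(beta_new)) stop("design matrix is rank deficient")
    # step-halve if the deviance worsens (guards rare IRLS overshoot)
    dev_new <- binom_deviance(X, beta_new, y)
    half <- 0L
    while (dev_new > dev_old + 1e-8 && half < 10L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- binom_deviance(X, beta_new, y)
      half <- half + 1L
    }
    beta <- beta_new
    dev_old <- dev_new
    if (max(abs(beta)) > 15) break  # runaway coefficients: separation
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  separated <- any(abs(beta) > 15) && max(abs(drop(crossprod(X, y - mu)))) > tol
  if (separated) converged <- FALSE
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(info))))
  loglik <- sum(y * eta - log1p(exp(eta)))
  aic <- 2 * p - 2 * loglik
  coef_df <- data.frame(
    term = colnames(X),
    beta = unname(beta),
    se = unname(se),
    ci_low = unname(beta - 1.96 * se),
    ci_high = unname(beta + 1.96 * se),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coef_df,
    loglik = loglik,
    aic = aic,
    rmse = sqrt(mean((y - mu)^2)),
    n_used = n,
    converged = converged,
    n_iter = it,
    fitted = mu,
    y = y
  ), class = "ohca_fit")
}

binom_deviance <- function(X, beta, y) {
  eta <- drop(X %*% beta)
  -2 * sum(y * eta - log1p(exp(eta)))
}

#' Root mean squared error of a fitted model
#'
#' The probability-scale RMSE `sqrt(mean((y - p_hat)^2))` over the rows
#' used in the fit (for complete-case fits, the complete cases only).
#'
#' @param fit An `ohca_fit`.
#' @return A single number in \[0, 1\].
#' @export
model_rmse <- function(fit) {
  stopifnot(inherits(fit, "ohca_fit"))
  sqrt(mean((fit$y - fit$fitted)^2))
}

#' Fit the association model to one (possibly imputed) dataset
#'
#' The analysis stage of the pipeline: for method `"cc"` incomplete rows
#' are dropped first; for imputation output the table is used as is (the
#' missingness-indicator method contributes its extra terms through the
#' design matrix).
#'
#' @param table A cohort table or an [imputed_cohort] object.
#' @param method One of `"cc"`, `"mm"`, `"mxi"`, `"mf"`, `"knn"`; only
#'   `"cc"` changes behaviour here (row filtering), the others are recorded
#'   as metadata.
#' @return An `ohca_fit` with an added `method` element.
#' @export
fit_association <- function(table, method = c("cc", "mm", "mxi", "mf", "knn")) {
  method <- match.arg(method)
  if (inherits(table, "imputed_cohort")) table <- table$table
  if (method == "cc") table <- complete_case_filter(table)
  X <- design_matrix(table)
  fit <- fit_logistic(X, as.numeric(table$bcpr))
  fit$method <- method
  fit
}

#' @export
print.ohca_fit <- function(x, ...) {
  cat("Logistic association fit",
      if (!is.null(x$method)) paste0(" [", x$method, "]"), "\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, RMSE = %.4f, converged: %s\n",
              x$n_used, x$loglik, x$aic, x$rmse, x$converged))
  cf <- x$coefficients
  cf[, -1] <- lapply(cf[, -1], function(z) signif(z, 4))
  print(cf, row.names = FALSE)
  invisible(x)
}
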