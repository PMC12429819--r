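#' @useDynLib ohcasim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis rbinom uniroot qlnorm plnorm runif qnorm
NULL

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# largest-remainder apportionment of n_target among categories proportional
# to counts; exact when n_target == sum(counts)
apportion <- function(counts, n_target) {
  q <- counts * n_target / sum(counts)
  base <- floor(q)
  rem <- n_target - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Sample ages from a quartile-matched log-normal
#'
#' Fits a log-normal to a printed (Q1, median, Q3) summary by matching the
#' median and the interquartile ratio, then samples from it truncated to the
#' adult range \[18, 110\] by inverse-CDF sampling.
#'
#' @param n Number of draws.
#' @param q1,med,q3 Printed age quartiles (years).
#' @return Numeric vector of ages in \[18, 110\].
#' @export
sample_age <- function(n, q1, med, q3) {
  stopifnot(q1 < med, med < q3, q1 > 0)
  mu <- log(med)
  sigma <- log(q3 / q1) / (2 * qnorm(0.75))
  lo <- plnorm(AGE_MIN, mu, sigma)
  hi <- plnorm(AGE_MAX, mu, sigma)
  qlnorm(runif(n, lo, hi), mu, sigma)
}

#' Generate a table-faithful synthetic cohort
#'
#' Reconstructs a cohort whose stratum totals and per-stratum covariate
#' level counts equal the published table exactly (at `scale = 1`).
#' Covariates are sampled independently of one another within each
#' alert x outcome stratum; ages are drawn from a log-normal matched to the
#' stratum's printed quartiles. At `scale < 1` counts are reduced by
#' largest-remainder apportionment so levels still sum to stratum totals.
#'
#' @param counts A [table1_counts()] object.
#' @param scale Fraction of the published cohort size to generate, in (0, 1].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An `ohca_cohort` data frame with `round(scale * N)` rows.
#' @export
generate_table_faithful <- function(counts = table1_counts(), scale = 1, seed = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0, scale <= 1)
  validate_table1_counts(counts)
  with_seed(seed, {
    strat_n <- vapply(counts$strata, `[[`, integer(1), "n")
    n_total <- as.integer(round(counts$total * scale))
    strat_take <- apportion(strat_n, n_total)
    pieces <- vector("list", length(counts$strata))
    for (i in seq_along(counts$strata)) {
      s <- counts$strata[[i]]
      m <- strat_take[i]
      if (m == 0L) next
      df <- data.frame(
        age = sample_age(m, s$age[["q1"]], s$age[["median"]], s$age[["q3"]])
      )
      for (v in names(cohort_domains)) {
        lev_take <- apportion(s[[v]][cohort_domains[[v]]], m)
        df[[v]] <- sample(rep(cohort_domains[[v]], lev_take))
      }
      df$alert_issued <- as.integer(s$alert_issued)
      df$bcpr <- as.integer(s$bcpr)
      pieces[[i]] <- df
    }
    tab <- do.call(rbind, pieces)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    tab$case_id <- seq_len(nrow(tab))
    as_cohort(tab)
  })
}

#' Reference coefficients of the BCPR association model
#'
#' The published log-odds coefficients of the full multivariable model on
#' the complete reference cohort. The intercept is not published; it is
#' `NA` here and is calibrated to a target outcome prevalence by the
#' model-based generator.
#'
#' @param intercept Optional log-odds intercept.
#' @return A list of class `true_coefficients` with elements `intercept`
#'   and `beta` (named vector over [model_terms]).
#' @export
true_coefficients <- function(intercept = NA_real_) {
  beta <- c(
    alert_issued       =  2.43,
    male               = -0.11,
    age                =  0.0015,
    witness_family     =  0.17,
    witness_healthcare =  2.16,
    witness_lay        = -0.11,
    calltime_06_18     =  0.011,
    calltime_19_23     = -0.063,
    location_public    =  1.03,
    rhythm_shockable   =  0.58,
    rhythm_unknown     =  2.03
  )
  structure(list(intercept = intercept, beta = beta), class = "true_coefficients")
}

check_true_coefficients <- function(coefs) {
  stopifnot(is.list(coefs), !is.null(coefs$beta))
  miss <- setdiff(model_terms, names(coefs$beta))
  if (length(miss)) stop("missing coefficient(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(coefs$beta[model_terms]))) stop("coefficients must be finite")
  coefs$beta <- coefs$beta[model_terms]
  coefs
}

#' Calibrate the model intercept to a target outcome prevalence
#'
#' Finds the log-odds intercept `a` such that the mean over cases of
#' `plogis(a + x_i' beta)` equals `target_prevalence`. The mean probability
#' is strictly increasing in `a`, so the root is unique; it is found by
#' bisection-based root-finding to an absolute prevalence error below 1e-8.
#'
#' @param table A complete cohort table (covariates only are used), or a
#'   numeric matrix whose columns follow [model_terms].
#' @param beta Named coefficient vector over [model_terms].
#' @param target_prevalence Target mean outcome probability, in (0, 1).
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(table, beta, target_prevalence) {
  stopifnot(is.numeric(target_prevalence), length(target_prevalence) == 1,
            target_prevalence > 0, target_prevalence < 1)
  X <- if (is.matrix(table)) table else design_matrix(table, intercept = FALSE)
  beta <- beta[colnames(X)]
  if (anyNA(beta)) stop("beta must name every model term")
  s <- drop(X %*% beta)
  f <- function(a) mean(plogis(a + s)) - target_prevalence
  lo <- qlogis(target_prevalence) - max(s)
  hi <- qlogis(target_prevalence) - min(s)
  if (lo == hi) return(lo)
  r <- uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 200L)
  r$root
}

#' Generate a model-based synthetic cohort with known true coefficients
#'
#' Samples covariates independently from the whole-cohort marginals of the
#' published table, then draws the outcome from a logistic model with the
#' supplied (default: published reference) coefficients. When the intercept
#' is not supplied it is calibrated so the expected outcome prevalence
#' equals `target_prevalence`.
#'
#' @param n Number of cases (>= 1).
#' @param coefs A [true_coefficients()] object; `NULL` for the defaults.
#' @param target_prevalence Target BCPR prevalence used to calibrate a
#'   missing intercept; default 0.653, the published overall rate.
#' @param seed Integer seed.
#' @param counts Stratum-count table supplying the covariate marginals.
#' @return A list with elements `cohort` (an `ohca_cohort`) and `coefs`
#'   (the coefficients actually used, intercept filled in).
#' @export
generate_model_based <- function(n, coefs = NULL, target_prevalence = 0.653,
                                 seed = NULL, counts = table1_counts()) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (is.null(coefs)) coefs <- true_coefficients()
  coefs <- check_true_coefficients(coefs)
  marg <- table1_marginals(counts)
  with_seed(seed, {
    df <- data.frame(case_id = seq_len(n))
    df$age <- sample_age(n, marg$age[["q1"]], marg$age[["median"]], marg$age[["q3"]])
    for (v in names(cohort_domains)) {
      df[[v]] <- sample(cohort_domains[[v]], n, replace = TRUE,
                        prob = marg[[v]] / sum(marg[[v]]))
    }
    p_alert <- marg$alert_issued[["yes"]] / sum(marg$alert_issued)
    df$alert_issued <- rbinom(n, 1L, p_alert)
    df$bcpr <- 0L  # placeholder until outcome is drawn
    X <- design_matrix(as_cohort(df), intercept = FALSE)
    a <- coefs$intercept
    if (is.null(a) || is.na(a)) {
      a <- calibrate_intercept(X, coefs$beta, target_prevalence)
    }
    p <- plogis(a + drop(X %*% coefs$beta[colnames(X)]))
    df$bcpr <- rbinom(n, 1L, p)
    coefs$intercept <- a
    list(cohort = as_cohort(df), coefs = coefs)
  })
}
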