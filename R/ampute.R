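#' Specify a MAR amputation mechanism
#'
#' Defines how missingness is introduced into a complete cohort: the target
#' overall proportion of cases receiving one missing value, the relative
#' frequency of the three missingness patterns (age, witness type, call
#' time), and per-pattern weights on fully observed predictor covariates.
#' Missingness probability for a case is
#' `plogis(shift + sum_j w_j z_j)` where `z_j` is the centred, range-scaled
#' level code of predictor `j` and the per-pattern `shift` is solved so the
#' expected missing proportion equals `proportion`. The mechanism never
#' looks at the value of the variable being deleted, so it is MAR by
#' construction.
#'
#' Defaults: age missingness is rarer than witness type / call time
#' (frequencies 0.2/0.4/0.4) and is driven by gender; witness type and call
#' time missingness are driven by arrest location with higher probability
#' in public locations. Weight 1 on a binary predictor is a missingness
#' log-odds difference of 1 between its levels (odds ratio about 2.7).
#'
#' @param proportion Overall fraction of cases to receive one missing
#'   value, in (0, 1).
#' @param pattern_freqs Named nonnegative frequencies over
#'   `c("age", "witness_type", "call_time")`, summing to 1.
#' @param weights Named list: per pattern, a named numeric vector of
#'   weights on predictor covariates (must be fully observed covariates:
#'   gender, arrest_location, first_rhythm).
#' @return A list of class `amputation_spec`.
#' @export
amputation_spec <- function(proportion,
                            pattern_freqs = c(age = 0.2, witness_type = 0.4,
                                              call_time = 0.4),
                            weights = list(
                              age          = c(gender = 1),
                              witness_type = c(arrest_location = 1),
                              call_time    = c(arrest_location = 1)
                            )) {
  stopifnot(is.numeric(proportion), length(proportion) == 1)
  if (proportion <= 0 || proportion >= 1) {
    stop("proportion must lie strictly between 0 and 1")
  }
  if (!setequal(names(pattern_freqs), amputable_vars)) {
    stop("pattern_freqs must be named over: ", paste(amputable_vars, collapse = ", "))
  }
  pattern_freqs <- pattern_freqs[amputable_vars]
  if (any(pattern_freqs < 0)) stop("pattern frequencies must be nonnegative")
  if (abs(sum(pattern_freqs) - 1) > 1e-12) stop("pattern frequencies must sum to 1")
  for (pat in names(weights)) {
    if (!pat %in% amputable_vars) stop("unknown pattern in weights: ", pat)
    bad <- setdiff(names(weights[[pat]]), fully_observed_vars)
    if (length(bad)) {
      stop("pattern ", pat, ": weight on ineligible predictor(s) ",
           paste(bad, collapse = ", "),
           " (only fully observed covariates may drive missingness)")
    }
  }
  structure(list(proportion = proportion, pattern_freqs = pattern_freqs,
                 weights = weights, mechanism = "MAR"),
            class = "amputation_spec")
}

# centred, range-scaled weighted score of a pattern's predictors, one value
# per row: level codes are mapped to [0, 1] and mean-centred, so a weight of
# 1 on a binary predictor is a missingness log-odds difference of 1 between
# its levels (odds ratio ~ e)
predictor_score <- function(table, wmap) {
  s <- numeric(nrow(table))
  for (nm in names(wmap)) {
    if (!nm %in% fully_observed_vars) stop("unknown predictor: ", nm)
    code <- as.numeric(as.integer(table[[nm]]))
    k <- length(levels(table[[nm]]))
    x <- if (k > 1) (code - 1) / (k - 1) else code * 0
    s <- s + wmap[[nm]] * (x - mean(x))
  }
  s
}

#' Assign a candidate missingness pattern to every case
#'
#' Each case receives exactly one candidate pattern, drawn multinomially
#' from the spec's pattern frequencies. Whether missingness then fires is
#' decided case by case in [ampute()]; the candidate scheme guarantees at
#' most one missing cell per row.
#'
#' @param table A complete cohort table.
#' @param spec An [amputation_spec()].
#' @param seed Integer seed.
#' @return Character vector of candidate patterns, one per row.
#' @export
assign_patterns <- function(table, spec, seed = NULL) {
  stopifnot(inherits(spec, "amputation_spec"))
  with_seed(seed, {
    sample(names(spec$pattern_freqs), nrow(table), replace = TRUE,
           prob = spec$pattern_freqs)
  })
}

#' Per-case missingness probability of a pattern
#'
#' `plogis(intercept_shift + weighted score)` of the pattern's predictor
#' covariates. Depends only on fully observed covariates, never on the
#' value that would go missing.
#'
#' @param table Cohort table supplying the predictor covariates (also used
#'   to centre and scale their codings).
#' @param pattern One of `"age"`, `"witness_type"`, `"call_time"`.
#' @param spec An [amputation_spec()].
#' @param intercept_shift Log-odds shift added to the weighted score.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
missingness_probability <- function(table, pattern, spec, intercept_shift = 0) {
  stopifnot(inherits(spec, "amputation_spec"))
  if (!pattern %in% amputable_vars) stop("unknown pattern: ", pattern)
  s <- predictor_score(table, spec$weights[[pattern]])
  plogis(intercept_shift + s)
}

#' Introduce MAR missingness into a complete cohort
#'
#' Every case gets one candidate pattern; within each pattern the
#' log-odds intercept is solved by monotone root-finding so that the
#' expected fraction of cases with a missing value equals
#' `spec$proportion`, and missingness fires Bernoulli with the resulting
#' per-case probability. At most one cell per row is ever deleted.
#'
#' @param table A complete cohort table.
#' @param spec An [amputation_spec()].
#' @param seed Integer seed.
#' @return A list with `table` (cohort with `NA` cells) and `mask`
#'   (data frame `case_id`, `pattern` with `"none"` for intact rows).
#' @export
ampute <- function(table, spec, seed = NULL) {
  stopifnot(inherits(spec, "amputation_spec"))
  table <- as_cohort(table)  # must be complete
  with_seed(seed, {
    cand <- sample(names(spec$pattern_freqs), nrow(table), replace = TRUE,
                   prob = spec$pattern_freqs)
    pattern <- rep("none", nrow(table))
    out <- table
    for (pat in amputable_vars) {
      idx <- which(cand == pat)
      if (!length(idx)) next
      s <- predictor_score(table, spec$weights[[pat]])[idx]
      shift <- solve_shift(s, spec$proportion)
      p <- plogis(shift + s)
      fire <- idx[runif(length(idx)) < p]
      if (length(fire)) {
        out[[pat]][fire] <- NA
        pattern[fire] <- pat
      }
    }
    mask <- data.frame(case_id = table$case_id, pattern = pattern,
                       stringsAsFactors = FALSE)
    tab <- as_cohort(out, allow_missing = TRUE)
    list(table = tab, mask = mask)
  })
}

# solve a in mean(plogis(a + s)) = target; strictly increasing in a
solve_shift <- function(s, target) {
  f <- function(a) mean(plogis(a + s)) - target
  lo <- qlogis(target) - max(s)
  hi <- qlogis(target) - min(s)
  if (lo == hi) return(lo)
  uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 200L)$root
}

#' Realized missingness pattern of an amputed table
#'
#' @param table A cohort table with missing cells.
#' @return Data frame `case_id`, `pattern` (the variable missing in each
#'   row, or `"none"`).
#' @export
missingness_mask <- function(table) {
  data.frame(case_id = table$case_id, pattern = missing_pattern_of(table),
             stringsAsFactors = FALSE)
}
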