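#' Published stratum counts of the reference OHCA cohort
#'
#' Loads the packaged transcription of the published cohort-characteristics
#' table: four strata (alert issued x bystander CPR), each with per-covariate
#' level counts and an age median/quartile summary. These counts define the
#' table-faithful synthetic cohort.
#'
#' @param path Optional path to an alternative counts file (JSON) in the same
#'   layout as the packaged fixture.
#' @return A list of class `table1_counts` with elements `total`, `overall`
#'   and `strata` (a list of four stratum records).
#' @export
table1_counts <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    if (!is.null(.fixture_cache$table1)) return(.fixture_cache$table1)
    path <- system.file("extdata", "table1_counts.json", package = "ohcasim")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$strata <- lapply(x$strata, function(s) {
    s$n <- as.integer(s$n)
    for (v in names(cohort_domains)) s[[v]] <- unlist(s[[v]])
    s
  })
  class(x) <- "table1_counts"
  validate_table1_counts(x)
  if (packaged) .fixture_cache$table1 <- x
  x
}

.fixture_cache <- new.env(parent = emptyenv())

#' Validate a stratum-count table
#'
#' Checks that within every stratum each covariate's level counts sum to the
#' stratum total, that levels match the declared domains, and that the four
#' stratum totals sum to the cohort total.
#'
#' @param counts A `table1_counts` object.
#' @return The object, invisibly.
#' @export
validate_table1_counts <- function(counts) {
  stopifnot(inherits(counts, "table1_counts"))
  tot <- sum(vapply(counts$strata, `[[`, integer(1), "n"))
  if (tot != counts$total) {
    stop("stratum totals sum to ", tot, ", expected ", counts$total)
  }
  for (s in counts$strata) {
    lab <- sprintf("stratum (alert=%d, bcpr=%d)", s$alert_issued, s$bcpr)
    for (v in names(cohort_domains)) {
      if (!setequal(names(s[[v]]), cohort_domains[[v]])) {
        stop(lab, ": levels of ", v, " do not match the declared domain")
      }
      if (sum(s[[v]]) != s$n) {
        stop(lab, ": counts of ", v, " sum to ", sum(s[[v]]),
             ", expected stratum total ", s$n)
      }
    }
    if (!all(c("median", "q1", "q3") %in% names(s$age))) {
      stop(lab, ": age summary must give median, q1 and q3")
    }
    if (!(s$age[["q1"]] < s$age[["median"]] && s$age[["median"]] < s$age[["q3"]])) {
      stop(lab, ": age quartiles not increasing")
    }
  }
  invisible(counts)
}

#' Whole-cohort covariate marginals implied by the stratum counts
#'
#' Sums the four strata; used by the model-based generator, which draws
#' covariates from these marginals and generates the outcome from the
#' logistic model instead of the stratum conditionals.
#'
#' @param counts A `table1_counts` object.
#' @return A list with per-covariate level-count vectors, the exposure split
#'   and the overall age quartile summary.
#' @export
table1_marginals <- function(counts = table1_counts()) {
  marg <- list()
  for (v in names(cohort_domains)) {
    m <- Reduce(`+`, lapply(counts$strata, `[[`, v))
    marg[[v]] <- m[cohort_domains[[v]]]
  }
  marg$alert_issued <- c(
    no  = counts$overall$alert_issued$no,
    yes = counts$overall$alert_issued$yes
  )
  marg$age <- unlist(counts$overall$age)
  marg$total <- counts$total
  marg
}
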