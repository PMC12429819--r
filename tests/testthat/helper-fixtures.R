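# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; no data files.

# hand-buildable cohort: supply vectors, defaults fill the rest
make_cohort <- function(n,
                        age = rep(50, n),
                        gender = rep("female", n),
                        witness_type = rep("not_witnessed", n),
                        arrest_location = rep("home", n),
                        call_time = rep("t00_05", n),
                        first_rhythm = rep("non_shockable", n),
                        alert_issued = rep(0L, n),
                        bcpr = rep(0L, n),
                        allow_missing = TRUE) {
  df <- data.frame(case_id = seq_len(n), age = age, gender = gender,
                   witness_type = witness_type,
                   arrest_location = arrest_location, call_time = call_time,
                   first_rhythm = first_rhythm, alert_issued = alert_issued,
                   bcpr = bcpr, stringsAsFactors = FALSE)
  as_cohort(df, allow_missing = allow_missing)
}

# small random complete cohort with all levels represented
random_cohort <- function(n, seed) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    make_cohort(
      n,
      age = round(runif(n, 20, 95), 1),
      gender = sample(cohort_domains$gender, n, TRUE),
      witness_type = sample(cohort_domains$witness_type, n, TRUE),
      arrest_location = sample(cohort_domains$arrest_location, n, TRUE),
      call_time = sample(cohort_domains$call_time, n, TRUE),
      first_rhythm = sample(cohort_domains$first_rhythm, n, TRUE),
      alert_issued = sample(0:1, n, TRUE),
      bcpr = sample(0:1, n, TRUE)
    )
  })
}

# punch single-cell holes into a complete cohort (one per chosen row)
punch_holes <- function(tab, rows, vars) {
  stopifnot(length(rows) == length(vars))
  for (i in seq_along(rows)) tab[[vars[i]]][rows[i]] <- NA
  as_cohort(tab, allow_missing = TRUE)
}

# Brute-force Gower KNN oracle: pure-R exhaustive search, independent of the
# compiled kernel. Donor k-set by (distance, case_id); median/mode fill with
# ties towards the earlier domain level.
knn_oracle <- function(tab, k, use_outcome = TRUE) {
  vars <- c("age", "gender", "witness_type", "arrest_location", "call_time",
            "first_rhythm", "alert_issued", if (use_outcome) "bcpr")
  age_rng <- diff(range(tab$age, na.rm = TRUE))
  if (!(age_rng > 0)) age_rng <- 1
  out <- tab
  for (i in seq_len(nrow(tab))) {
    for (v in c("age", "witness_type", "call_time")) {
      if (!is.na(tab[[v]][i])) next
      donors <- which(!is.na(tab[[v]]) & seq_len(nrow(tab)) != i)
      d <- vapply(donors, function(r) {
        gower_distance(tab[i, ], tab[r, ],
                       numeric_ranges = c(age = age_rng),
                       variables = setdiff(vars, v))
      }, numeric(1))
      ord <- order(d, tab$case_id[donors])
      sel <- donors[ord][seq_len(min(k, length(donors)))]
      if (v == "age") {
        out$age[i] <- stats::median(tab$age[sel])
      } else {
        lv <- levels(tab[[v]])
        cts <- table(factor(as.character(tab[[v]][sel]), levels = lv))
        out[[v]][i] <- lv[which.max(cts)]
      }
    }
  }
  as_cohort(out)
}
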