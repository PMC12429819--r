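# a 6-row table with one gap per amputable variable, for hand-checks
toy_gapped <- function() {
  tab <- make_cohort(
    6,
    age = c(20, 30, NA, 40, 50, 60),
    gender = c("female", "male", "female", "male", "female", "male"),
    witness_type = c("family", "lay", "lay", NA, "family", "not_witnessed"),
    arrest_location = c("home", "public", "home", "home", "public", "home"),
    call_time = c("t00_05", "t06_18", "t06_18", "t19_23", NA, "t06_18"),
    first_rhythm = c("non_shockable", "shockable", "unknown", "non_shockable",
                     "non_shockable", "shockable"),
    alert_issued = c(0L, 1L, 0L, 1L, 0L, 1L),
    bcpr = c(0L, 1L, 1L, 0L, 1L, 0L)
  )
  tab
}

test_that("mean/mode imputation fills with the documented statistics", {
  tab <- toy_gapped()
  imp <- impute_mean_mode(tab)
  expect_s3_class(imp, "imputed_cohort")
  expect_identical(imp$method, "mm")
  expect_equal(imp$table$age[3], mean(c(20, 30, 40, 50, 60)))
  # witness gaps -> mode of observed (family x2, lay x2, not_witnessed x1):
  # tie between family and lay resolved towards the earlier domain level;
  # the domain order is (not_witnessed, family, healthcare, lay), so family
  expect_identical(as.character(imp$table$witness_type[4]), "family")
  expect_identical(as.character(imp$table$call_time[5]), "t06_18")
  expect_false(anyNA(imp$table))
  # fully missing column is an error naming the column
  bad <- make_cohort(3, age = c(NA_real_, NA_real_, NA_real_))
  expect_error(impute_mean_mode(bad), "age")
})

test_that("mean imputation shrinks the variance of the imputed column", {
  complete <- generate_model_based(4000, seed = 14)$cohort
  amp <- ampute(complete, amputation_spec(0.3), seed = 15)
  imp <- impute_mean_mode(amp$table)
  expect_lt(var(imp$table$age), var(complete$age))
})

test_that("missingness-indicator fill matches the mask exactly", {
  tab <- toy_gapped()
  imp <- impute_missingness_indicator(tab)
  expect_setequal(imp$extra_terms,
                  c("age_missing", "witness_missing", "calltime_missing"))
  expect_identical(imp$table$age_missing, as.integer(is.na(tab$age)))
  expect_identical(imp$table$age[3], 0)
  expect_identical(as.character(imp$table$witness_type[4]), "missing")
  expect_identical(sum(imp$table$witness_type == "missing"),
                   sum(is.na(tab$witness_type)))
  # design matrix gains exactly the extra indicator columns
  X <- design_matrix(imp$table)
  expect_true(all(c("age_missing", "witness_missing", "calltime_missing")
                  %in% colnames(X)))
  expect_equal(sum(X[, "age_missing"]), sum(is.na(tab$age)))

  # identity case: no gaps -> same model terms as the base model
  comp <- random_cohort(20, seed = 16)
  imp0 <- impute_missingness_indicator(comp)
  expect_length(imp0$extra_terms, 0)
  expect_identical(colnames(design_matrix(imp0$table)),
                   colnames(design_matrix(comp)))
})

test_that("gower distance matches hand computations", {
  r1 <- list(age = 40, gender = "female", arrest_location = "home")
  r2 <- list(age = 60, gender = "female", arrest_location = "public")
  expect_equal(
    gower_distance(r1, r2, numeric_ranges = c(age = 80),
                   variables = c("age", "gender", "arrest_location")),
    (0.25 + 0 + 1) / 3
  )
  tab <- random_cohort(5, seed = 17)
  expect_equal(gower_distance(tab[1, ], tab[1, ]), 0)
  # all categoricals differ, continuous equal
  ra <- list(age = 50, gender = "female", arrest_location = "home",
             first_rhythm = "shockable")
  rb <- list(age = 50, gender = "male", arrest_location = "public",
             first_rhythm = "unknown")
  expect_equal(
    gower_distance(ra, rb, numeric_ranges = c(age = 10),
                   variables = c("age", "gender", "arrest_location", "first_rhythm")),
    3 / 4
  )
  # ordinal call time: adjacent levels are half the full range apart
  expect_equal(
    gower_distance(list(call_time = "t00_05"), list(call_time = "t06_18"),
                   variables = "call_time"),
    0.5
  )
  expect_error(gower_distance(list(age = NA), list(age = 50), variables = "age"),
               "no usable")
})

test_that("knn imputation donates from the nearest matching row", {
  # row 3 misses age; rows 1, 2, 4 donate; row 1 matches row 3 on every
  # other variable, rows 2 and 4 mismatch several -> k = 1 takes row 1
  tab <- make_cohort(
    4,
    age = c(25, 80, NA, 70),
    gender = c("female", "male", "female", "male"),
    witness_type = c("family", "lay", "family", "not_witnessed"),
    arrest_location = c("home", "public", "home", "public"),
    call_time = c("t00_05", "t19_23", "t00_05", "t06_18"),
    first_rhythm = c("non_shockable", "shockable", "non_shockable", "unknown"),
    alert_issued = c(0L, 1L, 0L, 1L),
    bcpr = c(1L, 0L, 1L, 0L)
  )
  imp <- impute_knn(tab, k = 1)
  expect_identical(imp$table$age[3], 25)
  # k covering all donors degenerates to the overall donor median
  imp_all <- suppressWarnings(impute_knn(tab, k = 10))
  expect_identical(imp_all$table$age[3], median(c(25, 80, 70)))
  expect_warning(impute_knn(tab, k = 10), "donors")
  # deterministic given the table
  expect_identical(impute_knn(tab, k = 1)$table, imp$table)
})

test_that("knn equals the brute-force oracle on small tables", {
  for (seed in c(31, 32, 33)) {
    tab <- random_cohort(25, seed = seed)
    set.seed(seed + 1000)
    rows <- sample(25, 6)
    vars <- sample(c("age", "witness_type", "call_time"), 6, replace = TRUE)
    gapped <- punch_holes(tab, rows, vars)
    for (k in c(1, 3, 5)) {
      got <- impute_knn(gapped, k = k)$table
      want <- knn_oracle(gapped, k = k)
      expect_equal(got$age, want$age, label = sprintf("seed %d k %d age", seed, k))
      expect_identical(as.character(got$witness_type),
                       as.character(want$witness_type),
                       label = sprintf("seed %d k %d witness", seed, k))
      expect_identical(as.character(got$call_time),
                       as.character(want$call_time),
                       label = sprintf("seed %d k %d calltime", seed, k))
    }
  }
})

test_that("missforest recovers a planted deterministic relation", {
  set.seed(41)
  n <- 2000
  loc <- sample(cohort_domains$arrest_location, n, TRUE)
  tab <- make_cohort(
    n,
    age = round(runif(n, 20, 95), 1),
    gender = sample(cohort_domains$gender, n, TRUE),
    witness_type = ifelse(loc == "home", "family", "lay"),  # planted rule
    arrest_location = loc,
    call_time = sample(cohort_domains$call_time, n, TRUE),
    first_rhythm = sample(cohort_domains$first_rhythm, n, TRUE),
    alert_issued = sample(0:1, n, TRUE),
    bcpr = sample(0:1, n, TRUE)
  )
  spec <- amputation_spec(0.2, pattern_freqs = c(age = 0, witness_type = 1,
                                                 call_time = 0))
  amp <- ampute(tab, spec, seed = 42)
  gap <- is.na(amp$table$witness_type)
  imp <- impute_missforest(amp$table, seed = 43)
  acc_mf <- mean(imp$table$witness_type[gap] == tab$witness_type[gap])
  expect_gte(acc_mf, 0.95)
  # and beats mean/mode on the same toy, in aggregate over seeds
  hits_mf <- 0; hits_mm <- 0
  for (s in 1:20) {
    a <- ampute(tab, spec, seed = 200 + s)
    g <- is.na(a$table$witness_type)
    hits_mf <- hits_mf +
      sum(impute_missforest(a$table, seed = 300 + s)$table$witness_type[g] ==
            tab$witness_type[g])
    hits_mm <- hits_mm +
      sum(impute_mean_mode(a$table)$table$witness_type[g] == tab$witness_type[g])
  }
  expect_gt(hits_mf, hits_mm)
})

test_that("missforest is seed-deterministic and is the identity without gaps", {
  comp <- random_cohort(60, seed = 44)
  expect_identical(impute_missforest(comp, seed = 1)$table, comp)
  gapped <- punch_holes(random_cohort(120, seed = 45),
                        rows = c(3, 20, 50, 90),
                        vars = c("age", "witness_type", "call_time", "age"))
  i1 <- impute_missforest(gapped, n_trees = 20, seed = 46)
  i2 <- impute_missforest(gapped, n_trees = 20, seed = 46)
  expect_identical(i1$table, i2$table)
})

test_that("all imputers preserve observed cells, row count and order", {
  complete <- generate_model_based(1500, seed = 47)$cohort
  amp <- ampute(complete, amputation_spec(0.3), seed = 48)
  obs <- !is.na(amp$table[, cohort_columns])
  imps <- list(
    mm = impute_mean_mode(amp$table),
    mxi = impute_missingness_indicator(amp$table),
    knn = impute_knn(amp$table),
    mf = impute_missforest(amp$table, n_trees = 30, seed = 49)
  )
  for (nm in names(imps)) {
    out <- imps[[nm]]$table
    expect_identical(nrow(out), nrow(amp$table))
    expect_identical(out$case_id, amp$table$case_id)
    for (v in cohort_columns) {
      o <- obs[, v]
      a <- out[[v]][o]; b <- amp$table[[v]][o]
      if (is.factor(a)) { a <- as.character(a); b <- as.character(b) }
      expect_identical(a, b, label = paste(nm, "preserves", v))
    }
    if (nm != "mxi") {
      expect_false(anyNA(out))
      for (v in names(cohort_domains)) {
        expect_true(all(as.character(out[[v]]) %in% cohort_domains[[v]]))
      }
    }
  }
})
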