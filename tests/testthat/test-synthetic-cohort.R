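test_that("table-faithful generator reproduces every printed count at scale 1", {
  counts <- table1_counts()
  tab <- generate_table_faithful(counts, scale = 1, seed = 11)

  expect_equal(nrow(tab), counts$total)
  expect_false(anyNA(tab))
  expect_false(anyDuplicated(tab$case_id) > 0)
  expect_true(all(tab$age >= 18 & tab$age <= 110))

  for (s in counts$strata) {
    sel <- tab$alert_issued == s$alert_issued & tab$bcpr == s$bcpr
    expect_identical(sum(sel), as.integer(s$n))
    for (v in names(cohort_domains)) {
      got <- table(tab[[v]][sel])
      for (lv in cohort_domains[[v]]) {
        expect_identical(unname(as.integer(got[lv])), as.integer(s[[v]][[lv]]),
                         label = sprintf("stratum(a=%d,b=%d) %s=%s",
                                         s$alert_issued, s$bcpr, v, lv))
      }
    }
  }
  # printed spot checks: BCPR counts and the lay-witness cell
  expect_identical(sum(tab$bcpr), 8666L)
  expect_identical(sum(tab$alert_issued == 1), 6876L)
  expect_identical(sum(tab$bcpr[tab$alert_issued == 1]), 5883L)
  sel <- tab$alert_issued == 0 & tab$bcpr == 0
  expect_identical(sum(tab$witness_type[sel] == "lay"), 637L)
})

test_that("scaled-down generation keeps counts internally consistent", {
  counts <- table1_counts()
  tab <- generate_table_faithful(counts, scale = 0.25, seed = 3)
  expect_equal(nrow(tab), round(0.25 * counts$total))
  # per stratum, every covariate's level counts sum to the stratum size
  for (s in counts$strata) {
    sel <- tab$alert_issued == s$alert_issued & tab$bcpr == s$bcpr
    for (v in names(cohort_domains)) {
      expect_identical(sum(table(tab[[v]][sel])), sum(sel))
    }
  }
  expect_error(generate_table_faithful(counts, scale = 0), "scale")
  expect_error(generate_table_faithful(counts, scale = 1.2), "scale")
})

test_that("inconsistent stratum counts are rejected with the stratum named", {
  counts <- table1_counts()
  counts$strata[[2]]$gender[["male"]] <- counts$strata[[2]]$gender[["male"]] + 1L
  expect_error(validate_table1_counts(counts), "alert=1, bcpr=0")
  expect_error(generate_table_faithful(counts), "alert=1, bcpr=0")
})

test_that("generation is seed-deterministic, byte-for-byte through CSV", {
  t1 <- generate_table_faithful(scale = 0.1, seed = 5)
  t2 <- generate_table_faithful(scale = 0.1, seed = 5)
  t3 <- generate_table_faithful(scale = 0.1, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$age, t3$age))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(t1, f1); write_cohort_csv(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("model-based generator hits its target prevalence and recovers beta", {
  # null model: all beta zero, intercept zero -> prevalence ~ 0.5
  coefs0 <- true_coefficients(intercept = 0)
  coefs0$beta[] <- 0
  g0 <- generate_model_based(20000, coefs = coefs0, seed = 2)
  expect_lt(abs(mean(g0$cohort$bcpr) - 0.5), 3 * sqrt(0.25 / 20000))

  # determinism and error contracts
  expect_identical(generate_model_based(10, seed = 9)$cohort,
                   generate_model_based(10, seed = 9)$cohort)
  expect_error(generate_model_based(0), "n")
  expect_error(generate_model_based(10, target_prevalence = 1.2),
               "target_prevalence")

  # prevalence converges to the 0.653 target as n grows
  p1 <- mean(generate_model_based(1e3, seed = 4)$cohort$bcpr)
  p2 <- mean(generate_model_based(1e5, seed = 4)$cohort$bcpr)
  expect_lt(abs(p2 - 0.653), abs(p1 - 0.653) + 1e-12)

  # large-n MLE recovery of the generator coefficients (3 Wald SEs)
  gen <- generate_model_based(2e5, seed = 7)
  fit <- fit_association(gen$cohort, method = "cc")
  cf <- fit$coefficients
  for (tm in model_terms) {
    i <- match(tm, cf$term)
    expect_lt(abs(cf$beta[i] - gen$coefs$beta[[tm]]), 3 * cf$se[i],
              label = paste("recovery of", tm))
  }
  expect_lt(abs(cf$beta[1] - gen$coefs$intercept), 3 * cf$se[1])
})

test_that("intercept calibration is exact, closed-form consistent and permutation-invariant", {
  tab <- random_cohort(500, seed = 21)
  beta0 <- true_coefficients()$beta
  beta0[] <- 0
  expect_equal(calibrate_intercept(tab, beta0, 0.653), qlogis(0.653),
               tolerance = 1e-9)
  expect_equal(calibrate_intercept(tab, beta0, 0.5), 0, tolerance = 1e-9)

  beta <- true_coefficients()$beta
  a <- calibrate_intercept(tab, beta, 0.653)
  X <- design_matrix(tab, intercept = FALSE)
  expect_lt(abs(mean(plogis(a + drop(X %*% beta[colnames(X)]))) - 0.653), 1e-8)

  perm <- tab[sample.int(nrow(tab)), ]
  expect_equal(calibrate_intercept(perm, beta, 0.653), a, tolerance = 1e-10)
})

test_that("age sampler respects truncation and roughly matches printed quartiles", {
  set.seed(31)
  x <- sample_age(20000, q1 = 58, med = 70, q3 = 82)
  expect_true(all(x >= 18 & x <= 110))
  q <- quantile(x, c(0.25, 0.5, 0.75))
  # truncation shifts the fitted quantiles slightly; a 2-year box is enough
  expect_lt(abs(q[[2]] - 70), 2)
  expect_lt(abs(q[[1]] - 58), 2)
  expect_lt(abs(q[[3]] - 82), 2)
})
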