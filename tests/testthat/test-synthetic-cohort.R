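test_that("feature-level cohort reproduces class-conditional moments and signs", {
  spec <- cohort_spec(10000, 10000, seed = 101)
  coh <- generate_feature_cohort(spec)
  expect_equal(nrow(coh), 20000)
  surv <- coh[coh$outcome == "survivor", ]
  dead <- coh[coh$outcome == "death", ]
  d <- table_feature_distributions()
  expect_equal(mean(surv$sdnn), 96.22, tolerance = 0.01)
  expect_equal(mean(dead$sdnn), 64.52, tolerance = 0.01)
  for (f in d$feature) {
    expect_equal(mean(surv[[f]]), d$mean_survivor[d$feature == f],
                 tolerance = 0.02)
    expect_equal(sd(surv[[f]]), d$sd_survivor[d$feature == f],
                 tolerance = 0.03)
  }
  # physical admissibility after truncation
  expect_true(all(coh$sdnn > 0) && all(coh$mean_nn > 0))
  expect_true(all(coh$dc > 0) && all(coh$ac < 0))
  expect_true(all(coh$lvef > 0 & coh$lvef < 1))
  # determinism
  coh2 <- generate_feature_cohort(cohort_spec(10000, 10000, seed = 101))
  expect_identical(coh, coh2)
})

test_that("degenerate near-zero spread collapses every row onto the class mean", {
  d <- table_feature_distributions()
  d$sd_survivor[] <- 1e-6
  d$sd_death[] <- 1e-6
  coh <- generate_feature_cohort(cohort_spec(5, 5, distributions = d, seed = 3))
  surv <- coh[coh$outcome == "survivor", d$feature]
  for (f in d$feature)
    expect_equal(unname(unlist(surv[[f]])),
                 rep(d$mean_survivor[d$feature == f], 5), tolerance = 1e-3)
})

test_that("invalid cohort specifications are rejected with explanations", {
  expect_error(cohort_spec(0, 0), "at least 2")
  bad <- diag(8); bad[1, 2] <- bad[2, 1] <- 1.5   # not PSD
  expect_error(cohort_spec(5, 5, correlation = bad), "positive-semidefinite")
  asym <- diag(8); asym[1, 2] <- 0.5
  expect_error(cohort_spec(5, 5, correlation = asym), "symmetric")
  d <- table_feature_distributions(); d$sd_death[1] <- 0
  expect_error(cohort_spec(5, 5, distributions = d), "> 0")
})

test_that("noiseless tachogram is exact and beat count scales with duration", {
  p <- rr_profile(mean_nn = 1000, circadian_amplitude = 0, short_term_sd = 0,
                  long_term_sd = 0, vpc_rate = 0, duration = 1, seed = 1)
  s <- generate_rr_series(p)
  expect_equal(nrow(s), 3600)
  expect_true(all(s$rr == 1000) && all(s$label == "N"))
  expect_equal(s$t, cumsum(s$rr))
  # variable profile: count still approximately duration * 3600e3 / mean_nn
  s2 <- generate_rr_series(rr_profile(mean_nn = 900, duration = 2, seed = 5))
  expect_equal(nrow(s2), round(2 * 3600 * 1000 / 900))
  expect_true(all(s2$rr > 0) && all(s2$label %in% c("N", "V")))
  expect_error(generate_rr_series(rr_profile(duration = -1)), "duration")
})

test_that("ectopy count is Poisson-consistent and episodes carry coupling + pause", {
  p <- rr_profile(vpc_rate = 10, duration = 24, coupling_fraction = 0.6,
                  seed = 42)
  s <- generate_rr_series(p)
  nv <- sum(s$label == "V")
  expect_true(abs(nv - 240) < 4 * sqrt(240))     # within Poisson error
  iv <- which(s$label == "V")[1]
  ref <- mean(s$rr[(iv - 2):(iv - 1)])
  expect_equal(s$rr[iv], 0.6 * ref)              # shortened coupling interval
  expect_equal(s$rr[iv + 1], 2 * ref - s$rr[iv]) # fully compensatory pause
})

test_that("artifact injection corrupts an exact count and leaves the input alone", {
  s <- generate_rr_series(rr_profile(mean_nn = 1000, duration = 1000 / 3600,
                                     vpc_rate = 0, seed = 2))
  expect_equal(nrow(s), 1000)
  expect_identical(inject_artifacts(s, 0), s)
  s2 <- inject_artifacts(s, 0.25, seed = 7)
  expect_equal(sum(s2$label == "X"), 250)
  expect_true(all(s$label == "N"))               # original untouched
  # corrupted series trips the sinus gate
  expect_false(sinus_fraction_gate(s2, 0.80)$pass)
  expect_true(sinus_fraction_gate(s, 0.80)$pass)
})

test_that("RR files round-trip through write and read", {
  s <- generate_rr_series(rr_profile(duration = 0.2, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_file(s, path)
  s2 <- read_rr_file(path)
  expect_equal(s2$rr, s$rr)
  expect_equal(s2$label, s$label)
  expect_equal(s2$t, s$t)
})
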