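make_vpc_series <- function(n_vpc = 1, to = 0, ts = 0, n = 200, coupling = 480) {
  rr <- rep(800, n)
  label <- rep("N", n)
  at <- seq(30, by = 30, length.out = n_vpc)
  for (a in at) {
    out <- plant_vpc(rr, label, a, coupling = coupling, to = to, ts = ts)
    rr <- out$rr; label <- out$label
  }
  rr_series(rr, label)
}

test_that("episode detection applies the eligibility and contamination rules", {
  expect_length(find_vpc_episodes(rr_series(rep(800, 100))), 0)

  s <- make_vpc_series(n_vpc = 5)
  ep <- find_vpc_episodes(s)
  expect_length(ep, 5)
  expect_equal(ep[[1]]$coupling, 480)
  expect_equal(ep[[1]]$pause, 1120)
  expect_equal(ep[[1]]$pre_rr, c(800, 800))

  # a second V inside the post-window disqualifies the episode
  s2 <- make_vpc_series(n_vpc = 1)
  iv <- which(s2$label == "V")
  s2$label[iv + 8] <- "V"
  expect_length(find_vpc_episodes(s2), 0)

  # long coupling interval (not premature enough) is ineligible
  s3 <- make_vpc_series(n_vpc = 1, coupling = 700)
  expect_length(find_vpc_episodes(s3), 0)

  # an artifact beat in the pre-window disqualifies the episode
  s4 <- make_vpc_series(n_vpc = 1)
  iv <- which(s4$label == "V")
  s4$label[iv - 1] <- "X"
  expect_length(find_vpc_episodes(s4), 0)
})

test_that("turbulence onset follows the two-before/two-after formula", {
  ep <- list(list(pre_rr = c(800, 800), post_rr = c(800, 800, rep(800, 13))))
  expect_equal(turbulence_onset(ep), 0)
  ep <- list(list(pre_rr = c(800, 800), post_rr = c(760, 760, rep(800, 13))))
  expect_equal(turbulence_onset(ep), -5)
  # post-ectopic shortening (early acceleration) gives negative TO;
  # lengthening gives positive TO
  ep <- list(list(pre_rr = c(800, 800), post_rr = c(840, 840, rep(800, 13))))
  expect_gt(turbulence_onset(ep), 0)
  # recording value is the mean over episodes
  eps <- list(list(pre_rr = c(800, 800), post_rr = rep(760, 15)),
              list(pre_rr = c(800, 800), post_rr = rep(800, 15)))
  expect_equal(turbulence_onset(eps), -2.5)
  expect_error(turbulence_onset(list()), "no eligible")
})

test_that("turbulence slope is the maximum 5-beat regression over the averaged tachogram", {
  # exactly linear averaged tachogram: slope recovered exactly
  ep <- list(list(post_rr = 800 + 10 * (1:15)))
  expect_equal(turbulence_slope(ep), 10)
  # flat, then a ramp of slope 20 spanning beats 8-12
  tach <- c(rep(800, 7), 800 + 20 * (1:5), rep(900, 3))
  expect_equal(turbulence_slope(list(list(post_rr = tach))), 20)
  # equals exhaustive window enumeration on random tachograms
  for (k in 1:50) {
    set.seed(k)
    tach <- runif(15, 700, 1000)
    expect_equal(turbulence_slope(list(list(post_rr = tach))), bf_ts(tach),
                 tolerance = 1e-10)
  }
  # averaging over episodes happens before the regression
  e1 <- list(post_rr = c(rep(800, 7), 800 + 30 * (1:5), rep(950, 3)))
  e2 <- list(post_rr = c(rep(800, 7), 800 + 10 * (1:5), rep(850, 3)))
  expect_equal(turbulence_slope(list(e1, e2)), 20)
})

test_that("injected turbulence parameters are recovered from noiseless tachograms", {
  p <- rr_profile(mean_nn = 900, circadian_amplitude = 0, short_term_sd = 0,
                  long_term_sd = 0, vpc_rate = 8,
                  turbulence_onset_true = -2.5, turbulence_slope_true = 15,
                  duration = 4, seed = 21)
  h <- hrt_features(generate_rr_series(p))
  expect_true(h$available)
  expect_gt(h$n_episodes, 0)
  expect_equal(h$to, -2.5, tolerance = 1e-8)
  expect_equal(h$ts, 15, tolerance = 1e-8)
})

test_that("recordings without ventricular ectopy carry no turbulence value", {
  s <- generate_rr_series(rr_profile(vpc_rate = 0, duration = 0.5, seed = 2))
  h <- hrt_features(s)
  expect_false(h$available)
  expect_equal(h$n_episodes, 0L)
  expect_true(is.na(h$to) && is.na(h$ts))
  # and no model configuration ever requests the turbulence columns
  for (m in c("hrv_complex", "dim6", "dim8"))
    expect_false(any(c("to", "ts") %in% feature_vector_config(m)$features))
})
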