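test_that("Fsk/IBMX normalization rescales to fraction of maximum", {
  tr <- fluor_trace(c(-1, 1, 2, 3, 4), c(1, 2, 3, 4, 4),
                    fsk_frames = 4:5)
  n <- fskibmx_normalize(tr)
  expect_equal(n$values, c(1, 2, 3, 4, 4) / 4)
  expect_equal(n$state, "fsk-normalized")
  # a trace equal to its Fsk mean everywhere maps to all 1
  tr2 <- fluor_trace(1:4, rep(6, 4), fsk_frames = 3:4)
  expect_equal(fskibmx_normalize(tr2)$values, rep(1, 4))
  expect_error(fskibmx_normalize(fluor_trace(1:3, c(1, 2, 3))), "fsk_frames")
  expect_error(fskibmx_normalize(fluor_trace(1:3, c(1, 2, -3),
                                             fsk_frames = 3L)), "positive")
})

test_that("normalized plateau recovers p*A/S from simulated traces", {
  kin <- kinetic_config(noise_sd = 0, amplitude_cv = 0, amplitude = 1.4,
                        plateau_fraction = 0.35, fsk_level = 2.8)
  sim <- simulate_biosensor_trace(kin)
  n <- fskibmx_normalize(sim$trace)
  expect_equal(plateau_value(n), 0.35 * 1.4 / 2.8, tolerance = 0.01)
})

test_that("phase integration matches closed forms and is additive", {
  # zero trace and constant trace
  z <- fluor_trace(seq(-1, 31, by = 1 / 3), rep(0, 97))
  expect_equal(integrate_phase(z, 0, 30), 0)
  cst <- fluor_trace(seq(-1, 31, by = 1 / 3), rep(1, 97))
  expect_equal(integrate_phase(cst, 0, 5), 5.0, tolerance = 1e-12)
  # exponential decay at 20 s sampling vs closed form, within 1%
  for (tau in c(2, 4, 8)) {
    tt <- seq(0, 30, by = 1 / 3)
    tr <- fluor_trace(tt, 1.7 * exp(-tt / tau))
    expect_equal(integrate_phase(tr, 0, 30),
                 1.7 * tau * (1 - exp(-30 / tau)), tolerance = 0.01)
  }
  # additivity with interpolated boundaries, and with 5 min off-grid
  set.seed(601)
  for (rep in 1:10) {
    tt <- sort(c(-2, 32, runif(58, -2, 32)))
    tr <- fluor_trace(tt, rnorm(60))
    a <- integrate_phase(tr, 0, 5); b <- integrate_phase(tr, 5, 30)
    expect_equal(a + b, integrate_phase(tr, 0, 30), tolerance = 1e-9)
  }
  expect_error(integrate_phase(cst, -5, 40), "span")
})

test_that("peak and plateau follow their window conventions", {
  tr <- fluor_trace(c(-1, 1, 2, 3), c(0, 1, 3, 2))
  pk <- peak_value(tr)
  expect_equal(pk$value, 3); expect_equal(pk$time_min, 2)
  # monotone increasing trace peaks at the last in-window sample
  tt <- seq(-1, 31, by = 1 / 3)
  inc <- fluor_trace(tt, tt + 1)
  expect_equal(peak_value(inc, c(0, 30))$value, 31)
  # pre-agonist samples never win even if larger
  tr2 <- fluor_trace(c(-1, 1, 2), c(10, 1, 2))
  expect_equal(peak_value(tr2)$value, 2)
  # ties report the earliest time
  tr3 <- fluor_trace(c(1, 2, 3), c(5, 5, 1))
  expect_equal(peak_value(tr3)$time_min, 1)
  # plateau: mean over [20, 30] inclusive
  expect_equal(plateau_value(fluor_trace(tt, rep(4.2, length(tt)))), 4.2)
  ramp <- fluor_trace(seq(20, 30, by = 0.01), seq(0, 1, length.out = 1001))
  expect_equal(plateau_value(ramp), 0.5, tolerance = 0.01)
  # grid oracle on a simulated noiseless trace
  kin <- kinetic_config(noise_sd = 0, amplitude_cv = 0)
  sim <- simulate_biosensor_trace(kin)
  sel <- sim$truth$times_min >= 20 & sim$truth$times_min <= 30
  expect_equal(plateau_value(sim$trace), mean(sim$truth$r_t[sel]),
               tolerance = 1e-9)
  inwin <- sim$truth$times_min > 0 & sim$truth$times_min <= 30
  expect_equal(peak_value(sim$trace)$value, max(sim$truth$r_t[inwin]))
})

test_that("summaries scale linearly with the trace", {
  kin <- kinetic_config(noise_sd = 0, amplitude_cv = 0)
  sim <- simulate_biosensor_trace(kin)
  s1 <- summarize_phases(sim$trace)
  tr2 <- fluor_trace(sim$trace$times_min, sim$trace$values * 2.5)
  s2 <- summarize_phases(tr2)
  for (col in c("auc_early", "auc_late", "auc_total", "peak", "plateau"))
    expect_equal(s2[[col]], 2.5 * s1[[col]], tolerance = 1e-12)
  expect_equal(s1$auc_total, s1$auc_early + s1$auc_late, tolerance = 1e-9)
  expect_lte(s1$plateau, s1$peak)
})

test_that("condition normalization maps the reference mean to 1", {
  df <- data.frame(condition = rep(c("ref", "mut"), each = 3),
                   plateau = c(1.5, 2.0, 2.5, 0.8, 1.0, 1.2),
                   peak = c(3, 4, 5, 3.5, 4.5, 4.0))
  n <- normalize_to_condition(df, "ref", stats = c("plateau", "peak"))
  expect_equal(mean(n$plateau[n$condition == "ref"]), 1.0)
  expect_equal(n$plateau[4], 0.8 / 2.0)
  expect_error(normalize_to_condition(df, "absent"), "not present")
  # two simulated conditions with true plateau ratio 0.5
  mk <- function(p, seeds) vapply(seeds, function(s) {
    sim <- simulate_biosensor_trace(kinetic_config(plateau_fraction = p,
                                                   seed = s))
    summarize_phases(sim$trace)$plateau
  }, 0)
  a <- mk(0.4, 1:9); b <- mk(0.2, 101:109)
  df <- data.frame(condition = rep(c("wt", "mut"), each = 9),
                   plateau = c(a, b))
  n <- normalize_to_condition(df, "wt", stats = "plateau")
  ratio <- mean(n$plateau[n$condition == "mut"])
  expect_lt(abs(ratio - 0.5), 0.12)  # sampling error at n = 9
})

test_that("ROI traces recover painted responses", {
  kin <- kinetic_config(noise_sd = 0, amplitude_cv = 0, fsk_epoch_duration = 0)
  times <- seq(-1, 30, by = 1 / 3)
  r_t <- biosensor_response(times, kin)
  n_t <- length(times)
  px <- array(0, c(n_t, 1, 1, 16, 16))
  roi <- matrix(FALSE, 16, 16); roi[5:12, 5:12] <- TRUE
  f0 <- 50; bg <- 10
  for (t in seq_len(n_t)) {
    fr <- matrix(bg, 16, 16)
    fr[roi] <- bg + f0 * (1 + r_t[t])   # linear fluorescence model
    px[t, 1, 1, , ] <- fr
  }
  mv <- image_stack(px, calibration(0.1, frame_interval = 20,
                                    agonist_frame = 4L))
  tr <- roi_trace(mv, roi)
  expect_equal(tr$values, r_t, tolerance = 1e-9)
  # constant movie -> dF/F0 identically 0
  cst <- image_stack(array(7, c(5, 1, 1, 8, 8)),
                     calibration(0.1, agonist_frame = 3L))
  roi8 <- matrix(FALSE, 8, 8); roi8[3:6, 3:6] <- TRUE
  expect_equal(roi_trace(cst, roi8, background = 0)$values, rep(0, 5))
  expect_error(roi_trace(mv, matrix(FALSE, 16, 16)), "empty")
})
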