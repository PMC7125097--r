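test_that("lassen_flow follows the piecewise pressure-flow curve", {
  expect_equal(lassen_flow(60, 45, 100, 2), 100)   # on the plateau
  expect_equal(lassen_flow(45, 45, 100, 2), 100)   # continuous at the limit
  expect_equal(lassen_flow(35, 45, 100, 2), 80)    # passive segment
  expect_equal(lassen_flow(0, 45, 100, 3), 0)      # floored at zero
  expect_error(lassen_flow(50, -1, 100, 2), "configuration")
  expect_error(lassen_flow(50, 45, 0, 2), "configuration")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(abp_end = 50, lla_true = 45), "abp_end < lla_true")
  expect_error(sim_config(slow_wave_band = c(0.05, 0.007)), "slow_wave_band")
  expect_error(sim_config(slow_wave_band = c(0.01, 0.9)), "Nyquist")
  expect_error(sim_config(noise_sd = c(abp = -1, icp = 1, rso2 = 1,
                                       rthb = 1, ldf = 1)), "noise_sd")
  expect_error(sim_config(abpopt_true = 40), "abpopt_true")
})

test_that("recordings are bit-identical under a fixed seed", {
  r1 <- generate_recording(sim_config(seed = 7))
  r2 <- generate_recording(sim_config(seed = 7))
  expect_identical(r1$recording$abp, r2$recording$abp)
  expect_identical(r1$recording$ldf, r2$recording$ldf)
  expect_identical(r1$truth$regime, r2$truth$regime)
  r3 <- generate_recording(sim_config(seed = 8))
  expect_false(identical(r1$recording$abp, r3$recording$abp))
})

test_that("noise-free, wave-free recording is the deterministic ramp response", {
  cfg <- sim_config(slow_wave_amp = 0,
                    noise_sd = c(abp = 0, icp = 0, rso2 = 0, rthb = 0, ldf = 0),
                    drift_sd = c(abp = 0, icp = 0, rso2 = 0, rthb = 0, ldf = 0),
                    seed = 1)
  r <- generate_recording(cfg)
  ramp <- r$recording$abp
  expect_equal(r$recording$ldf,
               lassen_flow(ramp, cfg$lla_true, cfg$plateau_flow,
                           cfg$passive_slope))
  expect_equal(r$recording$icp, rep(cfg$icp_baseline, length(ramp)))
  expect_equal(r$recording$rthb, rep(cfg$rthb_baseline, length(ramp)))
  expect_equal(r$recording$rso2,
               pmin(100, pmax(0, 50 + 20 * (r$recording$ldf - 100) / 100)))
})

test_that("slow waves concentrate their power inside the configured band", {
  set.seed(42)
  for (rep in 1:3) {
    x <- slow_waves(14400, band = c(0.007, 0.05), amp = 3, k = 8)
    pg <- Mod(fft(x))^2
    f <- (seq_along(pg) - 1) / length(pg)  # cycles per sample at 1 Hz
    half <- f <= 0.5
    inband <- half & f >= 0.007 & f <= 0.05
    expect_gt(sum(pg[inband]) / sum(pg[half]), 0.8)
  }
})

test_that("rTHb couples against ABP above the LLA and with it below", {
  r <- generate_recording(sim_config(seed = 11))
  abp <- block_means(r$recording$abp, 10L)
  rthb <- block_means(r$recording$rthb, 10L)
  above <- r$truth$regime == "above"
  # detrend the ramp/drift before correlating so the slow waves dominate
  dt_res <- function(v, sel) resid(lm(v[sel] ~ poly(seq_len(sum(sel)), 3)))
  expect_lt(cor(dt_res(abp, above), dt_res(rthb, above)), 0)
  expect_gt(cor(dt_res(abp, !above), dt_res(rthb, !above)), 0)
})

test_that("recording structure and physiological ranges hold", {
  r <- generate_recording(sim_config(seed = 3, sample_rate_hz = 4))
  rec <- r$recording
  lens <- vapply(list(rec$abp, rec$icp, rec$rso2, rec$rthb, rec$ldf),
                 length, integer(1))
  expect_true(all(lens == lens[1]))
  expect_equal(length(rec$time_s), lens[1])
  expect_true(all(rec$rso2 >= 0 & rec$rso2 <= 100))
  expect_gt(r$truth$abpopt_true, r$truth$lla_true)
  expect_true(r$truth$time_of_lla_crossing > 0 &&
                r$truth$time_of_lla_crossing < sim_config()$duration_s)
})

test_that("recording CSV and ground-truth JSON round-trip", {
  r <- generate_recording(sim_config(seed = 5, duration_s = 3600))
  f <- tempfile(fileext = ".csv")
  write_recording_csv(r$recording, f)
  back <- read_recording_csv(f)
  expect_equal(back$abp, r$recording$abp, tolerance = 1e-9)
  expect_equal(back$ldf, r$recording$ldf, tolerance = 1e-9)
  expect_equal(back$sample_rate_hz, 1)
  fj <- tempfile(fileext = ".json")
  write_truth_json(r$truth, fj)
  tr <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(tr$lla_true, r$truth$lla_true)
  expect_equal(tr$abpopt_true, r$truth$abpopt_true)
  unlink(c(f, fj))
})

test_that("malformed recording CSVs are rejected with a schema error", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 1:5, abp_mmhg = 1:5), f, row.names = FALSE)
  expect_error(read_recording_csv(f), "schema error")
  unlink(f)
})
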