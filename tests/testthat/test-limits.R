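test_that("exact piecewise-linear data give the exact breakpoint", {
  abp <- seq(30, 60, by = 0.5)
  ldf <- ifelse(abp < 45, 2 * abp, 90)
  sw <- make_sw(abp = abp, ldf = ldf)
  est <- find_lla(sw)
  expect_equal(est$lla, 45, tolerance = 1e-9)
  expect_lt(est$sse, 1e-18)
  expect_equal(est$left$slope, 2, tolerance = 1e-9)
  expect_equal(est$right$slope, 0, tolerance = 1e-9)
})

test_that("a single straight line has no breakpoint", {
  abp <- seq(30, 60, by = 1)
  sw <- make_sw(abp = abp, ldf = 3 * abp + 7)
  expect_error(find_lla(sw), "degenerate-intersection")
})

test_that("insufficient data is a defined error", {
  expect_error(find_lla(make_sw(abp = rnorm(10, 50), ldf = rnorm(10))),
               "no-LLA")
  expect_error(find_lla(make_sw(abp = rnorm(50, 50, 1),
                                ldf = rnorm(50))), "no-LLA")  # span < 15
})

test_that("noisy Lassen data match the exhaustive lm-based split oracle", {
  set.seed(51)
  for (rep in 1:3) {
    abp <- runif(300, 25, 80)
    ldf <- lassen_flow(abp, 48, 100, 2) + rnorm(300, 0, 3)
    sw <- make_sw(abp = abp, ldf = ldf)
    est <- find_lla(sw)
    orc <- oracle_find_lla(abp, ldf)
    expect_equal(est$lla, orc$lla, tolerance = 1e-9)
    expect_equal(est$sse, orc$sse, tolerance = 1e-9)
    expect_lt(abs(est$lla - 48), 5)
  }
})

test_that("5-minute windows pair median ABP with mean index", {
  sw <- make_sw(abp = rep(60, 90))
  ix <- structure(data.frame(time_s = (1:90) * 10, value = rep(0.5, 90)),
                  class = c("index_series", "data.frame"))
  med <- median_abp_epochs(sw, ix)
  expect_equal(med$abp_median, rep(60, 3))
  expect_equal(med$index_mean, rep(0.5, 3))

  sw2 <- make_sw(abp = rep(c(40, 50, 60, 70, 80), each = 6))
  expect_equal(median_abp_epochs(sw2, NULL)$abp_median, 60)

  set.seed(52)
  abp <- rnorm(120, 60, 8)
  sw3 <- make_sw(abp = abp)
  med3 <- median_abp_epochs(sw3, NULL)
  for (w in 1:4) {
    expect_equal(med3$abp_median[w],
                 sort(abp[((w - 1) * 30 + 1):(w * 30)])[15:16] |> mean())
  }
  expect_equal(nrow(median_abp_epochs(make_sw(abp = rep(60, 10)), NULL)), 0L)
})

test_that("binning Fisher-transforms and groups into half-open 5-mmHg bins", {
  s <- data.frame(abp_median = c(52, 53), index_mean = c(0.5, 0.5))
  cur <- bin_index_curve(s)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$bin_lo, 50)
  expect_equal(cur$mean_z, atanh(0.5))
  expect_equal(cur$n, 2L)

  s2 <- data.frame(abp_median = 60, index_mean = 1.0)
  expect_equal(bin_index_curve(s2)$mean_z, atanh(0.99))  # clipped, finite

  set.seed(53)
  s3 <- data.frame(abp_median = runif(200, 10, 110),
                   index_mean = runif(200, -1, 1))
  cur3 <- bin_index_curve(s3)
  expect_true(all(cur3$bin_lo >= 20 & cur3$bin_hi <= 100))
  for (i in seq_len(nrow(cur3))) {
    sel <- s3$abp_median >= cur3$bin_lo[i] & s3$abp_median < cur3$bin_hi[i]
    expect_equal(cur3$mean_z[i],
                 mean(atanh(pmin(0.99, pmax(-0.99, s3$index_mean[sel])))),
                 tolerance = 1e-12)
    expect_equal(cur3$n[i], sum(sel))
  }
})

test_that("quadratic vertex fitting classifies shapes and matches oracle", {
  centers <- seq(32.5, 77.5, by = 5)
  exact <- data.frame(bin_center = centers,
                      mean_z = (centers - 50)^2 / 100, n = 5)
  class(exact) <- c("binned_index_curve", "data.frame")
  fit <- fit_u_vertex(exact)
  expect_equal(fit$vertex, 50, tolerance = 1e-9)
  expect_equal(fit$fit_error, 0, tolerance = 1e-9)
  expect_equal(fit$shape, "full_u")

  lin <- data.frame(bin_center = centers, mean_z = 2 - 0.02 * centers, n = 5)
  class(lin) <- c("binned_index_curve", "data.frame")
  fl <- fit_u_vertex(lin)
  expect_equal(fl$shape, "none")
  expect_true(is.na(fl$vertex))

  set.seed(54)
  noisy <- data.frame(bin_center = centers,
                      mean_z = (centers - 55)^2 / 150 + rnorm(10, 0, 0.05),
                      n = sample(3:10, 10, replace = TRUE))
  class(noisy) <- c("binned_index_curve", "data.frame")
  fn <- fit_u_vertex(noisy)
  orc <- oracle_quad_fit(noisy$bin_center, noisy$mean_z, noisy$n)
  expect_equal(fn$vertex, orc$vertex, tolerance = 1e-9)
  expect_equal(fn$a, unname(orc$a), tolerance = 1e-9)

  expect_error(fit_u_vertex(exact[1:3, ]), "no-fit")
})

test_that("fit error vanishes exactly when bins lie on the quadratic", {
  centers <- seq(40, 80, by = 5)
  on_curve <- data.frame(bin_center = centers,
                         mean_z = 0.002 * (centers - 61)^2 + 0.1,
                         n = rep(4, length(centers)))
  class(on_curve) <- c("binned_index_curve", "data.frame")
  expect_lt(fit_u_vertex(on_curve)$fit_error, 1e-10)
  off <- on_curve
  off$mean_z[3] <- off$mean_z[3] + 0.1
  expect_gt(fit_u_vertex(off)$fit_error, 1e-3)
})

test_that("multi-window ABPopt is the weighted average of window vertices", {
  # stationary U: ABP cycles through the 5-mmHg bin centres in 5-min blocks
  # and the index is an exact quadratic of the bin centre in Fisher-z, so
  # every window fits the same parabola and every vertex is exactly 62
  centers <- seq(42.5, 87.5, by = 5)
  n_win <- 50
  abp <- rep(rep(centers, length.out = n_win), each = 30)
  val <- tanh(0.0008 * (abp - 62)^2 + 0.05)
  n <- length(abp)
  sw <- make_sw(abp = abp)
  ix <- structure(data.frame(time_s = (1:n) * 10, value = val),
                  class = c("index_series", "data.frame"))
  est <- multiwindow_abpopt(ix, sw, lla = 40)
  expect_s3_class(est, "abpopt_estimate")
  verts <- est$windows$vertex[est$windows$weight > 0]
  expect_true(all(abs(verts - verts[1]) < 1e-6))   # unanimity across windows
  expect_equal(est$abpopt, verts[1], tolerance = 1e-9)
  expect_equal(est$abpopt, 62, tolerance = 1e-6)

  # final value recomputes from the per-window table (componentwise oracle)
  with(est$windows[est$windows$weight > 0 & is.finite(est$windows$vertex), ],
       expect_equal(est$abpopt, sum(weight * vertex) / sum(weight),
                    tolerance = 1e-12))
})

test_that("ABPopt uses only above-LLA data and degrades to missing", {
  set.seed(56)
  n <- 200   # < 2 h of above-LLA samples
  sw <- make_sw(abp = runif(n, 50, 80))
  ix <- structure(data.frame(time_s = (1:n) * 10, value = rnorm(n, 0, 0.1)),
                  class = c("index_series", "data.frame"))
  est <- multiwindow_abpopt(ix, sw, lla = 78)   # almost nothing above
  expect_true(is.na(est$abpopt))

  # weights: shorter windows and better fits weigh more
  r <- generate_recording(sim_config(seed = 57))
  an_sw <- block_average(r$recording)
  ixr <- moving_index(an_sw, "abp", "rthb", name = "HVx")
  est2 <- multiwindow_abpopt(ixr, an_sw, lla = find_lla(an_sw))
  w <- est2$windows
  expect_true(all(diff(w$hours) > 0))
  expect_equal(nrow(w), 12L)
  same_n <- w$n_samples == max(w$n_samples)
  expect_true(all(diff(w$weight[same_n]) <= 1e-12))  # longer nominal -> less
})
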