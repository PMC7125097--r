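test_that("above/below partition means match a masked-mean oracle", {
  n <- 100
  abp <- c(rep(60, 50), rep(40, 50))
  sw <- make_sw(abp = abp)
  ix <- structure(data.frame(time_s = (1:n) * 10,
                             value = c(rep(0.2, 50), rep(0.8, 50))),
                  class = c("index_series", "data.frame"))
  p <- paired_above_below(ix, sw, lla = 50)
  expect_equal(p$above, 0.2)
  expect_equal(p$below, 0.8)
  expect_true(p$complete)

  p1 <- paired_above_below(ix, sw, lla = 20)   # everything above
  expect_true(is.na(p1$below) && !p1$complete)

  set.seed(61)
  ix2 <- structure(data.frame(time_s = (1:n) * 10, value = runif(n, -1, 1)),
                   class = c("index_series", "data.frame"))
  p2 <- paired_above_below(ix2, sw, lla = 50)
  expect_equal(p2$above, mean(ix2$value[abp >= 50]), tolerance = 1e-12)
  expect_equal(p2$below, mean(ix2$value[abp < 50]), tolerance = 1e-12)
})

test_that("AUC equals pairwise concordance on trivial and random inputs", {
  expect_equal(roc_with_cutoff(c(1, 2, 3, 10, 11, 12),
                               c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_with_cutoff(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(62)
  for (rep in 1:5) {
    sc <- sample(1:6, 10, replace = TRUE)   # forces ties
    lab <- sample(c(TRUE, FALSE), 10, replace = TRUE, prob = c(.5, .5))
    if (length(unique(lab)) < 2) next
    expect_equal(roc_with_cutoff(sc, lab)$auc, oracle_auc(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(roc_with_cutoff(1:5, rep(TRUE, 5)), "single-class")
})

test_that("AUC and DeLong agree with pROC as an independent cross-check", {
  skip_if_not_installed("pROC")
  set.seed(63)
  lab <- rep(c(0, 1), each = 25)
  sa <- rnorm(50) + lab
  sb <- rnorm(50) + 0.5 * lab
  expect_equal(roc_with_cutoff(sa, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sa, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  ours <- delong_test(sa, sb, lab)
  theirs <- pROC::roc.test(pROC::roc(lab, sa, quiet = TRUE, direction = "<"),
                           pROC::roc(lab, sb, quiet = TRUE, direction = "<"),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p, theirs$p.value, tolerance = 1e-9)
})

test_that("Youden cutoff maximizes sensitivity + specificity with exact CIs", {
  set.seed(64)
  lab <- rep(c(FALSE, TRUE), each = 30)
  sc <- rnorm(60, mean = ifelse(lab, 1.2, 0))
  r <- roc_with_cutoff(sc, lab)
  j_all <- vapply(sort(unique(sc)), function(c0)
    mean(sc[lab] >= c0) + mean(sc[!lab] < c0) - 1, numeric(1))
  expect_equal(r$sensitivity + r$specificity - 1, max(j_all),
               tolerance = 1e-12)
  ci <- binom.test(round(r$sensitivity * sum(lab)), sum(lab))$conf.int
  expect_equal(r$sens_ci, as.numeric(ci), tolerance = 1e-12)
  expect_true(r$sens_ci[1] <= r$sensitivity && r$sensitivity <= r$sens_ci[2])
})

test_that("DeLong variance matches structural-component enumeration", {
  set.seed(65)
  lab <- rep(c(TRUE, FALSE), c(12, 15))
  sa <- rnorm(27) + lab
  sb <- 0.6 * sa + rnorm(27, 0, 0.8)
  dl <- delong_test(sa, sb, lab)
  expect_equal(dl$se^2, oracle_delong_var(sa, sb, lab), tolerance = 1e-9)

  self <- delong_test(sa, sa, lab)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)

  swap <- delong_test(sb, sa, lab)
  expect_equal(swap$diff, -dl$diff, tolerance = 1e-12)
  expect_equal(swap$p, dl$p, tolerance = 1e-12)
})

test_that("DeLong test holds its size under label permutation", {
  set.seed(66)
  n <- 60
  sa <- rnorm(n); sb <- rnorm(n)
  base_lab <- rep(c(TRUE, FALSE), each = n / 2)
  rej <- 0; nperm <- 2000
  for (i in seq_len(nperm)) {
    lab <- sample(base_lab)
    p <- delong_test(sa, sb, lab)$p
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nperm, 0.03)
  expect_lte(rej / nperm, 0.07)
})

test_that("paired t behaves classically and flags degeneracy", {
  x <- rnorm(10)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(x, x - 2), "degenerate")
  set.seed(67)
  a <- rnorm(20); b <- rnorm(20)
  res <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(abs(t_oracle), df = 19,
                                    lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Bland-Altman agreement statistics match direct computation", {
  a <- c(50, 55, 60, 65)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_upper - ba0$loa_lower, 0)

  ba2 <- bland_altman(a, a - 2)
  expect_equal(ba2$bias, 2)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(2, 2))

  set.seed(68)
  x <- rnorm(30, 60, 5); y <- x + rnorm(30, 1, 2)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean(x - y), tolerance = 1e-12)
  expect_equal(ba$loa_upper, mean(x - y) + 1.96 * sd(x - y),
               tolerance = 1e-12)
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
  expect_error(bland_altman(1:2, 2:3), "3 complete pairs")
})
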