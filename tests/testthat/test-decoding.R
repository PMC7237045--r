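test_that("z-scoring standardizes training data and reuses its statistics", {
  zs <- zscore_fit(cbind(a = c(1, 3), b = c(0, 10)))
  expect_equal(as.numeric(zs$z[, 1]), c(-1, 1) / sqrt(2))  # sample SD
  expect_equal(colMeans(zs$z), c(a = 0, b = 0))
  # an already-standardized matrix passes through unchanged
  x <- withr::with_seed(10, matrix(rnorm(50), 10, 5))
  xs <- scale(x)[, ]  # scale() uses the sample SD
  zs2 <- zscore_fit(xs)
  expect_equal(zs2$z, xs, ignore_attr = TRUE)
  # test transform uses training statistics
  tr <- matrix(c(0, 2, 4, 6), 4, 1)
  te <- matrix(c(10, 20), 2, 1)
  zt <- zscore_apply(te, zscore_fit(tr))
  expect_equal(as.numeric(zt), (c(10, 20) - 3) / sd(c(0, 2, 4, 6)))
  # constant neurons are flagged and zeroed
  zc <- zscore_fit(matrix(c(1, 1, 1, 2, 3, 4), 3, 2))
  expect_true(zc$constant[1])
  expect_equal(as.numeric(zc$z[, 1]), c(0, 0, 0))
})

test_that("raw-rate and z-scored rules classify identically", {
  withr::with_seed(11, {
    n <- 60
    x <- rbind(matrix(rnorm(n / 2 * 8, 0), n / 2, 8),
               matrix(rnorm(n / 2 * 8, 0.8), n / 2, 8))
    x[, 5] <- x[, 5] * 20 + 3  # un-standardized scales
    labels <- rep(c("low", "high"), each = n / 2)
  })
  zs <- zscore_fit(x)
  fit <- selnet:::fit_margin_rule(zs$z, labels)
  raw <- raw_weight_conversion(fit$xi, fit$eta, zs$mean, zs$sd)
  dec_z <- drop(zs$z %*% fit$xi) > fit$eta
  dec_r <- drop(x %*% raw$w) > raw$b
  expect_identical(dec_z, dec_r)            # exact decision equivalence
  # identity transform: all means 0, SDs 1
  id <- raw_weight_conversion(fit$xi, fit$eta, rep(0, 8), rep(1, 8))
  expect_equal(id$w, fit$xi)
  expect_equal(id$b, fit$eta)
})

test_that("rescaling a neuron rescales its raw weight but not decisions", {
  withr::with_seed(12, {
    n <- 80
    x <- rbind(matrix(rnorm(n / 2 * 6, 0), n / 2, 6),
               matrix(rnorm(n / 2 * 6, 0.7), n / 2, 6))
    labels <- rep(c("low", "high"), each = n / 2)
  })
  fit1 <- {
    zs <- zscore_fit(x)
    f <- selnet:::fit_margin_rule(zs$z, labels)
    c(raw_weight_conversion(f$xi, f$eta, zs$mean, zs$sd),
      list(dec = drop(zs$z %*% f$xi) > f$eta))
  }
  x2 <- x
  x2[, 3] <- 2 * x[, 3]  # doubling a neuron's rates
  fit2 <- {
    zs <- zscore_fit(x2)
    f <- selnet:::fit_margin_rule(zs$z, labels)
    c(raw_weight_conversion(f$xi, f$eta, zs$mean, zs$sd),
      list(dec = drop(zs$z %*% f$xi) > f$eta))
  }
  expect_equal(fit2$w[3], fit1$w[3] / 2, tolerance = 1e-6)
  expect_identical(fit1$dec, fit2$dec)
})

test_that("decoders find no signal in label-independent activity", {
  withr::with_seed(13, {
    r <- array(runif(30 * 50 * 80), c(30, 50, 80))
  })
  act <- fake_activity(r, labels = rep(c("low", "high"), each = 40))
  dec <- fit_population_decoder(act, group = "all", n_splits = 10, seed = 14)
  expect_gt(dec$accuracy, 35)
  expect_lt(dec$accuracy, 65)
})

test_that("decoders recover a strong embedded signal", {
  withr::with_seed(15, {
    n_tr <- 80
    lab <- rep(c("low", "high"), each = n_tr / 2)
    r <- array(runif(20 * 50 * n_tr, 0, 0.2), c(20, 50, n_tr))
    bump <- outer(rnorm(20), rep(0.15, 50))
    for (t in which(lab == "high")) r[, , t] <- r[, , t] + bump
  })
  act <- fake_activity(r, labels = lab)
  dec <- fit_population_decoder(act, group = "all", n_splits = 10, seed = 16)
  expect_gt(dec$accuracy, 90)
  # degenerate single-class training is rejected
  expect_error(selnet:::fit_margin_rule(matrix(rnorm(20), 10, 2),
                                        rep("high", 10)),
               "single class")
})

test_that("decoder groups respect membership rules", {
  withr::with_seed(17, {
    r <- array(runif(40 * 50 * 20), c(40, 50, 20))
  })
  is_exc <- rep(c(TRUE, FALSE), c(30, 10))
  input <- c(rep(TRUE, 6), rep(FALSE, 34))
  act <- fake_activity(r, labels = rep(c("low", "high"), each = 10),
                       is_exc = is_exc, input_mask = input)
  d_all <- fit_population_decoder(act, group = "all", n_splits = 2, seed = 1)
  expect_equal(d_all$members, 7:40)  # input-receiving neurons excluded
  d_inh <- fit_population_decoder(act, group = "inh", n_splits = 2, seed = 1)
  expect_equal(d_inh$members, 31:40)
  d_sub <- fit_population_decoder(act, group = "exc_sub", n_splits = 2,
                                  n_members = 5, seed = 1)
  expect_length(d_sub$members, 5)
  expect_true(all(d_sub$members %in% 7:30))
  # all-E-input layout: exclusion would empty the excitatory population
  act2 <- fake_activity(r, labels = rep(c("low", "high"), each = 10),
                        is_exc = is_exc,
                        input_mask = is_exc)
  d2 <- fit_population_decoder(act2, group = "all", n_splits = 2, seed = 1)
  expect_equal(d2$members, 1:40)
})

test_that("weight reports are calibrated on synthetic weights", {
  withr::with_seed(18, {
    w <- tibble::tibble(
      neuron = 1:420,
      type = rep(c("exc", "inh"), c(320, 100)),
      zweight = rnorm(420),
      raw_weight = rnorm(420)  # one normal distribution for E and I
    )
  })
  dec <- structure(list(weights = w), class = "population_decoder")
  rep_ <- weight_distribution_report(dec)
  expect_gt(rep_$p_exc_vs_inh, 0.05)   # no E/I difference to detect
  expect_gt(rep_$p_lilliefors, 0.001)  # normal weights look normal
  expect_equal(rep_$n_exc, 320)
})
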