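test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(auc_stat(c(1, 2, 3), c(2, 3, 4)), (6 + 0.5 * 2) / 9)
  expect_equal(auc_stat(1:3, 1:3), 0.5)           # equal multisets
  expect_equal(auc_stat(c(1, 2), c(5, 6)), 1)     # fully separated
  expect_equal(auc_stat(c(5, 6), c(1, 2)), 0)
  withr::with_seed(42, {
    for (rep in 1:20) {
      nl <- sample(2:50, 1)
      nh <- sample(2:50, 1)
      low <- sample(1:12, nl, replace = TRUE) + 0.1 * rbinom(nl, 1, 0.5)
      high <- sample(1:12, nh, replace = TRUE) + 0.1 * rbinom(nh, 1, 0.5)
      expect_equal(auc_stat(low, high), auc_brute(low, high))
      # swapping categories reflects the AUC
      expect_equal(auc_stat(high, low), 1 - auc_stat(low, high))
    }
  })
  expect_error(auc_stat(numeric(0), 1:3), "non-empty")
})

test_that("trial responses are window means of the rate tensor", {
  r <- array(0, c(2, 4, 3))
  r[1, , ] <- matrix(c(1, 2, 3, 4,
                       4, 3, 2, 1,
                       5, 5, 5, 5), 4, 3) / 10
  r[2, , ] <- 0.2
  act <- fake_activity(r, labels = c("low", "low", "high"))
  resp <- trial_responses(act, window = c(0, 4))
  expect_equal(resp[, 1], c(0.25, 0.25, 0.5))  # time-swapped trials agree
  expect_equal(resp[, 2], rep(0.2, 3))         # constant neuron
  resp2 <- trial_responses(act, window = c(2, 4))
  expect_equal(resp2[1, 1], mean(c(3, 4)) / 10)
})

test_that("shuffle bounds bracket 0.5 and match the null AUC width", {
  withr::with_seed(1, {
    resp <- matrix(rnorm(800 * 30), 800, 30)
  })
  is_high <- rep(c(FALSE, TRUE), each = 400)
  sb <- shuffle_bounds(resp, is_high, n_shuffles = 400, seed = 2)
  expect_true(all(sb$lo < 0.5 & sb$hi > 0.5))
  # Mann-Whitney null SD at 400 + 400 trials
  se <- sqrt((400 + 400 + 1) / (12 * 400 * 400))
  expect_equal(mean(sb$hi - sb$lo), 2 * 1.96 * se, tolerance = 0.1)
  expect_error(shuffle_bounds(resp, is_high, n_shuffles = 10), "200")
})

test_that("the shuffle test is calibrated near a 5% false-positive rate", {
  withr::with_seed(3, {
    r <- array(runif(300 * 2 * 200, 0, 1), c(300, 2, 200))
  })
  act <- fake_activity(r, labels = rep(c("low", "high"), each = 100),
                       bin_width = 25)
  sel <- compute_selectivity(act, window = c(25, 50), n_shuffles = 500,
                             seed = 4)
  expect_gt(mean(sel$significant), 0.02)
  expect_lt(mean(sel$significant), 0.09)
})

test_that("selectivity tables label preference and index correctly", {
  withr::with_seed(5, {
    n_tr <- 60
    r <- array(0, c(3, 2, n_tr))
    lab <- rep(c("low", "high"), each = n_tr / 2)
    shift <- ifelse(lab == "high", 0.3, 0)
    r[1, , ] <- rep(runif(n_tr) + shift, each = 2)      # prefers high
    r[2, , ] <- rep(runif(n_tr) - shift, each = 2)      # prefers low
    r[3, , ] <- rep(runif(n_tr), each = 2)              # unselective
  })
  act <- fake_activity(r, labels = lab, bin_width = 25)
  sel <- compute_selectivity(act, n_shuffles = 300, seed = 6)
  expect_equal(sel$preferred[1:2], c("high", "low"))
  expect_true(all(sel$significant[1:2]))
  expect_equal(sel$index, 2 * abs(sel$auc - 0.5))
  expect_true(all(sel$index >= 0 & sel$index <= 1))
  s <- selectivity_summary(sel)
  expect_setequal(s$type, c("exc", "inh"))
})

test_that("noise correlations have the right structure", {
  withr::with_seed(7, {
    base <- rnorm(40)
    r <- array(0, c(4, 2, 40))
    r[1, , ] <- rep(base, each = 2)
    r[2, , ] <- rep(base, each = 2)        # identical residuals -> +1
    r[3, , ] <- rep(-base, each = 2)       # negated residuals  -> -1
    r[4, , ] <- 0.5                        # zero variance -> excluded
  })
  act <- fake_activity(r, labels = rep(c("low", "high"), 20), bin_width = 25)
  expect_warning(cc <- noise_correlations(act), "zero-variance")
  expect_equal(diag(cc)[1:3], rep(1, 3))
  expect_equal(cc[1, 2], 1)
  expect_equal(cc[1, 3], -1)
  expect_true(all(is.na(cc[4, ])))
  expect_equal(cc, t(cc))
})

test_that("pool connectivity is flat when labels are random", {
  net <- build_network(network_spec(), seed = 31)
  withr::with_seed(8, {
    sig <- rbinom(500, 1, 0.5) == 1
    pref <- ifelse(sig, sample(c("low", "high"), 500, replace = TRUE), "none")
  })
  tab <- tibble::tibble(
    neuron = 1:500, type = ifelse(net$is_exc, "exc", "inh"),
    receives_input = net$input_mask, auc = 0.5, lo = 0.4, hi = 0.6,
    significant = sig, preferred = pref, index = 0
  )
  class(tab) <- c("selectivity_table", class(tab))
  pc <- pool_connection_stats(net, tab)
  expect_equal(nrow(pc), 8)
  # selectivity labels independent of the wiring: every pool prob ~ 0.2
  for (k in seq_len(nrow(pc))) {
    se <- sqrt(0.2 * 0.8 / pc$n_pairs[k])
    expect_lt(abs(pc$prob[k] - 0.2), 4 * se)
  }
  expect_equal(pc$ratio, pc$prob / 0.2)
})

test_that("empty pools yield undefined probabilities", {
  net <- small_net(seed = 1)
  tab <- tibble::tibble(
    neuron = 1:50, type = ifelse(net$is_exc, "exc", "inh"),
    receives_input = net$input_mask, auc = 0.6, lo = 0.4, hi = 0.55,
    significant = TRUE, preferred = "high", index = 0.2
  )
  class(tab) <- c("selectivity_table", class(tab))
  pc <- pool_connection_stats(net, tab)
  # all neurons prefer "high": every same/opposite split involving pool 1
  # of either type is empty on one side
  expect_true(any(is.na(pc$prob)))
  same_ee <- pc[pc$source_type == "E" & pc$target_type == "E" &
                  pc$relation == "same", ]
  expect_false(is.na(same_ee$prob))
})
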