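test_that("invalid specifications are rejected", {
  expect_error(network_spec(n_exc = -1), "sizes")
  expect_error(network_spec(p_conn = 1.2), "probability")
  expect_error(network_spec(g_exc = -0.1), "positive")
  expect_error(network_spec(g_inh = 0.2), "positive")
  expect_error(network_spec(weight_sd = -1), "non-negative")
  expect_error(network_spec(pool_weights = matrix(1, 3, 3)), "2x2")
  expect_error(network_spec(pool_weights = matrix(c(1, 1, 1, 1), 2, 2)),
               "negative inh")
})

test_that("zero connection probability yields an empty weight matrix", {
  net <- build_network(small_spec(p_conn = 0), seed = 1)
  expect_true(all(net$weights == 0))
})

test_that("columns obey Dale's principle and the diagonal is empty", {
  for (s in 1:5) {
    net <- small_net(seed = s)
    W <- net$weights
    expect_true(all(W[, net$is_exc] >= 0))
    expect_true(all(W[, !net$is_exc] <= 0))
    expect_true(all(diag(W) == 0))
  }
  # the all-E-input variant keeps the same sign structure
  netv <- build_network(small_spec(variant = "all_e_input"), seed = 1)
  expect_true(all(netv$weights[, netv$is_exc] >= 0))
  expect_true(all(netv$weights[, !netv$is_exc] <= 0))
  expect_true(all(netv$input_mask == netv$is_exc))
})

test_that("default networks are balanced on average", {
  # expected row sum is p (n_E g_E + n_I g_I) = 0; the empirical mean over
  # 500 rows must sit within 3 standard errors of zero
  net <- build_network(network_spec(), seed = 11)
  rs <- rowSums(net$weights)
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se)
})

test_that("empirical sparsity matches p_conn across draws", {
  # pooled over 10 default draws: ~2.5e6 off-diagonal entries, binomial CI
  # for p = 0.2 is well inside [0.195, 0.205]
  frac <- vapply(1:10, function(s) {
    W <- build_network(network_spec(), seed = 100 + s)$weights
    mean(W[row(W) != col(W)] != 0)
  }, numeric(1))
  expect_gt(mean(frac), 0.195)
  expect_lt(mean(frac), 0.205)
})

test_that("pool means match their targets", {
  net <- build_network(network_spec(), seed = 21)
  pm <- pool_mean_table(net)
  e_pool <- pm[pm$source_type == "exc", ]
  w_e <- sum(e_pool$mean_weight * e_pool$n_nonzero) / sum(e_pool$n_nonzero)
  se_e <- 0.045 / sqrt(sum(e_pool$n_nonzero))
  expect_lt(abs(w_e - 0.18), 3 * se_e)

  netv <- build_network(network_spec(variant = "all_e_input"), seed = 22)
  pmv <- pool_mean_table(netv)
  ie <- pmv[pmv$target_type == "exc" & pmv$source_type == "inh", ]
  ii <- pmv[pmv$target_type == "inh" & pmv$source_type == "inh", ]
  expect_lt(abs(ie$mean_weight - (-0.8)), 3 * 0.045 / sqrt(ie$n_nonzero))
  expect_lt(abs(ii$mean_weight - (-0.82)), 3 * 0.045 / sqrt(ii$n_nonzero))
})

test_that("homogeneous networks have zero within-pool variance", {
  net <- build_network(small_spec(homogeneous = TRUE), seed = 3)
  pm <- pool_mean_table(net)
  expect_true(all(pm$sd_weight == 0, na.rm = TRUE))
  W <- net$weights
  expect_true(all(W[W > 0] == 0.18))
  expect_true(all(W[W < 0] == -0.72))
})

test_that("network draws are reproducible and seed-sensitive", {
  a <- build_network(small_spec(), seed = 7)
  b <- build_network(small_spec(), seed = 7)
  c <- build_network(small_spec(), seed = 8)
  expect_identical(a$weights, b$weights)
  expect_identical(a$input_mask, b$input_mask)
  expect_false(identical(a$weights != 0, c$weights != 0))
})

test_that("variants preserve topology while changing weights", {
  net <- small_net(seed = 5)
  sc <- network_variant(net, weight_scale = 1.5)
  expect_identical(sc$weights != 0, net$weights != 0)
  expect_equal(sc$weights, 1.5 * net$weights)
  hom <- network_variant(net, homogeneous = TRUE)
  expect_identical(hom$weights != 0, net$weights != 0)
  expect_true(all(hom$weights[hom$weights > 0] == 0.18))
})

test_that("networks round-trip through JSON serialization", {
  net <- small_net(seed = 9)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$weights, net$weights)
  expect_equal(back$is_exc, net$is_exc)
  expect_equal(back$input_mask, net$input_mask)
  expect_equal(back$spec$g_inh, net$spec$g_inh)
  unlink(path)
})

test_that("tidiers summarize a network sensibly", {
  net <- small_net(seed = 4)
  edges <- tidy(net)
  expect_equal(nrow(edges), sum(net$weights != 0))
  expect_true(all(edges$weight[edges$from_type == "inh"] <= 0))
  g <- glance(net)
  expect_equal(g$n_exc, 40)
  expect_equal(g$n_input, sum(net$input_mask))
})
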