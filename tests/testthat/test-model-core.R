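test_that("validation accepts well-formed networks and names each violation", {
  expect_length(validate_network(single_link_network()), 0)

  # edge pointing the wrong way across layers
  bad_layer <- noisy_or_network(
    nodes = data.frame(id = c("D", "S"), layer = c("disease", "symptom")),
    disease_cpts = list(D = list(parents = c(S = 0.5), leak_failure = 0.8)),
    symptom_cpts = list(S = list(parents = NULL, leak_failure = 0.9)))
  expect_match(validate_network(bad_layer), "layer-order", all = FALSE)

  # out-of-range failure probability
  bad_prob <- noisy_or_network(
    nodes = data.frame(id = c("D", "S"), layer = c("disease", "symptom")),
    disease_cpts = list(D = list(parents = NULL, leak_failure = 0.8)),
    symptom_cpts = list(S = list(parents = c(D = 1.3), leak_failure = 0.9)))
  expect_match(validate_network(bad_prob), "probability-range", all = FALSE)

  dup <- noisy_or_network(
    nodes = data.frame(id = c("D", "D"), layer = c("disease", "disease")),
    disease_cpts = list(D = list(parents = NULL, leak_failure = 0.5)))
  expect_match(validate_network(dup), "duplicate-id", all = FALSE)
})

test_that("structural evaluation is the deterministic noisy-OR mechanism", {
  net <- single_link_network()
  all_fail <- exogenous_state(edge_noise = c("D->S" = 0L),
                              leak_noise = c(D = 1L, S = 1L))
  # all leaks fail, no risk on: everything off
  expect_equal(structural_eval(net, all_fail),
               c(D = 0L, S = 0L))
  # forcing the disease on with a working edge activates the symptom
  expect_equal(structural_eval(net, all_fail, c(D = 1L))[["S"]], 1L)
  # curing it removes the only active cause
  expect_equal(structural_eval(net, all_fail, c(D = 0L))[["S"]], 0L)
  # incomplete noise is an error naming the missing entry
  expect_error(structural_eval(net, exogenous_state(leak_noise = c(D = 1L, S = 1L))),
               "D->S")
})

test_that("switching a disease on never switches a symptom off (monotonicity)", {
  for (seed in 1:10) {
    net <- generate_network(small_generator(seed))
    noise <- forward_sample(net, seed * 7)$noise
    for (d in disease_ids(net)) {
      off <- structural_eval(net, noise, stats::setNames(0L, d))
      on <- structural_eval(net, noise, stats::setNames(1L, d))
      expect_true(all(on[symptom_ids(net)] >= off[symptom_ids(net)]))
    }
    for (r in risk_ids(net)) {
      off <- structural_eval(net, noise, stats::setNames(0L, r))
      on <- structural_eval(net, noise, stats::setNames(1L, r))
      expect_true(all(on >= off))
    }
  }
})

test_that("joint probability matches the worked example and the exogenous-state oracle", {
  net <- single_link_network()
  expect_equal(joint_probability(net, c(D = 0, S = 0)), 0.8 * 0.9)
  expect_equal(joint_probability(net, c(D = 1, S = 0)), 0.2 * 0.4 * 0.9)
  expect_error(joint_probability(net, c(D = 1)), "partial")

  # against the 8-state exogenous enumeration
  for (d in 0:1) for (s in 0:1) {
    want <- exo_event_prob(net, function(a) a[["D"]] == d && a[["S"]] == s)
    expect_equal(joint_probability(net, c(D = d, S = s)), want, tolerance = 1e-12)
  }

  # and on random networks
  for (seed in 1:5) {
    rnet <- generate_network(small_generator(seed, n_symptom = 2))
    fj <- full_joint(rnet)
    expect_equal(sum(fj$probs), 1, tolerance = 1e-12)
    i <- sample(nrow(fj$states), 3)
    for (j in i) {
      a <- fj$states[j, ]
      expect_equal(joint_probability(rnet, a),
                   exo_event_prob(rnet, function(x) all(x[names(a)] == a)),
                   tolerance = 1e-12)
    }
  }
})

test_that("forward sampling is seed-deterministic and matches the joint", {
  net <- single_link_network()
  expect_identical(forward_sample(net, 11), forward_sample(net, 11))

  degenerate <- noisy_or_network(
    nodes = data.frame(id = c("R", "D", "S"), layer = c("risk", "disease", "symptom")),
    risk_priors = c(R = 0),
    disease_cpts = list(D = list(parents = c(R = 0.5), leak_failure = 1)),
    symptom_cpts = list(S = list(parents = c(D = 0.5), leak_failure = 1)))
  for (seed in c(1, 99, 12345))
    expect_true(all(forward_sample(degenerate, seed)$assignment == 0L))

  # chi-square goodness of fit of sampled assignments against the joint
  n <- 20000
  draws <- vapply(seq_len(n), function(i) {
    a <- forward_sample(net, i)$assignment
    paste0(a[["D"]], a[["S"]])
  }, "")
  cells <- c("00", "01", "10", "11")
  expected <- vapply(cells, function(cl)
    joint_probability(net, c(D = as.integer(substr(cl, 1, 1)),
                             S = as.integer(substr(cl, 2, 2)))), 0)
  observed <- as.vector(table(factor(draws, levels = cells)))
  gof <- stats::chisq.test(observed, p = expected)
  expect_gt(gof$p.value, 0.001)

  # empirical P(S = 1) within 3 standard errors of the closed form 0.208
  p_hat <- mean(draws %in% c("01", "11"))
  expect_lt(abs(p_hat - 0.208), 3 * sqrt(0.208 * 0.792 / n))
})

test_that("model files round-trip and schema violations are caught", {
  net <- generate_network(small_generator(3))
  tf <- withr::local_tempfile(fileext = ".json")
  write_model(net, tf)
  expect_equal(read_model(tf), net)

  dup <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes":[{"id":"D","layer":"disease"},{"id":"D","layer":"disease"}],
              "cpts":[{"child":"D","leak_failure":0.5}]}', dup)
  expect_error(read_model(dup), "duplicate node id", class = "cfdiag_schema_error")

  noleak <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes":[{"id":"D","layer":"disease"}],
              "cpts":[{"child":"D"}]}', noleak)
  expect_error(read_model(noleak), "leak_failure", class = "cfdiag_schema_error")

  extra <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes":[{"id":"D","layer":"disease"}],
              "cpts":[{"child":"D","leak_failure":0.5}],"surprise":1}', extra)
  expect_error(read_model(extra, strict = TRUE), "unknown field",
               class = "cfdiag_schema_error")
  expect_warning(net2 <- read_model(extra, strict = FALSE), "unknown field")
  expect_equal(disease_ids(net2), "D")
})
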