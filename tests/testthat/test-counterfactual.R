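test_that("twin construction copies intervened nodes and their descendants", {
  net <- single_link_network()
  tw <- build_twin_network(net, c(D = 0L))
  expect_setequal(tw$copies, c("D", "S"))

  expect_length(build_twin_network(net, NULL)$copies, 0)
  expect_equal(build_twin_network(net, c(S = 1L))$copies, "S")

  cf <- confounder_fixture("confounded")
  expect_setequal(build_twin_network(cf, c(R = 0L))$copies,
                  c("R", "D", "D_latent", "S"))
  expect_setequal(build_twin_network(cf, stats::setNames(0L, "leak:S"))$copies, "S")
})

test_that("counterfactual probabilities match hand algebra and the abduction oracle", {
  net <- single_link_network()
  ev <- evidence(positive = "S")
  q_cure <- counterfactual_query(ev, c(D = 0L), "S", 0L)
  expect_equal(counterfactual_probability(net, q_cure), 0.108 / 0.208,
               tolerance = 1e-12)
  expect_equal(abduction_query(net, q_cure), 0.108 / 0.208, tolerance = 1e-12)

  # under the null intervention the counterfactual equals the fact
  expect_equal(counterfactual_probability(
    net, counterfactual_query(ev, NULL, "S", 1L)), 1, tolerance = 1e-12)
  expect_equal(counterfactual_probability(
    net, counterfactual_query(evidence(negative = "S"), NULL, "S", 0L)), 1,
    tolerance = 1e-12)

  # switching off the leak and all non-D parents of S leaves no cause
  two <- noisy_or_network(
    nodes = data.frame(id = c("D", "D2", "S"),
                       layer = c("disease", "disease", "symptom")),
    disease_cpts = list(D = list(parents = NULL, leak_failure = 0.8),
                        D2 = list(parents = NULL, leak_failure = 0.7)),
    symptom_cpts = list(S = list(parents = c(D2 = 0.3), leak_failure = 0.9)))
  q_no_cause <- counterfactual_query(
    evidence(positive = "S"),
    stats::setNames(c(0L, 0L), c("leak:S", "D2")), "S", 1L)
  expect_equal(counterfactual_probability(two, q_no_cause), 0, tolerance = 1e-12)

  # random networks, random queries, against abduction-action-prediction
  for (seed in 1:15) {
    rnet <- generate_network(small_generator(seed, n_symptom = 2))
    set.seed(seed + 300)
    rev <- random_evidence(rnet, max_pos = 2)
    target <- sample(symptom_ids(rnet), 1)
    iv <- stats::setNames(sample(0:1, 1), sample(disease_ids(rnet), 1))
    q <- counterfactual_query(rev, iv, target, sample(0:1, 1))
    expect_equal(counterfactual_probability(rnet, q), abduction_query(rnet, q),
                 tolerance = 1e-10)
  }
})

test_that("worked single-link measures are exact on every route", {
  net <- single_link_network()
  ev <- evidence(positive = "S")
  for (m in c("closed_form", "twin_def", "abduction")) {
    expect_equal(expected_sufficiency(net, ev, "D", method = m), 0.12 / 0.208,
                 tolerance = 1e-9)
    expect_equal(expected_disablement(net, ev, "D", method = m), 0.108 / 0.208,
                 tolerance = 1e-9)
  }
})

test_that("a deterministic necessary cause has expected disablement 1", {
  det <- single_link_network(prior = 0.2, lambda = 0, leak = 1)
  ev <- evidence(positive = "S")
  for (m in c("closed_form", "twin_def", "abduction"))
    expect_equal(expected_disablement(det, ev, "D", method = m), 1,
                 tolerance = 1e-9)
  # the 0 * infinity cancellation agrees with the twin route near lambda = 0
  near <- single_link_network(prior = 0.2, lambda = 1e-6, leak = 0.9)
  expect_equal(expected_disablement(near, ev, "D", "closed_form"),
               expected_disablement(near, ev, "D", "twin_def"),
               tolerance = 1e-9)
})

test_that("measures vanish without positive evidence or causal connection", {
  net <- confounder_fixture("confounded")
  ev <- evidence(positive = "S")
  for (m in c("closed_form", "twin_def", "abduction")) {
    # D has no directed path to S: exact zero (causality desideratum)
    expect_lt(abs(expected_sufficiency(net, ev, "D", method = m)), 1e-12)
    expect_lt(abs(expected_disablement(net, ev, "D", method = m)), 1e-12)
    # no positive symptoms: zero for every disease
    expect_equal(expected_sufficiency(net, evidence(negative = "S"), "D_latent",
                                      method = m), 0)
    expect_equal(expected_disablement(net, evidence(negative = "S"), "D_latent",
                                      method = m), 0)
  }
})

test_that("measures respect the consistency bound and range", {
  for (seed in 1:20) {
    net <- generate_network(small_generator(seed))
    set.seed(seed + 900)
    ev <- random_evidence(net)
    n_pos <- length(ev$positive)
    for (d in disease_ids(net)) {
      post <- posterior_disease(net, ev, d)
      for (f in c(expected_sufficiency, expected_disablement)) {
        val <- f(net, ev, d)
        expect_gte(val, 0)
        expect_lte(val, n_pos + 1e-12)
        expect_lte(val, n_pos * post + 1e-12)
        if (post == 0) expect_equal(val, 0)
      }
    }
  }
})

test_that("the better explainer of more symptoms outranks the one-symptom explainer", {
  net <- simplicity_fixture()
  ev <- evidence(positive = c("S1", "S2"))
  for (m in c("expected_sufficiency", "expected_disablement")) {
    rk <- rank_diseases(net, ev, measure = m)
    expect_equal(rk$entries$disease[1], "D_A")
    expect_gt(rk$entries$score[1], rk$entries$score[2])
  }
})

test_that("closed form, twin network and abduction agree on random networks", {
  worst <- 0
  for (seed in 1:30) {
    net <- generate_network(small_generator(seed, n_symptom = sample(2:3, 1)))
    set.seed(seed + 40)
    ev <- random_evidence(net)
    for (d in disease_ids(net)) {
      suff <- vapply(c("closed_form", "twin_def", "abduction"), function(m)
        expected_sufficiency(net, ev, d, method = m), 0)
      dis <- vapply(c("closed_form", "twin_def", "abduction"), function(m)
        expected_disablement(net, ev, d, method = m), 0)
      worst <- max(worst, diff(range(suff)), diff(range(dis)))
    }
  }
  expect_lt(worst, 1e-9)
})
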