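test_that("network generation is seed-stable, valid and density-aware", {
  cfg <- small_generator(7)
  expect_identical(generate_network(cfg), generate_network(cfg))

  for (seed in 1:40)
    expect_length(validate_network(generate_network(small_generator(seed))), 0)

  # density 1 gives complete bipartite layers
  dense <- generate_network(generator_config(n_risk = 2, n_disease = 3,
                                             n_symptom = 2, density_risk = 1,
                                             density_symptom = 1, seed = 3))
  for (d in disease_ids(dense))
    expect_setequal(node_parents(dense, d), risk_ids(dense))
  for (s in symptom_ids(dense))
    expect_setequal(node_parents(dense, s), disease_ids(dense))

  # every symptom keeps at least one parent even at low density
  sparse <- generate_network(generator_config(n_disease = 4, n_symptom = 4,
                                              density_symptom = 0.05, seed = 5))
  for (s in symptom_ids(sparse))
    expect_gte(length(node_parents(sparse, s)), 1)

  expect_error(generate_network(generator_config(density_symptom = 0, seed = 1)),
               "impossible config")
  expect_error(generator_config(density_risk = 1.4), "\\[0, 1\\]")
})

test_that("vignettes reveal evidence as configured and always carry a present symptom", {
  cfg <- generator_config(n_risk = 2, n_disease = 3, n_symptom = 4,
                          reveal_positive = 1, reveal_negative = 1,
                          reveal_risk = 1, seed = 9)
  net <- generate_network(cfg)
  vg <- generate_vignette(net, cfg, seed = 123)
  # full reveal: evidence covers the whole sampled symptom and risk layers
  expect_setequal(c(vg$evidence$positive, vg$evidence$negative), symptom_ids(net))
  expect_setequal(names(vg$evidence$risk), risk_ids(net))
  expect_true(vg$true_disease %in% disease_ids(net))
  expect_gte(vg$k, 1)

  # determinism
  expect_identical(generate_vignette(net, cfg, seed = 123),
                   generate_vignette(net, cfg, seed = 123))

  # partial reveal never leaves the positive set empty
  cfg2 <- generator_config(n_risk = 2, n_disease = 3, n_symptom = 4,
                           reveal_positive = 0, reveal_negative = 0.2, seed = 9)
  for (s in 1:25) {
    vg2 <- generate_vignette(net, cfg2, seed = s)
    expect_gte(length(vg2$evidence$positive), 1)
    expect_true(all(vg2$evidence$positive %in% symptom_ids(net)))
    expect_length(intersect(vg2$evidence$positive, vg2$evidence$negative), 0)
  }
})

test_that("a deterministic disease-symptom link is always positively evidenced", {
  det <- noisy_or_network(
    nodes = data.frame(id = c("D", "S"), layer = c("disease", "symptom")),
    disease_cpts = list(D = list(parents = NULL, leak_failure = 0.9)),
    symptom_cpts = list(S = list(parents = c(D = 0), leak_failure = 1)))
  cfg <- generator_config(n_disease = 1, n_symptom = 1, reveal_positive = 0.5,
                          seed = 1)
  for (s in 1:10)
    expect_equal(generate_vignette(det, cfg, seed = s)$evidence$positive, "S")
})

test_that("sampled symptom activation matches the closed-form rate", {
  # P(S = 1 | do(D = 1)) = 1 - leak * lambda = 1 - 0.9 * 0.4 = 0.64
  net <- single_link_network()
  cfg <- generator_config(n_disease = 1, n_symptom = 1, reveal_positive = 1,
                          reveal_negative = 1, seed = 1)
  n <- 1000
  hits <- vapply(seq_len(n), function(s)
    "S" %in% generate_vignette(net, cfg, seed = s)$evidence$positive, TRUE)
  p <- 1 - 0.9 * 0.4
  # conditioned on acceptance (>= 1 present child symptom) every vignette
  # shows S, so compare the acceptance rate instead via rejection counts:
  # here S is the only child, so acceptance implies S on; the unconditional
  # activation rate is recovered from first-draw successes.
  first_try <- vapply(seq_len(n), function(s) {
    a <- structural_eval(net, forward_sample(net, s)$noise, c(D = 1L))
    a[["S"]] == 1L
  }, TRUE)
  expect_lt(abs(mean(first_try) - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(hits))
})

test_that("cohorts are reproducible byte for byte and reject n = 0", {
  cfg <- generator_config(n_risk = 2, n_disease = 3, n_symptom = 3, seed = 31)
  net <- generate_network(cfg)
  expect_error(generate_cohort(net, cfg, 0), "at least 1")

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  c1 <- generate_cohort(net, cfg, 12, path = f1)
  c2 <- generate_cohort(net, cfg, 12, path = f2)
  expect_identical(c1, c2)
  expect_identical(readLines(f1), readLines(f2))

  # round-trips through the vignette schema
  back <- read_cohort(f1)
  expect_equal(length(back), 12)
  expect_equal(back[[1]]$true_disease, c1[[1]]$true_disease)
  expect_equal(back[[1]]$evidence, c1[[1]]$evidence)
  expect_equal(back[[1]]$k, c1[[1]]$k)
})

test_that("cohort true-disease frequencies match the configured weighting", {
  cfg <- generator_config(n_risk = 1, n_disease = 4, n_symptom = 3,
                          density_symptom = 1, seed = 91)
  net <- generate_network(cfg)
  cohort <- generate_cohort(net, cfg, 400)
  freq <- table(factor(vapply(cohort, `[[`, "", "true_disease"),
                       levels = disease_ids(net)))
  gof <- stats::chisq.test(as.vector(freq), p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)
})

test_that("true diseases recover better-than-random mean ranks end to end", {
  cfg <- generator_config(n_risk = 2, n_disease = 4, n_symptom = 5,
                          density_symptom = 0.5, seed = 77)
  net <- generate_network(cfg)
  cohort <- generate_cohort(net, cfg, 60)
  res <- evaluate_cohort(net, cohort)
  random_expect <- (length(disease_ids(net)) + 1) / 2
  for (m in res$measures)
    expect_lt(res$summary[[paste0("mean_rank_", m)]], random_expect)
})
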