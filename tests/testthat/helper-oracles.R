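# Independent brute-force oracles built purely from the exported SCM
# primitives, used to verify the analytic inference paths.

# Enumerate every exogenous state of a (small) network with its probability.
enumerate_exo <- function(net) {
  rids <- sort(risk_ids(net))
  children <- c(sort(disease_ids(net)), sort(symptom_ids(net)))
  comp <- list()
  for (r in rids)
    comp[[paste0("risk:", r)]] <- net$risk_priors[[r]]
  for (ch in children) {
    for (p in sort(node_parents(net, ch)))
      comp[[paste0(p, "->", ch)]] <- edge_lambda(net, p, ch)
    cpt <- net$disease_cpts[[ch]]
    if (is.null(cpt)) cpt <- net$symptom_cpts[[ch]]
    comp[[paste0("leak:", ch)]] <- cpt$leak_failure
  }
  m <- length(comp)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(grid) <- names(comp)
  probs <- apply(grid, 1, function(bits)
    prod(ifelse(bits == 1, unlist(comp), 1 - unlist(comp))))
  states <- lapply(seq_len(nrow(grid)), function(i) {
    bits <- grid[i, ]
    is_risk <- startsWith(names(bits), "risk:")
    is_leak <- startsWith(names(bits), "leak:")
    exogenous_state(
      risk_draws = stats::setNames(bits[is_risk], sub("^risk:", "", names(bits)[is_risk])),
      edge_noise = bits[!is_risk & !is_leak],
      leak_noise = stats::setNames(bits[is_leak], sub("^leak:", "", names(bits)[is_leak])))
  })
  list(states = states, probs = probs)
}

# P(event) by exogenous enumeration + deterministic structural evaluation;
# `event` is a predicate on a total assignment.
exo_event_prob <- function(net, event, intervention = NULL) {
  exo <- enumerate_exo(net)
  sum(vapply(seq_along(exo$states), function(i) {
    a <- structural_eval(net, exo$states[[i]], intervention)
    if (event(a)) exo$probs[i] else 0
  }, 0))
}

# Full-joint table over total assignments via joint_probability.
full_joint <- function(net) {
  ids <- net$nodes$id
  states <- as.matrix(expand.grid(rep(list(0:1), length(ids))))
  colnames(states) <- ids
  probs <- apply(states, 1, function(a) joint_probability(net, a))
  list(states = states, probs = probs)
}

# Conditional event probabilities from the full joint.
joint_event_prob <- function(fj, event) {
  keep <- apply(fj$states, 1, event)
  sum(fj$probs[keep])
}

evidence_matcher <- function(ev) {
  function(a) {
    for (r in names(ev$risk)) if (a[[r]] != ev$risk[[r]]) return(FALSE)
    for (s in ev$positive) if (a[[s]] != 1) return(FALSE)
    for (s in ev$negative) if (a[[s]] != 0) return(FALSE)
    TRUE
  }
}

# Draw a random partial evidence set for a generated network.
random_evidence <- function(net, max_pos = 3) {
  sids <- symptom_ids(net)
  rids <- risk_ids(net)
  pos <- sample(sids, sample.int(min(max_pos, length(sids)), 1))
  rest <- setdiff(sids, pos)
  neg <- rest[stats::runif(length(rest)) < 0.3]
  shown <- rids[stats::runif(length(rids)) < 0.5]
  evidence(risk = stats::setNames(stats::rbinom(length(shown), 1, 0.5), shown),
           positive = pos, negative = neg)
}

small_generator <- function(seed, n_symptom = 3)
  generator_config(n_risk = 2, n_disease = 3, n_symptom = n_symptom,
                   density_risk = 0.5, density_symptom = 0.5, seed = seed)

# Symmetric two-disease fixture: D_A explains two present symptoms, D_B one;
# all priors, lambdas and leaks equal.
simplicity_fixture <- function() {
  noisy_or_network(
    nodes = data.frame(id = c("D_A", "D_B", "S1", "S2"),
                       layer = c("disease", "disease", "symptom", "symptom")),
    disease_cpts = list(D_A = list(parents = NULL, leak_failure = 0.9),
                        D_B = list(parents = NULL, leak_failure = 0.9)),
    symptom_cpts = list(
      S1 = list(parents = c(D_A = 0.3), leak_failure = 0.95),
      S2 = list(parents = c(D_A = 0.3, D_B = 0.3), leak_failure = 0.95)))
}
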