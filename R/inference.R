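# Exact associative inference on three-layer noisy-OR networks.
#
# Everything here reduces to one primitive: the probability that a chosen
# set of symptoms is jointly OFF (optionally with one disease forced ON),
# given the observed risk factors.  Conditioned on the full risk layer the
# diseases are independent, and an all-off symptom event factorises over
# diseases as  prod_j [ P(D_j=0|r) + P(D_j=1|r) * w_j ]  with
# w_j = prod over off symptoms of lambda_{j,s}; the symptom leaks contribute
# prod leak_failure.  Partial risk evidence is handled by enumerating only
# the unobserved risk factors that are parents of a disease relevant to the
# event.  Positive symptom evidence is recovered from all-off terms by
# inclusion-exclusion over subsets of the positive set (quickscore style).

# P(off-symptoms all 0 [, require_on = 1] | risk evidence).
# drop_lambda_child: divide the factor lambda_{require_on, child} out of the
# require_on disease's product analytically — used for the 0*infinity
# cancellation in the expected-disablement closed form.
.all_off_prob <- function(network, risk_ev, off, require_on = NULL,
                          drop_lambda_child = NULL) {
  off <- unique(off)
  scpts <- network$symptom_cpts
  # diseases whose state influences the event
  relevant <- unique(c(require_on,
                       unlist(lapply(off, function(s) names(scpts[[s]]$parents)))))
  if (!length(relevant)) relevant <- character(0)

  leak_prod <- prod(vapply(off, function(s) scpts[[s]]$leak_failure, 0))

  # per-disease symptom-failure weight w_j
  w <- vapply(relevant, function(j) {
    lam <- vapply(off, function(s) edge_lambda(network, j, s), 0)
    if (!is.null(drop_lambda_child) && identical(j, require_on)) {
      k <- match(drop_lambda_child, off)
      if (!is.na(k)) lam <- lam[-k]
    }
    prod(lam)
  }, 0)

  # risk factors needing enumeration: unobserved parents of relevant diseases
  pa_r <- unique(unlist(lapply(relevant, function(j)
    names(network$disease_cpts[[j]]$parents))))
  enum_r <- setdiff(pa_r, names(risk_ev))
  m <- length(enum_r)
  if (m > 20L)
    stop("exact inference would enumerate 2^", m,
         " unobserved risk configurations; model too large for the exact contract",
         call. = FALSE)

  total <- 0
  for (mask in 0:(bitwShiftL(1L, m) - 1L)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L)
    r <- c(risk_ev, stats::setNames(bits, enum_r))
    wr <- prod(ifelse(bits == 1L, network$risk_priors[enum_r],
                      1 - network$risk_priors[enum_r]))
    term <- 1
    for (j in relevant) {
      cpt <- network$disease_cpts[[j]]
      q <- cpt$leak_failure
      for (pr in names(cpt$parents)) if (r[[pr]] == 1L) q <- q * cpt$parents[[pr]]
      pj <- 1 - q
      term <- term * if (identical(j, require_on)) pj * w[[j]] else q + pj * w[[j]]
    }
    total <- total + wr * term
  }
  leak_prod * total
}

#' Likelihood of the symptom evidence
#'
#' Computes `P(S+ = 1, S- = 0 | R)` exactly, marginalising all diseases and
#' every unobserved risk factor.  Positive evidence is expanded by
#' inclusion-exclusion over subsets of the positive set, so the cost is
#' `2^|S+|` all-off terms (capped at `|S+| <= 16`).
#'
#' @param network a [noisy_or_network()].
#' @param ev an [evidence()] object.
#' @return Probability in \[0, 1\]; `0` is a legal return for impossible
#'   evidence.
#' @export
evidence_likelihood <- function(network, ev) {
  ev <- .check_evidence(network, ev)
  terms <- .subset_apply(ev$positive, function(W, sz)
    (-1)^sz * .all_off_prob(network, ev$risk, c(ev$negative, W)))
  max(0, sum(unlist(terms)))
}

#' Posterior probability of a disease
#'
#' Exact `P(D = 1 | evidence)` under the network (the associative
#' diagnostic score).  Equals the disease's marginal given the risk evidence
#' when no symptom is observed.
#'
#' @inheritParams evidence_likelihood
#' @param disease_id a disease id.
#' @return Probability in \[0, 1\].
#' @export
posterior_disease <- function(network, ev, disease_id) {
  ev <- .check_evidence(network, ev)
  denom <- evidence_likelihood(network, ev)
  if (denom <= 0)
    .stop_domain("conditioning on null event: evidence has probability zero")
  num <- sum(unlist(.subset_apply(ev$positive, function(W, sz)
    (-1)^sz * .all_off_prob(network, ev$risk, c(ev$negative, W),
                            require_on = disease_id))))
  min(1, max(0, num / denom))
}

#' Joint switched-off-subset likelihood
#'
#' The term `P(S- = 0, Z = 0, D_k = 1 | R)`: all negative-evidence symptoms
#' and all symptoms in `Z` are off while disease `D_k` is on, given the risk
#' evidence.  These are the building blocks of the closed-form counterfactual
#' measures; the value is monotone non-increasing in `Z` under set inclusion.
#'
#' @inheritParams posterior_disease
#' @param Z character vector of symptom ids, a subset of the positive
#'   evidence.
#' @return Probability in \[0, 1\].
#' @export
negated_subset_likelihood <- function(network, ev, disease_id, Z = character()) {
  ev <- .check_evidence(network, ev)
  extra <- setdiff(Z, ev$positive)
  if (length(extra))
    stop("Z must be a subset of the positive symptom evidence; offending: ",
         paste(extra, collapse = ", "), call. = FALSE)
  .all_off_prob(network, ev$risk, c(ev$negative, Z), require_on = disease_id)
}

#' Marginal disease probability given risk evidence only
#'
#' `P(D = 1 | R)` — the patient-specific prior used for rarity
#' stratification.
#'
#' @inheritParams posterior_disease
#' @param risk named 0/1 vector of observed risk factors (may be empty).
#' @return Probability in \[0, 1\].
#' @export
disease_prior <- function(network, disease_id, risk = integer()) {
  .all_off_prob(network, .named_int(risk), character(0), require_on = disease_id)
}

#' Associative (posterior) disease ranking
#'
#' Ranks every modelled disease by its exact posterior given the evidence —
#' the standard Bayesian diagnostic ranking.
#'
#' @inheritParams evidence_likelihood
#' @return A `diagnosis_ranking` (see [rank_diseases()]).
#' @export
posterior_ranking <- function(network, ev) {
  rank_diseases(network, ev, measure = "posterior")
}
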