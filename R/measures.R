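#' Counterfactual diagnostic measures
#'
#' @description
#' Two causally grounded scores for how well a disease explains the present
#' symptoms, each an expected symptom count in a counterfactual world that
#' shares its exogenous noise with the factual one:
#'
#' * **Expected disablement** — the expected number of present symptoms that
#'   would switch off if we intervened to cure the disease, `do(D = 0)`
#'   (necessary-cause flavour).
#' * **Expected sufficiency** — the expected number of present symptoms that
#'   would persist if we intervened to switch off every other possible cause
#'   of the present symptoms: all their other disease parents and their leak
#'   (exogenous) causes (sufficient-cause flavour).
#'
#' Both are computable three ways, and the routes agree to numerical
#' precision:
#'
#' * `"closed_form"` — exact expression for three-layer noisy-OR networks:
#'   an inclusion-exclusion sum over subsets `Z` of the positive symptoms of
#'   `(-1)^|Z| P(S- = 0, Z = 0, D = 1 | R) * tau(D, Z)`, normalised by the
#'   evidence likelihood, where `tau(D, Z) = sum over S in S+ \ Z of
#'   (1 - lambda_{D,S})` for sufficiency and `tau(D, Z) = sum over S in Z of
#'   (1 - 1/lambda_{D,S})` for disablement.
#' * `"twin_def"` — the defining expectation evaluated by exact inference on
#'   the twin network (no inclusion-exclusion, no noise enumeration).
#' * `"abduction"` — abduction-action-prediction by exhaustive noise
#'   enumeration; exponential, for verification on small networks.
#'
#' A `lambda = 0` edge makes `1/lambda` infinite in the disablement `tau`,
#' but the joint it multiplies contains the matching factor `lambda` (the
#' event includes that symptom off while the disease is on), so the product
#' is kept in analytically cancelled form and the limit is finite.
#'
#' The counterfactual count is taken over the factually present symptoms
#' only: symptoms that were absent or unobserved but would activate in the
#' counterfactual world are not counted.
#'
#' @param network a [noisy_or_network()].
#' @param ev an [evidence()] object with positive evidence likelihood.
#' @param disease_id the candidate disease.
#' @param method computation route, see above.
#' @return Non-negative scalar, at most `length(ev$positive)`.
#' @examples
#' net <- single_link_network()
#' ev <- evidence(positive = "S")
#' expected_disablement(net, ev, "D")   # 0.108 / 0.208
#' expected_sufficiency(net, ev, "D")   # 0.120 / 0.208
#' @export
expected_sufficiency <- function(network, ev, disease_id,
                                 method = c("closed_form", "twin_def", "abduction")) {
  method <- match.arg(method)
  ev <- .check_evidence(network, ev)
  if (!length(ev$positive)) return(0)
  switch(method,
    closed_form = {
      denom <- .measure_denominator(network, ev)
      terms <- .subset_apply(ev$positive, function(Z, sz) {
        tau <- sum(1 - vapply(setdiff(ev$positive, Z),
                              function(s) edge_lambda(network, disease_id, s), 0))
        if (tau == 0) return(0)
        (-1)^sz * tau *
          .all_off_prob(network, ev$risk, c(ev$negative, Z), require_on = disease_id)
      })
      max(0, sum(unlist(terms)) / denom)
    },
    twin_def = {
      iv <- .sufficiency_intervention(network, ev, disease_id)
      res <- .twin_expectations(network, ev, iv,
                                lapply(ev$positive, function(s) list(node = s, value = 1L)))
      if (res$denominator <= 0)
        .stop_domain("conditioning on null event: evidence has probability zero")
      max(0, sum(res$numerators) / res$denominator)
    },
    abduction = .abduction_measure(network, ev, disease_id, "sufficiency"))
}

#' @rdname expected_sufficiency
#' @export
expected_disablement <- function(network, ev, disease_id,
                                 method = c("closed_form", "twin_def", "abduction")) {
  method <- match.arg(method)
  ev <- .check_evidence(network, ev)
  if (!length(ev$positive)) return(0)
  switch(method,
    closed_form = {
      denom <- .measure_denominator(network, ev)
      terms <- .subset_apply(ev$positive, function(Z, sz) {
        if (!length(Z)) return(0)
        base <- .all_off_prob(network, ev$risk, c(ev$negative, Z),
                              require_on = disease_id)
        acc <- 0
        for (S in Z) {
          # base * (1 - 1/lambda) = base - base/lambda, with the division
          # performed inside the joint so lambda = 0 stays finite
          cancelled <- .all_off_prob(network, ev$risk, c(ev$negative, Z),
                                     require_on = disease_id,
                                     drop_lambda_child = S)
          acc <- acc + (base - cancelled)
        }
        (-1)^sz * acc
      })
      max(0, sum(unlist(terms)) / denom)
    },
    twin_def = {
      res <- .twin_expectations(network, ev, stats::setNames(0L, disease_id),
                                lapply(ev$positive, function(s) list(node = s, value = 0L)))
      if (res$denominator <= 0)
        .stop_domain("conditioning on null event: evidence has probability zero")
      max(0, sum(res$numerators) / res$denominator)
    },
    abduction = .abduction_measure(network, ev, disease_id, "disablement"))
}

.measure_denominator <- function(network, ev) {
  denom <- evidence_likelihood(network, ev)
  if (denom <= 0)
    .stop_domain("conditioning on null event: evidence has probability zero")
  denom
}

# do(Pa(S+) \ D = 0) including each present symptom's leak parent
.sufficiency_intervention <- function(network, ev, disease_id) {
  pa <- unique(unlist(lapply(ev$positive, function(s)
    names(network$symptom_cpts[[s]]$parents))))
  others <- setdiff(pa, disease_id)
  c(stats::setNames(rep(0L, length(others)), others),
    stats::setNames(rep(0L, length(ev$positive)), paste0("leak:", ev$positive)))
}

.abduction_measure <- function(network, ev, disease_id, which) {
  ab <- .abduction_posterior(network, ev)
  iv <- if (which == "disablement") stats::setNames(0L, disease_id)
        else .sufficiency_intervention(network, ev, disease_id)
  cf <- .eval_matrix(network, ab$tab, ab$B, iv)
  cf_pos <- cf[, ev$positive, drop = FALSE]
  counts <- if (which == "disablement") rowSums(1L - cf_pos) else rowSums(cf_pos)
  sum(ab$W * counts) / sum(ab$W)
}
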