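#' Construct a three-layer noisy-OR diagnostic network
#'
#' A `noisy_or_network` is a three-layer Bayesian network over binary nodes —
#' risk factors, diseases and symptoms — in which every disease and symptom
#' follows a noisy-OR mechanism: each parent that is "on" activates the child
#' unless its activation independently fails (probability `lambda`), and an
#' always-on leak parent activates the child unless it fails (probability
#' `leak_failure`).  Interpreted as a structural causal model, every edge and
#' every leak carries its own binary exogenous failure variable, which is what
#' makes interventional and counterfactual queries well defined.
#'
#' Diseases with no risk-factor parents are parameterised purely by their
#' leak: the marginal prevalence is `1 - leak_failure`.
#'
#' @param nodes data.frame with columns `id` (character, unique), `layer`
#'   (one of `"risk"`, `"disease"`, `"symptom"`) and optionally `label`.
#' @param risk_priors named numeric vector, `P(R = 1)` per risk-factor id.
#' @param disease_cpts named list, one entry per disease id: a list with
#'   `parents` (named numeric vector of failure probabilities `lambda`, names
#'   are risk-factor ids; may be empty) and `leak_failure` in \[0, 1\].
#' @param symptom_cpts named list, one entry per symptom id, same shape as
#'   `disease_cpts` but with disease ids as parents.
#' @return An object of class `noisy_or_network`.
#' @seealso [validate_network()], [structural_eval()], [read_model()]
#' @examples
#' net <- single_link_network()
#' validate_network(net)
#' @export
noisy_or_network <- function(nodes, risk_priors = numeric(),
                             disease_cpts = list(), symptom_cpts = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "layer", "label")]
  nodes$id <- as.character(nodes$id)
  nodes$layer <- as.character(nodes$layer)
  nodes$label <- as.character(nodes$label)
  net <- structure(
    list(nodes = nodes,
         risk_priors = unlist(risk_priors)[],
         disease_cpts = lapply(disease_cpts, .as_cpt),
         symptom_cpts = lapply(symptom_cpts, .as_cpt)),
    class = "noisy_or_network")
  if (length(net$risk_priors) == 0) net$risk_priors <- stats::setNames(numeric(0), character(0))
  net
}

.as_cpt <- function(cpt) {
  parents <- cpt$parents
  if (is.null(parents) || length(parents) == 0) {
    parents <- stats::setNames(numeric(0), character(0))
  } else {
    parents <- unlist(parents)
  }
  list(parents = parents, leak_failure = as.numeric(cpt$leak_failure))
}

#' @export
print.noisy_or_network <- function(x, ...) {
  n <- table(factor(x$nodes$layer, levels = c("risk", "disease", "symptom")))
  n_edges <- sum(vapply(x$disease_cpts, function(c) length(c$parents), 0L)) +
    sum(vapply(x$symptom_cpts, function(c) length(c$parents), 0L))
  cat(sprintf("<noisy_or_network> %d risk factor(s), %d disease(s), %d symptom(s), %d edge(s)\n",
              n[["risk"]], n[["disease"]], n[["symptom"]], n_edges))
  invisible(x)
}

#' @export
summary.noisy_or_network <- function(object, ...) {
  print(object)
  for (d in disease_ids(object)) {
    cpt <- object$disease_cpts[[d]]
    cat(sprintf("  disease %s: leak_failure=%.4g, parents: %s\n", d,
                cpt$leak_failure,
                if (length(cpt$parents)) paste(names(cpt$parents), collapse = ", ") else "(none)"))
  }
  for (s in symptom_ids(object)) {
    cpt <- object$symptom_cpts[[s]]
    cat(sprintf("  symptom %s: leak_failure=%.4g, parents: %s\n", s,
                cpt$leak_failure,
                if (length(cpt$parents)) paste(names(cpt$parents), collapse = ", ") else "(none)"))
  }
  invisible(object)
}

#' Node id accessors
#'
#' @param network a [noisy_or_network()].
#' @return Character vector of node ids in the requested layer, in the order
#'   they appear in the node table.
#' @export
risk_ids <- function(network) network$nodes$id[network$nodes$layer == "risk"]

#' @rdname risk_ids
#' @export
disease_ids <- function(network) network$nodes$id[network$nodes$layer == "disease"]

#' @rdname risk_ids
#' @export
symptom_ids <- function(network) network$nodes$id[network$nodes$layer == "symptom"]

#' Parents of a node
#'
#' @param network a [noisy_or_network()].
#' @param id node id.
#' @return Character vector of parent ids (risk factors for a disease,
#'   diseases for a symptom; empty for a risk factor).
#' @export
node_parents <- function(network, id) {
  if (id %in% names(network$disease_cpts)) return(names(network$disease_cpts[[id]]$parents))
  if (id %in% names(network$symptom_cpts)) return(names(network$symptom_cpts[[id]]$parents))
  character(0)
}

#' Edge failure probability
#'
#' Returns the noisy-OR failure probability `lambda` on the edge
#' `parent -> child`.  Absent edges behave as edges that always fail, so the
#' value for a non-parent is 1; this convention makes the closed-form
#' counterfactual measures degrade gracefully for diseases unconnected to a
#' symptom.
#'
#' @param network a [noisy_or_network()].
#' @param parent,child node ids.
#' @return Numeric scalar in \[0, 1\].
#' @export
edge_lambda <- function(network, parent, child) {
  cpt <- network$disease_cpts[[child]]
  if (is.null(cpt)) cpt <- network$symptom_cpts[[child]]
  if (is.null(cpt)) return(1)
  i <- match(parent, names(cpt$parents))
  if (is.na(i)) 1 else cpt$parents[[i]]
}

.leak_failure <- function(network, child) {
  cpt <- network$disease_cpts[[child]]
  if (is.null(cpt)) cpt <- network$symptom_cpts[[child]]
  cpt$leak_failure
}

#' Validate a noisy-OR network
#'
#' Checks every structural invariant of the three-layer model: unique ids,
#' known layers, probabilities in \[0, 1\], exactly one CPT per disease and
#' symptom, one prior per risk factor, and edges that only run risk->disease
#' and disease->symptom.  Violations are described, never thrown, so callers
#' can report all problems at once.
#'
#' @param network a [noisy_or_network()].
#' @return Character vector of violation descriptions; empty when the network
#'   is well formed.
#' @export
validate_network <- function(network) {
  v <- character(0)
  nodes <- network$nodes
  dup <- unique(nodes$id[duplicated(nodes$id)])
  for (id in dup) v <- c(v, sprintf("duplicate-id: node id '%s' is not unique", id))
  bad_layer <- nodes$id[!nodes$layer %in% c("risk", "disease", "symptom")]
  for (id in bad_layer) v <- c(v, sprintf("unknown-layer: node '%s' has an unrecognised layer", id))

  rids <- risk_ids(network); dids <- disease_ids(network); sids <- symptom_ids(network)

  miss_prior <- setdiff(rids, names(network$risk_priors))
  for (id in miss_prior) v <- c(v, sprintf("missing-prior: risk factor '%s' has no prior", id))
  extra_prior <- setdiff(names(network$risk_priors), rids)
  for (id in extra_prior) v <- c(v, sprintf("stray-prior: prior given for '%s' which is not a risk node", id))
  for (id in intersect(rids, names(network$risk_priors))) {
    p <- network$risk_priors[[id]]
    if (!is.finite(p) || p < 0 || p > 1)
      v <- c(v, sprintf("probability-range: prior of risk factor '%s' is %g, outside [0,1]", id, p))
  }

  check_cpts <- function(cpts, children, parent_pool, parent_layer, child_layer) {
    out <- character(0)
    miss <- setdiff(children, names(cpts))
    for (id in miss) out <- c(out, sprintf("missing-cpt: %s '%s' has no CPT", child_layer, id))
    stray <- setdiff(names(cpts), children)
    for (id in stray) out <- c(out, sprintf("stray-cpt: CPT given for '%s' which is not a %s node", id, child_layer))
    for (id in intersect(children, names(cpts))) {
      cpt <- cpts[[id]]
      l0 <- cpt$leak_failure
      if (length(l0) != 1 || !is.finite(l0) || l0 < 0 || l0 > 1)
        out <- c(out, sprintf("probability-range: leak_failure of '%s' is outside [0,1]", id))
      for (p in names(cpt$parents)) {
        if (!p %in% parent_pool)
          out <- c(out, sprintf("layer-order: edge %s->%s violates the %s->%s layering", p, id, parent_layer, child_layer))
        lam <- cpt$parents[[p]]
        if (!is.finite(lam) || lam < 0 || lam > 1)
          out <- c(out, sprintf("probability-range: lambda on edge %s->%s is %g, outside [0,1]", p, id, lam))
      }
      if (anyDuplicated(names(cpt$parents)))
        out <- c(out, sprintf("duplicate-edge: '%s' lists a parent twice", id))
    }
    out
  }
  v <- c(v, check_cpts(network$disease_cpts, dids, rids, "risk", "disease"))
  v <- c(v, check_cpts(network$symptom_cpts, sids, dids, "disease", "symptom"))
  v
}

.assert_valid <- function(network) {
  v <- validate_network(network)
  if (length(v)) stop("invalid network: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(network)
}

#' Single-link worked example network
#'
#' The smallest interesting diagnostic network: one disease `D` with marginal
#' prevalence `prior` (encoded through its leak) and one symptom `S` with
#' activation failure `lambda` on the D->S edge and leak failure `leak`.
#' With the defaults, `P(S=1) = 1 - 0.9 (1 - 0.2 * 0.6) = 0.208`, the
#' posterior of D given S is `0.128/0.208`, its expected sufficiency
#' `0.12/0.208` and its expected disablement `0.108/0.208`.
#'
#' @param prior marginal prevalence of the disease.
#' @param lambda failure probability of the disease->symptom activation.
#' @param leak leak failure probability of the symptom.
#' @return A [noisy_or_network()] with one disease and one symptom.
#' @export
single_link_network <- function(prior = 0.2, lambda = 0.4, leak = 0.9) {
  noisy_or_network(
    nodes = data.frame(id = c("D", "S"), layer = c("disease", "symptom")),
    disease_cpts = list(D = list(parents = NULL, leak_failure = 1 - prior)),
    symptom_cpts = list(S = list(parents = c(D = lambda), leak_failure = leak)))
}
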