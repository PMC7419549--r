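#' Build a twin network for an intervention
#'
#' The twin network represents the factual and counterfactual worlds in one
#' SCM: every node affected by the intervention (each intervened node, each
#' child whose leak is forced, and all of their descendants) gets a
#' counterfactual copy whose incoming mechanism is severed or modified, while
#' both copies of every mechanism share the same exogenous noise entries.
#' Counterfactual queries then become ordinary conditional queries on this
#' single model: the factual half carries the evidence, the counterfactual
#' half the intervention.
#'
#' @param network a [noisy_or_network()].
#' @param intervention named 0/1 vector of `do()` targets (node ids or
#'   `"leak:<child>"`); may be empty.
#' @return An object of class `twin_network` with fields `base`,
#'   `intervention` and `copies` (ids of nodes with a counterfactual copy).
#' @export
build_twin_network <- function(network, intervention = NULL) {
  iv <- .check_intervention(network, intervention)
  seeds <- unique(sub("^leak:", "", names(iv)))
  copies <- character(0)
  if (length(seeds)) {
    dis_children <- function(rid)
      names(Filter(function(c) rid %in% names(c$parents), network$disease_cpts))
    sym_children <- function(did)
      names(Filter(function(c) did %in% names(c$parents), network$symptom_cpts))
    for (s in seeds) {
      layer <- network$nodes$layer[match(s, network$nodes$id)]
      copies <- c(copies, s)
      if (layer == "risk") {
        ds <- dis_children(s)
        copies <- c(copies, ds, unlist(lapply(ds, sym_children)))
      } else if (layer == "disease") {
        copies <- c(copies, sym_children(s))
      }
    }
  }
  structure(list(base = network, intervention = iv,
                 copies = sort(unique(copies))),
            class = "twin_network")
}

#' @export
print.twin_network <- function(x, ...) {
  cat(sprintf("<twin_network> %d counterfactual cop%s under do(%s)\n",
              length(x$copies), if (length(x$copies) == 1) "y" else "ies",
              if (length(x$intervention))
                paste(sprintf("%s=%d", names(x$intervention), x$intervention),
                      collapse = ", ")
              else ""))
  if (length(x$copies)) cat("  copied nodes:", paste(x$copies, collapse = ", "), "\n")
  invisible(x)
}

#' Counterfactual query specification
#'
#' @param ev factual [evidence()].
#' @param intervention named 0/1 vector of `do()` targets.
#' @param target node id whose counterfactual copy is queried.
#' @param value queried value (0 or 1).
#' @return An object of class `counterfactual_query`.
#' @export
counterfactual_query <- function(ev, intervention, target, value) {
  structure(list(evidence = ev, intervention = intervention,
                 target = target, value = as.integer(value)),
            class = "counterfactual_query")
}

# ---- twin-network exact inference engine ----------------------------------
#
# Computes, in one pass, P(factual evidence) and a numerator
# P(factual evidence, counterfactual node = value) for each requested term.
# The enumeration runs over the factual risk layer and over joint
# (factual, counterfactual) disease configurations, whose per-disease joint
# distribution under shared noise is written down analytically; symptom-layer
# two-world terms are likewise analytic:
#   P(S_f = 0, S_cf = 0 | pa_f, pa_cf) = prod of failure probabilities over
#   the union of the attempts active in either world (shared noise counted
#   once), from which the full 2x2 joint follows.
# This is exact inference on the twin network without enumerating noise.
.twin_expectations <- function(network, ev, intervention, terms) {
  ev <- .check_evidence(network, ev)
  iv <- .check_intervention(network, intervention)

  nodes <- network$nodes
  layer_of <- function(id) nodes$layer[match(id, nodes$id)]
  iv_ids <- names(iv)
  is_leak <- startsWith(iv_ids, "leak:")
  leak_child <- sub("^leak:", "", iv_ids[is_leak])
  iv_leak <- stats::setNames(iv[is_leak], leak_child)
  iv_node <- iv[!is_leak]
  iv_risk <- iv_node[vapply(names(iv_node), layer_of, "") == "risk"]
  iv_dis  <- iv_node[vapply(names(iv_node), layer_of, "") == "disease"]
  iv_sym  <- iv_node[vapply(names(iv_node), layer_of, "") == "symptom"]

  term_nodes <- vapply(terms, `[[`, "", "node")
  term_vals  <- vapply(terms, function(t) as.integer(t$value), 0L)
  term_layer <- vapply(term_nodes, layer_of, "")
  evid_sym <- c(ev$positive, ev$negative)

  relevant_dis <- unique(c(
    unlist(lapply(c(evid_sym, term_nodes[term_layer == "symptom"]),
                  function(s) names(network$symptom_cpts[[s]]$parents))),
    names(iv_dis), names(iv_leak)[layer_of(names(iv_leak)) == "disease"],
    term_nodes[term_layer == "disease"]))
  relevant_dis <- relevant_dis[!is.na(relevant_dis)]

  pa_r <- unique(c(unlist(lapply(relevant_dis, function(j)
    names(network$disease_cpts[[j]]$parents))),
    term_nodes[term_layer == "risk"]))
  enum_r <- setdiff(pa_r, names(ev$risk))
  if (length(enum_r) > 20L)
    stop("twin inference would enumerate 2^", length(enum_r),
         " risk configurations; model too large for the exact contract",
         call. = FALSE)

  denom <- 0
  nums <- numeric(length(terms))

  for (mask in 0:(bitwShiftL(1L, length(enum_r)) - 1L)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_along(enum_r) - 1L), 1L)
    r <- c(ev$risk, stats::setNames(bits, enum_r))
    wr <- prod(ifelse(bits == 1L, network$risk_priors[enum_r],
                      1 - network$risk_priors[enum_r]))
    if (wr == 0) next
    rp <- r
    for (t in intersect(names(iv_risk), names(rp))) rp[[t]] <- iv_risk[[t]]

    # per-disease joint over (factual, counterfactual) states
    dis_entries <- lapply(relevant_dis, function(j) {
      cpt <- network$disease_cpts[[j]]
      pa <- names(cpt$parents)
      on_f <- pa[vapply(pa, function(p) r[[p]] == 1L, TRUE)]
      qF <- cpt$leak_failure * prod(cpt$parents[on_f])
      if (j %in% names(iv_dis)) {
        v <- iv_dis[[j]]
        return(list(pairs = rbind(c(0L, v), c(1L, v)), probs = c(qF, 1 - qF)))
      }
      on_c <- pa[vapply(pa, function(p) rp[[p]] == 1L, TRUE)]
      leak_cf <- if (j %in% names(iv_leak)) iv_leak[[j]] else NA_integer_
      if (is.na(leak_cf) && setequal(on_f, on_c)) {
        return(list(pairs = rbind(c(0L, 0L), c(1L, 1L)), probs = c(qF, 1 - qF)))
      }
      if (identical(leak_cf, 1L)) { qC <- 0; qB <- 0 }
      else {
        lc <- if (identical(leak_cf, 0L)) 1 else cpt$leak_failure
        qC <- lc * prod(cpt$parents[on_c])
        lb <- cpt$leak_failure        # factual leak always a live attempt
        qB <- lb * prod(cpt$parents[union(on_f, on_c)])
      }
      p <- c(qB, qF - qB, qC - qB, 1 - qF - qC + qB)
      list(pairs = rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)),
           probs = pmax(p, 0))
    })

    nd <- length(relevant_dis)
    if (nd == 0L) {
      Dm <- matrix(0L, 1, 0); Pm <- matrix(0L, 1, 0); pc <- 1
    } else {
      grid <- as.matrix(expand.grid(lapply(dis_entries, function(e)
        seq_len(nrow(e$pairs)))))
      pc <- rep(1, nrow(grid))
      Dm <- matrix(0L, nrow(grid), nd, dimnames = list(NULL, relevant_dis))
      Pm <- Dm
      for (jj in seq_len(nd)) {
        e <- dis_entries[[jj]]
        Dm[, jj] <- e$pairs[grid[, jj], 1L]
        Pm[, jj] <- e$pairs[grid[, jj], 2L]
        pc <- pc * e$probs[grid[, jj]]
      }
      keep <- pc > 0
      Dm <- Dm[keep, , drop = FALSE]; Pm <- Pm[keep, , drop = FALSE]
      pc <- pc[keep]
    }
    ncmb <- length(pc)

    # factual off-probability of a symptom, per combination
    q_fact <- function(s, states) {
      cpt <- network$symptom_cpts[[s]]
      q <- rep(cpt$leak_failure, ncmb)
      for (j in names(cpt$parents))
        q <- q * ifelse(states[, j] == 1L, cpt$parents[[j]], 1)
      q
    }
    f_ev <- lapply(evid_sym, function(s) {
      q <- q_fact(s, Dm)
      if (s %in% ev$positive) 1 - q else q
    })
    names(f_ev) <- evid_sym
    ev_factor <- Reduce(`*`, f_ev, rep(1, ncmb))

    denom <- denom + wr * sum(pc * ev_factor)

    for (ti in seq_along(terms)) {
      node <- term_nodes[ti]; v <- term_vals[ti]
      if (term_layer[ti] == "risk") {
        cf_val <- if (node %in% names(iv_risk)) iv_risk[[node]]
                  else if (node %in% names(r)) r[[node]] else NA_integer_
        nums[ti] <- nums[ti] + wr * sum(pc * ev_factor) * as.integer(cf_val == v)
      } else if (term_layer[ti] == "disease") {
        nums[ti] <- nums[ti] + wr * sum(pc * ev_factor * (Pm[, node] == v))
      } else {
        ev_excl <- Reduce(`*`, f_ev[setdiff(evid_sym, node)], rep(1, ncmb))
        cpt <- network$symptom_cpts[[node]]
        if (node %in% names(iv_sym)) {
          fact <- if (node %in% evid_sym) f_ev[[node]] else rep(1, ncmb)
          g <- fact * as.integer(iv_sym[[node]] == v)
        } else {
          qF <- q_fact(node, Dm)
          leak_cf <- if (node %in% names(iv_leak)) iv_leak[[node]] else NA_integer_
          if (identical(leak_cf, 1L)) { qC <- rep(0, ncmb); qB <- rep(0, ncmb) }
          else {
            lc <- if (identical(leak_cf, 0L)) 1 else cpt$leak_failure
            qC <- rep(lc, ncmb); qB <- rep(cpt$leak_failure, ncmb)
            for (j in names(cpt$parents)) {
              lam <- cpt$parents[[j]]
              qC <- qC * ifelse(Pm[, j] == 1L, lam, 1)
              qB <- qB * ifelse(Dm[, j] == 1L | Pm[, j] == 1L, lam, 1)
            }
          }
          g <- if (node %in% ev$positive) {
            if (v == 1L) 1 - qF - qC + qB else qC - qB
          } else if (node %in% ev$negative) {
            if (v == 1L) qF - qB else qB
          } else {
            if (v == 1L) 1 - qC else qC
          }
        }
        nums[ti] <- nums[ti] + wr * sum(pc * ev_excl * g)
      }
    }
  }
  list(denominator = denom, numerators = nums)
}

#' Exact counterfactual probability on the twin network
#'
#' Computes `P(target' = value | evidence, do(intervention))`: the
#' probability that the counterfactual copy of `target` takes `value` under
#' the intervention, conditioned on the factual evidence, with all exogenous
#' noise shared between the two worlds.  Inference runs on the twin network
#' by exact summation (see [build_twin_network()]); it agrees with
#' abduction-action-prediction ([abduction_query()]) to numerical precision.
#'
#' @param network a [noisy_or_network()].
#' @param query a [counterfactual_query()].
#' @return Probability in \[0, 1\].
#' @export
counterfactual_probability <- function(network, query) {
  res <- .twin_expectations(network, query$evidence, query$intervention,
                            list(list(node = query$target, value = query$value)))
  if (res$denominator <= 0)
    .stop_domain("conditioning on null event: factual evidence has probability zero")
  min(1, max(0, res$numerators[1] / res$denominator))
}

#' Abduction-action-prediction oracle
#'
#' Reference implementation of the same counterfactual query by the
#' textbook three-step recipe: enumerate every exogenous state, keep those
#' consistent with the factual evidence (abduction), apply the intervention
#' and re-evaluate the network deterministically (action + prediction), and
#' average.  Exponential in the number of noise terms, so only usable on
#' small networks; it exists to verify [counterfactual_probability()] and the
#' closed-form measures.
#'
#' @inheritParams counterfactual_probability
#' @return Probability in \[0, 1\].
#' @export
abduction_query <- function(network, query) {
  ab <- .abduction_posterior(network, query$evidence)
  cf <- .eval_matrix(network, ab$tab, ab$B, query$intervention)
  sum(ab$W[cf[, query$target] == query$value]) / sum(ab$W)
}

# noise posterior given factual evidence, as (bit matrix, weights)
.abduction_posterior <- function(network, ev) {
  ev <- .check_evidence(network, ev)
  enum <- .enumerate_noise(network)
  fact <- .eval_matrix(network, enum$tab, enum$B, NULL)
  keep <- rep(TRUE, nrow(enum$B))
  for (rid in names(ev$risk)) keep <- keep & fact[, rid] == ev$risk[[rid]]
  for (s in ev$positive) keep <- keep & fact[, s] == 1L
  for (s in ev$negative) keep <- keep & fact[, s] == 0L
  W <- enum$W[keep]
  if (sum(W) <= 0)
    .stop_domain("conditioning on null event: factual evidence has probability zero")
  list(tab = enum$tab, B = enum$B[keep, , drop = FALSE], W = W,
       fact = fact[keep, , drop = FALSE])
}
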