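#' Exogenous (noise) state of the structural causal model
#'
#' In the SCM reading of a noisy-OR network every source of randomness is an
#' explicit binary exogenous variable: one draw per risk factor, one failure
#' indicator per edge (`u = 1` means the activation fails, with
#' `P(u = 1) = lambda`) and one failure indicator per leak
#' (`P(u0 = 1) = leak_failure`).  Given a complete exogenous state the whole
#' network is deterministic, which is what [structural_eval()] exploits.
#'
#' @param risk_draws named integer vector (0/1), one entry per risk factor.
#' @param edge_noise named integer vector (0/1), names of the form
#'   `"parent->child"`, one entry per edge.
#' @param leak_noise named integer vector (0/1), one entry per disease or
#'   symptom (the leak of that child).
#' @return An object of class `exogenous_state`.
#' @export
exogenous_state <- function(risk_draws = integer(), edge_noise = integer(),
                            leak_noise = integer()) {
  structure(list(risk_draws = .named_int(risk_draws),
                 edge_noise = .named_int(edge_noise),
                 leak_noise = .named_int(leak_noise)),
            class = "exogenous_state")
}

.named_int <- function(x) {
  out <- as.integer(unlist(x))
  names(out) <- names(unlist(x))
  if (length(out) == 0) names(out) <- character(0)
  out
}

.edge_key <- function(parent, child) paste0(parent, "->", child)

# Canonical table of every exogenous component, in the deterministic order
# used by forward_sample and the enumeration oracle: risks sorted by id,
# edges sorted by (child, parent), leaks sorted by child id.
.noise_table <- function(network) {
  rids <- sort(risk_ids(network))
  rows <- list()
  if (length(rids))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "risk", parent = NA_character_, child = rids,
      name = paste0("risk:", rids),
      p1 = as.numeric(network$risk_priors[rids]))
  children <- c(sort(disease_ids(network)), sort(symptom_ids(network)))
  for (ch in children) {
    pa <- sort(node_parents(network, ch))
    if (length(pa))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "edge", parent = pa, child = ch,
        name = .edge_key(pa, ch),
        p1 = vapply(pa, function(p) edge_lambda(network, p, ch), 0))
  }
  if (length(children))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "leak", parent = NA_character_, child = children,
      name = paste0("leak:", children),
      p1 = vapply(children, function(ch) .leak_failure(network, ch), 0))
  if (!length(rows))
    return(data.frame(kind = character(), parent = character(),
                      child = character(), name = character(), p1 = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.check_intervention <- function(network, intervention) {
  if (is.null(intervention) || length(intervention) == 0)
    return(stats::setNames(integer(0), character(0)))
  iv <- .named_int(intervention)
  ids <- names(iv)
  leak_targets <- startsWith(ids, "leak:")
  bad <- ids[!leak_targets & !ids %in% network$nodes$id]
  bad <- c(bad, ids[leak_targets & !sub("^leak:", "", ids) %in%
                      c(names(network$disease_cpts), names(network$symptom_cpts))])
  if (length(bad))
    stop("intervention targets not in network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!iv %in% c(0L, 1L)))
    stop("intervention values must be 0 or 1", call. = FALSE)
  iv
}

#' Deterministic structural evaluation of the SCM
#'
#' Evaluates every node of the network given a complete exogenous state and
#' an optional intervention.  Risk factors take their drawn values; each
#' non-intervened child is the Boolean OR of `parent_value AND NOT u_edge`
#' over its parents, OR `NOT u_leak` for the always-on leak parent.
#' Intervened nodes take their forced values and their incoming mechanism is
#' ignored; a target of the form `"leak:<child>"` forces the leak
#' contribution of that child instead (used by the sufficiency measure to
#' switch off exogenous causes).
#'
#' @param network a [noisy_or_network()].
#' @param noise an [exogenous_state()]; must be complete.
#' @param intervention named 0/1 vector of `do()` targets (node ids or
#'   `"leak:<child>"`), or `NULL`.
#' @return Named integer vector of 0/1 values over all nodes (a total
#'   assignment).
#' @export
structural_eval <- function(network, noise, intervention = NULL) {
  tab <- .noise_table(network)
  iv <- .check_intervention(network, intervention)
  have <- c(paste0("risk:", names(noise$risk_draws)), names(noise$edge_noise),
            paste0("leak:", names(noise$leak_noise)))
  missing <- setdiff(tab$name, have)
  if (length(missing))
    stop("incomplete exogenous state; missing entries: ",
         paste(missing, collapse = ", "), call. = FALSE)

  val <- stats::setNames(integer(nrow(network$nodes)), network$nodes$id)
  for (r in risk_ids(network))
    val[r] <- if (r %in% names(iv)) iv[[r]] else noise$risk_draws[[r]]
  eval_child <- function(ch, cpt) {
    if (ch %in% names(iv)) return(iv[[ch]])
    leak_key <- paste0("leak:", ch)
    on <- if (leak_key %in% names(iv)) iv[[leak_key]] else 1L - noise$leak_noise[[ch]]
    for (p in names(cpt$parents)) {
      u <- noise$edge_noise[[.edge_key(p, ch)]]
      on <- on | (val[[p]] & !u)
    }
    as.integer(on)
  }
  for (d in disease_ids(network)) val[d] <- eval_child(d, network$disease_cpts[[d]])
  for (s in symptom_ids(network)) val[s] <- eval_child(s, network$symptom_cpts[[s]])
  val
}

#' Joint probability of a total assignment
#'
#' Product over nodes of the noisy-OR conditional terms: a risk factor
#' contributes its prior, and a child that is off contributes
#' `leak_failure * prod(lambda over parents that are on)`, a child that is on
#' the complement.  Sums to one over all total assignments.
#'
#' @param network a [noisy_or_network()].
#' @param assignment named 0/1 vector covering every node.
#' @return Probability of the assignment under the network.
#' @export
joint_probability <- function(network, assignment) {
  a <- .named_int(assignment)
  missing <- setdiff(network$nodes$id, names(a))
  if (length(missing))
    stop("partial assignment; missing nodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- 1
  for (r in risk_ids(network)) {
    pr <- network$risk_priors[[r]]
    p <- p * if (a[[r]] == 1L) pr else 1 - pr
  }
  off_term <- function(ch, cpt) {
    q <- cpt$leak_failure
    for (pa in names(cpt$parents)) if (a[[pa]] == 1L) q <- q * cpt$parents[[pa]]
    q
  }
  for (d in disease_ids(network)) {
    q <- off_term(d, network$disease_cpts[[d]])
    p <- p * if (a[[d]] == 1L) 1 - q else q
  }
  for (s in symptom_ids(network)) {
    q <- off_term(s, network$symptom_cpts[[s]])
    p <- p * if (a[[s]] == 1L) 1 - q else q
  }
  p
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Forward-sample the SCM
#'
#' Draws a complete exogenous state (each component independently with its
#' stated probability, in the canonical sorted order so results are
#' platform-stable) and evaluates the network.  The same seed always yields
#' the same `(noise, assignment)` pair.
#'
#' @param network a [noisy_or_network()].
#' @param seed integer seed for the draw.
#' @return List with elements `noise` (an [exogenous_state()]) and
#'   `assignment` (named 0/1 vector).
#' @export
forward_sample <- function(network, seed) {
  tab <- .noise_table(network)
  bits <- .with_seed(seed, as.integer(stats::runif(nrow(tab)) < tab$p1))
  noise <- .bits_to_state(tab, bits)
  list(noise = noise,
       assignment = structural_eval(network, noise, NULL))
}

.bits_to_state <- function(tab, bits) {
  exogenous_state(
    risk_draws = stats::setNames(bits[tab$kind == "risk"], tab$child[tab$kind == "risk"]),
    edge_noise = stats::setNames(bits[tab$kind == "edge"], tab$name[tab$kind == "edge"]),
    leak_noise = stats::setNames(bits[tab$kind == "leak"], tab$child[tab$kind == "leak"]))
}

# ---- vectorised exogenous-state enumeration (abduction oracle backend) ----

# All 2^m exogenous states as a bit matrix plus their probabilities.
.enumerate_noise <- function(network, max_bits = 22L) {
  tab <- .noise_table(network)
  m <- nrow(tab)
  if (m > max_bits)
    stop(sprintf("noise enumeration needs 2^%d states; limit is 2^%d", m, max_bits),
         call. = FALSE)
  n <- bitwShiftL(1L, m)
  idx <- 0:(n - 1L)
  B <- vapply(seq_len(m),
              function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L),
              integer(n))
  if (m == 1L) B <- matrix(B, ncol = 1L)
  if (m == 0L) B <- matrix(integer(0), nrow = 1L, ncol = 0L)
  W <- rep(1, nrow(B))
  for (j in seq_len(m)) W <- W * ifelse(B[, j] == 1L, tab$p1[j], 1 - tab$p1[j])
  list(tab = tab, B = B, W = W)
}

# Vectorised structural_eval over the rows of a bit matrix.
.eval_matrix <- function(network, tab, B, intervention = NULL) {
  iv <- .check_intervention(network, intervention)
  n <- nrow(B)
  col <- function(name) B[, match(name, tab$name)]
  out <- matrix(0L, nrow = n, ncol = nrow(network$nodes),
                dimnames = list(NULL, network$nodes$id))
  for (r in risk_ids(network))
    out[, r] <- if (r %in% names(iv)) rep(iv[[r]], n) else col(paste0("risk:", r))
  eval_child <- function(ch, cpt) {
    if (ch %in% names(iv)) return(rep(iv[[ch]], n))
    leak_key <- paste0("leak:", ch)
    on <- if (leak_key %in% names(iv)) rep(iv[[leak_key]], n) else 1L - col(leak_key)
    for (p in names(cpt$parents))
      on <- on | (out[, p] & !col(.edge_key(p, ch)))
    as.integer(on)
  }
  for (d in disease_ids(network)) out[, d] <- eval_child(d, network$disease_cpts[[d]])
  for (s in symptom_ids(network)) out[, s] <- eval_child(s, network$symptom_cpts[[s]])
  out
}
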