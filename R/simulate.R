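#' Configuration for the synthetic network and vignette generator
#'
#' Collects every knob of the fixture generator: layer sizes, edge densities,
#' parameter ranges, evidence-reveal probabilities and the differential-size
#' distribution.  Defaults describe a small but clinically plausible regime:
#' moderately prevalent risk factors, diseases with low baseline prevalence
#' (leak failure near one), symptoms that rarely appear without a modelled
#' cause, vignettes that reveal most present symptoms but few absent ones,
#' and differential sizes averaging 2.58 diseases.
#'
#' @param n_risk,n_disease,n_symptom layer sizes.
#' @param density_risk probability of each risk->disease edge.
#' @param density_symptom probability of each disease->symptom edge; every
#'   symptom is guaranteed at least one disease parent, so this must be
#'   positive.
#' @param risk_prior_range,lambda_range,disease_leak_range,symptom_leak_range
#'   uniform sampling ranges within \[0, 1\].
#' @param reveal_positive,reveal_negative,reveal_risk probability that a
#'   sampled-present symptom, sampled-absent symptom, or risk-factor value is
#'   included in the vignette evidence.
#' @param k_mean mean differential size; `k ~ 1 + Poisson(k_mean - 1)`.
#' @param disease_choice `"uniform"` or `"prior"` (prior-weighted) choice of
#'   the vignette's true disease.
#' @param seed master seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_risk = 2, n_disease = 3, n_symptom = 3,
                             density_risk = 0.5, density_symptom = 0.5,
                             risk_prior_range = c(0.05, 0.5),
                             lambda_range = c(0.1, 0.9),
                             disease_leak_range = c(0.7, 0.99),
                             symptom_leak_range = c(0.85, 0.99),
                             reveal_positive = 0.9, reveal_negative = 0.3,
                             reveal_risk = 0.75,
                             k_mean = 2.58,
                             disease_choice = c("uniform", "prior"),
                             seed = 1L) {
  cfg <- list(n_risk = as.integer(n_risk), n_disease = as.integer(n_disease),
              n_symptom = as.integer(n_symptom),
              density_risk = density_risk, density_symptom = density_symptom,
              risk_prior_range = risk_prior_range, lambda_range = lambda_range,
              disease_leak_range = disease_leak_range,
              symptom_leak_range = symptom_leak_range,
              reveal_positive = reveal_positive,
              reveal_negative = reveal_negative, reveal_risk = reveal_risk,
              k_mean = k_mean, disease_choice = match.arg(disease_choice),
              seed = as.integer(seed))
  probs <- c(cfg$density_risk, cfg$density_symptom, cfg$reveal_positive,
             cfg$reveal_negative, cfg$reveal_risk,
             cfg$risk_prior_range, cfg$lambda_range, cfg$disease_leak_range,
             cfg$symptom_leak_range)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities and ranges must lie in [0, 1]", call. = FALSE)
  if (cfg$n_disease < 1) stop("need at least one disease", call. = FALSE)
  if (cfg$k_mean < 1) stop("k_mean must be at least 1", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Generate a random three-layer noisy-OR network
#'
#' Draws a layered DAG honouring the configured edge densities (every
#' symptom receives at least one disease parent; when the density draw gives
#' none, one parent is drawn uniformly) with all parameters uniform in their
#' configured ranges.  Deterministic given the seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (default: the config's master seed).
#' @return A valid [noisy_or_network()].
#' @export
generate_network <- function(config, seed = config$seed) {
  if (config$n_symptom > 0 && config$density_symptom <= 0)
    stop("impossible config: density_symptom = 0 cannot satisfy the ",
         "at-least-one-parent rule for symptoms", call. = FALSE)
  wd <- max(2, nchar(as.character(max(config$n_risk, config$n_disease,
                                      config$n_symptom))))
  rid <- sprintf(paste0("R%0", wd, "d"), seq_len(config$n_risk))
  did <- sprintf(paste0("D%0", wd, "d"), seq_len(config$n_disease))
  sid <- sprintf(paste0("S%0", wd, "d"), seq_len(config$n_symptom))
  runif_in <- function(n, rg) stats::runif(n, rg[1], rg[2])
  .with_seed(seed, {
    priors <- stats::setNames(runif_in(config$n_risk, config$risk_prior_range), rid)
    disease_cpts <- lapply(did, function(d) {
      pa <- rid[stats::runif(config$n_risk) < config$density_risk]
      list(parents = stats::setNames(runif_in(length(pa), config$lambda_range), pa),
           leak_failure = runif_in(1, config$disease_leak_range))
    })
    names(disease_cpts) <- did
    symptom_cpts <- lapply(sid, function(s) {
      pa <- did[stats::runif(config$n_disease) < config$density_symptom]
      if (!length(pa)) pa <- sample(did, 1L)
      list(parents = stats::setNames(runif_in(length(pa), config$lambda_range), pa),
           leak_failure = runif_in(1, config$symptom_leak_range))
    })
    names(symptom_cpts) <- sid
    noisy_or_network(
      nodes = data.frame(id = c(rid, did, sid),
                         layer = rep(c("risk", "disease", "symptom"),
                                     c(length(rid), length(did), length(sid)))),
      risk_priors = priors, disease_cpts = disease_cpts,
      symptom_cpts = symptom_cpts)
  })
}

#' Simulate one clinical vignette
#'
#' Chooses a true disease (among diseases with at least one symptom child,
#' since a vignette must present symptoms), samples a patient world by
#' drawing exogenous
#' noise and evaluating the SCM with the true disease forced on (do-style
#' conditioning, rejecting worlds in which no child symptom of the true
#' disease is present), then reveals a non-exhaustive subset of the world as
#' evidence: each present symptom with probability `reveal_positive` (at
#' least one present child symptom of the true disease is always revealed so
#' the vignette has positive evidence), each absent symptom as negative
#' evidence with probability `reveal_negative` (unrevealed absent symptoms
#' become unobserved, never negative), and each risk factor with probability
#' `reveal_risk`.
#'
#' @param network a [noisy_or_network()].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param id vignette identifier.
#' @param max_reject rejection cap for the no-present-symptom case.
#' @return An object of class `clinical_vignette`.
#' @export
generate_vignette <- function(network, config, seed, id = paste0("vignette-", seed),
                              max_reject = 1e4) {
  all_dids <- disease_ids(network)
  if (!length(all_dids)) stop("network has no diseases", call. = FALSE)
  tab <- .noise_table(network)
  children_of <- function(d)
    names(Filter(function(c) d %in% names(c$parents), network$symptom_cpts))
  # only a disease with symptom children can present a vignette
  dids <- all_dids[vapply(all_dids, function(d) length(children_of(d)) > 0, TRUE)]
  if (!length(dids))
    stop("no disease has a symptom child; cannot produce positive evidence",
         call. = FALSE)
  .with_seed(seed, {
    true <- if (config$disease_choice == "prior") {
      w <- vapply(dids, function(d) disease_prior(network, d), 0)
      if (sum(w) <= 0) stop("all disease priors are zero", call. = FALSE)
      sample(dids, 1L, prob = w)
    } else if (length(dids) == 1L) dids else sample(dids, 1L)
    kids <- children_of(true)
    assignment <- NULL
    for (i in seq_len(max_reject)) {
      bits <- as.integer(stats::runif(nrow(tab)) < tab$p1)
      noise <- .bits_to_state(tab, bits)
      a <- structural_eval(network, noise, stats::setNames(1L, true))
      if (any(a[kids] == 1L)) { assignment <- a; break }
    }
    if (is.null(assignment))
      stop("rejection cap (", max_reject, ") exceeded while sampling a world ",
           "with a present symptom; consider lower symptom leak failures or ",
           "denser disease->symptom edges", call. = FALSE)
    sids <- symptom_ids(network)
    on <- sids[assignment[sids] == 1L]
    off <- sids[assignment[sids] == 0L]
    anchor <- {
      on_kids <- kids[assignment[kids] == 1L]
      if (length(on_kids) == 1L) on_kids else sample(on_kids, 1L)
    }
    pos <- unique(c(anchor, on[stats::runif(length(on)) < config$reveal_positive]))
    neg <- off[stats::runif(length(off)) < config$reveal_negative]
    rids <- risk_ids(network)
    shown <- rids[stats::runif(length(rids)) < config$reveal_risk]
    k <- min(length(dids), 1L + stats::rpois(1L, config$k_mean - 1))
    structure(list(
      id = id, true_disease = true,
      evidence = evidence(risk = assignment[shown], positive = sort(pos),
                          negative = sort(neg)),
      k = as.integer(k),
      provenance = list(seed = seed, generator = "cfdiag",
                        disease_choice = config$disease_choice,
                        reveal_positive = config$reveal_positive,
                        reveal_negative = config$reveal_negative,
                        reveal_risk = config$reveal_risk)),
      class = "clinical_vignette")
  })
}

#' @export
print.clinical_vignette <- function(x, ...) {
  cat(sprintf("<vignette> %s (true disease: %s, k = %s)\n", x$id,
              x$true_disease, x$k))
  print(x$evidence)
  invisible(x)
}

#' Simulate a cohort of vignettes
#'
#' Generates `n` vignettes with per-vignette seeds derived as
#' `master seed + index`, so the cohort is reproducible element-wise, and
#' optionally writes the byte-stable cohort JSON.
#'
#' @param network a [noisy_or_network()].
#' @param config a [generator_config()].
#' @param n number of vignettes (`>= 1`).
#' @param path optional output file for [write_cohort()].
#' @return List of `clinical_vignette` objects (invisibly writes `path` if given).
#' @export
generate_cohort <- function(network, config, n, path = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  cohort <- lapply(seq_len(n), function(i) {
    tryCatch(generate_vignette(network, config, seed = config$seed + i,
                               id = sprintf("vignette-%04d", i)),
             error = function(e)
               stop("vignette ", i, ": ", conditionMessage(e), call. = FALSE))
  })
  if (!is.null(path)) write_cohort(cohort, path)
  cohort
}

#' Confounded-structure fixture networks
#'
#' Small networks reproducing the three canonical disease/symptom causal
#' shapes used to illustrate why the posterior can fail as a diagnostic
#' score, realised inside the three-layer family:
#'
#' * `"direct"` — `D -> S`: the disease directly causes the symptom.
#' * `"confounded"` — a shared risk factor drives both the ranked disease
#'   `D` and a latent disease `D_latent` which causes `S`; `D` has **no**
#'   directed path to `S`, yet observing `S` raises its posterior through
#'   the back-door path.  Counterfactual measures score `D` exactly zero.
#' * `"both"` — direct cause plus the confounding path.
#'
#' * `"misleading"` — the confounded shape parameterised so the back-door
#'   association dominates: the risk factor activates `D` almost surely but
#'   drives `S` only weakly through `D_latent`, so the posterior ranks the
#'   non-cause `D` first while the counterfactual measures still score it
#'   exactly zero.
#'
#' @param shape which causal shape to build.
#' @return A valid [noisy_or_network()] containing disease `D` and symptom
#'   `S` (plus `R` and `D_latent` for the confounded shapes).
#' @export
confounder_fixture <- function(shape = c("confounded", "direct", "both",
                                         "misleading")) {
  shape <- match.arg(shape)
  if (shape == "direct") return(single_link_network())
  if (shape == "misleading") {
    return(noisy_or_network(
      nodes = data.frame(
        id = c("R", "D", "D_latent", "S"),
        layer = c("risk", "disease", "disease", "symptom")),
      risk_priors = c(R = 0.25),
      disease_cpts = list(
        D = list(parents = c(R = 0.02), leak_failure = 0.999),
        D_latent = list(parents = c(R = 0.85), leak_failure = 0.97)),
      symptom_cpts = list(
        S = list(parents = c(D_latent = 0.55), leak_failure = 0.9))))
  }
  d_to_s <- if (shape == "both") c(D_latent = 0.3, D = 0.4) else c(D_latent = 0.3)
  noisy_or_network(
    nodes = data.frame(
      id = c("R", "D", "D_latent", "S"),
      layer = c("risk", "disease", "disease", "symptom")),
    risk_priors = c(R = 0.3),
    disease_cpts = list(
      D = list(parents = c(R = 0.2), leak_failure = 0.95),
      D_latent = list(parents = c(R = 0.2), leak_failure = 0.95)),
    symptom_cpts = list(
      S = list(parents = d_to_s, leak_failure = 0.95)))
}
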