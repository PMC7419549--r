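#' Rank all diseases under a diagnostic measure
#'
#' Produces a full, deterministic ranking of every modelled disease under the
#' chosen measure.  Ties are broken by the higher posterior, then by
#' lexicographic disease id, so rankings are stable across runs.  Two rank
#' columns are attached: `position` is the 1-based place in the delivered
#' (tie-broken) order, used by top-k metrics; `position_min` shares the best
#' place among score ties, used for mean-rank summaries.
#'
#' @param network a [noisy_or_network()].
#' @param ev an [evidence()] object.
#' @param measure one of `"posterior"`, `"expected_disablement"`,
#'   `"expected_sufficiency"`.
#' @param method computation route for the counterfactual measures (see
#'   [expected_sufficiency()]).
#' @return An object of class `diagnosis_ranking`: a list with `measure` and
#'   `entries` (data.frame `disease`, `score`, `posterior`, `position`,
#'   `position_min`, sorted by rank).
#' @export
rank_diseases <- function(network, ev,
                          measure = c("posterior", "expected_disablement",
                                      "expected_sufficiency"),
                          method = "closed_form") {
  measure <- match.arg(measure)
  ev <- .check_evidence(network, ev)
  dids <- disease_ids(network)
  if (!length(dids)) stop("network has no diseases to rank", call. = FALSE)
  post <- vapply(dids, function(d) posterior_disease(network, ev, d), 0)
  score <- switch(measure,
    posterior = post,
    expected_disablement = vapply(dids, function(d)
      expected_disablement(network, ev, d, method = method), 0),
    expected_sufficiency = vapply(dids, function(d)
      expected_sufficiency(network, ev, d, method = method), 0))
  ord <- order(-score, -post, dids)
  entries <- data.frame(disease = dids[ord], score = score[ord],
                        posterior = post[ord])
  entries$position <- seq_len(nrow(entries))
  entries$position_min <- rank(-entries$score, ties.method = "min")
  rownames(entries) <- NULL
  structure(list(measure = measure, entries = entries),
            class = "diagnosis_ranking")
}

#' @export
print.diagnosis_ranking <- function(x, ...) {
  cat(sprintf("<diagnosis_ranking> measure: %s\n", x$measure))
  df <- x$entries
  df$score <- .fmt6(df$score)
  df$posterior <- .fmt6(df$posterior)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Position of a disease in a ranking
#'
#' @param ranking a `diagnosis_ranking`.
#' @param disease_id disease id.
#' @param ties `"order"` for the deterministic tie-broken position (top-k
#'   semantics) or `"min"` for the shared best position among score ties
#'   (mean-rank semantics).
#' @return Integer position (1-based).
#' @export
rank_of <- function(ranking, disease_id, ties = c("order", "min")) {
  ties <- match.arg(ties)
  i <- match(disease_id, ranking$entries$disease)
  if (is.na(i)) stop("disease '", disease_id, "' not in ranking", call. = FALSE)
  if (ties == "order") ranking$entries$position[i] else ranking$entries$position_min[i]
}

#' Evaluate diagnostic measures over a vignette cohort
#'
#' Runs the requested measures on every vignette, records the position of
#' the masked true disease, and assembles the cohort summary: top-k accuracy
#' curves, mean ranks, pairwise win/draw/loss counts against the posterior,
#' error-reduction curves, rarity strata, and matched-differential accuracy
#' where vignettes carry a differential size `k`.  Per-vignette inference
#' failures (e.g. zero-probability evidence) are caught, reported in
#' `failures`, and the run continues.
#'
#' @param network a [noisy_or_network()].
#' @param cohort list of vignettes ([generate_cohort()] or [read_cohort()]).
#' @param measures character subset of the three measures.
#' @param method computation route for counterfactual measures.
#' @param band_edges strictly increasing rarity band edges in (0, 1) on
#'   `P(D = 1 | R)`.  The default bands are conventional, not canonical.
#' @return An object of class `cohort_result` with `per_vignette`
#'   (data.frame), `summary` (list) and `failures`.
#' @export
evaluate_cohort <- function(network, cohort,
                            measures = c("posterior", "expected_sufficiency",
                                         "expected_disablement"),
                            method = "closed_form",
                            band_edges = default_band_edges()) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  if (length(band_edges) && (is.unsorted(band_edges, strictly = TRUE) ||
                             any(band_edges <= 0) || any(band_edges >= 1)))
    stop("band_edges must be strictly increasing within (0, 1)", call. = FALSE)

  rows <- list(); failures <- list()
  for (vg in cohort) {
    row <- tryCatch({
      prior <- disease_prior(network, vg$true_disease, vg$evidence$risk)
      out <- data.frame(id = vg$id, true_disease = vg$true_disease,
                        true_prior = prior,
                        k = if (is.null(vg$k)) NA_integer_ else vg$k)
      for (m in measures) {
        rk <- rank_diseases(network, vg$evidence, measure = m, method = method)
        out[[paste0("rank_", m)]] <- rank_of(rk, vg$true_disease, "order")
        out[[paste0("rank_min_", m)]] <- rank_of(rk, vg$true_disease, "min")
      }
      out
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- list(id = vg$id,
                                                 message = conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop("every vignette failed evaluation", call. = FALSE)
  per <- do.call(rbind, rows)
  per$band <- .rarity_band(per$true_prior, band_edges)

  n_dis <- length(disease_ids(network))
  summary <- list(n = nrow(per), n_failed = length(failures),
                  n_diseases = n_dis, measures = measures,
                  band_edges = band_edges,
                  band_note = "band edges are configuration defaults, not published thresholds",
                  tie_note = "mean ranks use tie-min positions; top-k uses the deterministic tie-broken order")
  for (m in measures) {
    summary[[paste0("topk_", m)]] <-
      vapply(seq_len(n_dis), function(k) mean(per[[paste0("rank_", m)]] <= k), 0)
    summary[[paste0("mean_rank_", m)]] <- mean(per[[paste0("rank_min_", m)]])
  }
  if ("posterior" %in% measures) {
    for (m in setdiff(measures, "posterior")) {
      acc_a <- summary$topk_posterior
      acc_c <- summary[[paste0("topk_", m)]]
      summary[[paste0("error_reduction_", m)]] <-
        ifelse(acc_a < 1, 1 - (1 - acc_c) / (1 - acc_a), NA_real_)
      summary[[paste0("comparison_", m)]] <-
        rank_positions_comparison(per[[paste0("rank_min_posterior")]],
                                  per[[paste0("rank_min_", m)]])
    }
  }
  if (!anyNA(per$k))
    summary$matched_k_accuracy <- vapply(measures, function(m)
      mean(per[[paste0("rank_", m)]] <= per$k), 0)
  structure(list(per_vignette = per, summary = summary, failures = failures,
                 measures = measures, band_edges = band_edges),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort_result> %d vignette(s), %d failed, %d disease(s)\n",
              s$n, s$n_failed, s$n_diseases))
  for (m in x$measures)
    cat(sprintf("  %-22s top-1 %.4f  top-5 %.4f  mean rank %.3f\n", m,
                s[[paste0("topk_", m)]][1],
                s[[paste0("topk_", m)]][min(5, s$n_diseases)],
                s[[paste0("mean_rank_", m)]]))
  invisible(x)
}

#' Top-k diagnostic accuracy
#'
#' Fraction of vignettes whose true disease appears in the top `k` of the
#' delivered ranking.  Non-decreasing in `k` and equal to 1 at
#' `k = ` number of diseases, since rankings are full.
#'
#' @param x a `cohort_result` or an integer vector of true-disease positions.
#' @param k cutoff, `1 <= k <= ` number of diseases.
#' @param measure which measure's ranks to use when `x` is a `cohort_result`.
#' @return Fraction in \[0, 1\].
#' @export
top_k_accuracy <- function(x, k, measure = NULL) {
  ranks <- if (inherits(x, "cohort_result")) {
    measure <- measure %||% x$measures[1]
    x$per_vignette[[paste0("rank_", measure)]]
  } else as.numeric(x)
  if (!length(ranks)) stop("empty cohort", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  mean(ranks <= k)
}

#' Relative error reduction between two accuracies
#'
#' `1 - (1 - acc_cf) / (1 - acc_assoc)`: the relative reduction in error
#' rate when switching from the associative to the counterfactual ranking.
#' Negative when the counterfactual accuracy is lower.
#'
#' @param acc_assoc accuracy of the reference (associative) ranking, `< 1`.
#' @param acc_cf accuracy of the comparison ranking.
#' @return Numeric (vectorised).
#' @export
error_reduction <- function(acc_assoc, acc_cf) {
  if (any(acc_assoc >= 1))
    stop("error reduction is undefined when the reference accuracy is 1",
         call. = FALSE)
  1 - (1 - acc_cf) / (1 - acc_assoc)
}

#' Compare true-disease positions between two measures
#'
#' Counts vignettes where measure B ranks the true disease strictly higher
#' (numerically smaller position) than measure A (a win for B), strictly
#' lower (a loss), or the same (a draw), and reports mean positions.
#'
#' @param x a `cohort_result`, or an integer vector of positions for A.
#' @param measure_a,measure_b measure names when `x` is a `cohort_result`.
#' @param positions_b positions for B when `x` is a vector.
#' @return List with `wins_b`, `losses_b`, `draws`, `n`, `mean_a`, `mean_b`.
#' @export
rank_comparison <- function(x, measure_a, measure_b, positions_b = NULL) {
  if (inherits(x, "cohort_result")) {
    a <- x$per_vignette[[paste0("rank_min_", measure_a)]]
    b <- x$per_vignette[[paste0("rank_min_", measure_b)]]
    if (is.null(a) || is.null(b))
      stop("both measures must have been computed on the cohort", call. = FALSE)
  } else {
    a <- as.numeric(x); b <- as.numeric(positions_b)
    if (length(a) != length(b))
      stop("position vectors must describe identical vignettes", call. = FALSE)
  }
  rank_positions_comparison(a, b)
}

rank_positions_comparison <- function(a, b) {
  list(wins_b = sum(b < a), losses_b = sum(b > a), draws = sum(a == b),
       n = length(a), mean_a = mean(a), mean_b = mean(b))
}

#' Default rarity band edges
#'
#' Conventional cut points on the patient-specific disease prior
#' `P(D = 1 | R)` used to stratify results by disease rareness.  They are a
#' configuration default, not published thresholds.
#'
#' @return Numeric vector of strictly increasing edges in (0, 1).
#' @export
default_band_edges <- function() c(1e-4, 1e-3, 1e-2, 5e-2, 2e-1)

.rarity_band <- function(prior, band_edges) {
  if (!length(band_edges)) return(rep("all", length(prior)))
  edges <- c(0, band_edges, 1)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  as.character(cut(prior, breaks = edges, labels = labs,
                   include.lowest = TRUE, right = FALSE))
}

#' Stratify cohort results by disease rareness
#'
#' Assigns each vignette to a rarity band by the true disease's prior given
#' the vignette's risk evidence, and summarises each band separately.  Bands
#' partition the cohort.
#'
#' @param network a [noisy_or_network()] (used only when priors must be
#'   recomputed; may be `NULL` if `cohort` already carries them).
#' @param cohort a `cohort_result`.
#' @param band_edges strictly increasing edges in (0, 1); empty for a single
#'   band.
#' @return Named list, one entry per non-empty band, each with `n`,
#'   mean ranks and top-1 accuracy per measure.
#' @export
stratify_by_rarity <- function(network, cohort, band_edges = default_band_edges()) {
  if (length(band_edges) && (is.unsorted(band_edges, strictly = TRUE) ||
                             any(band_edges <= 0) || any(band_edges >= 1)))
    stop("band_edges must be strictly increasing within (0, 1)", call. = FALSE)
  per <- cohort$per_vignette
  band <- .rarity_band(per$true_prior, band_edges)
  out <- list()
  for (bl in unique(band)) {
    sub <- per[band == bl, , drop = FALSE]
    entry <- list(n = nrow(sub))
    for (m in cohort$measures) {
      entry[[paste0("mean_rank_", m)]] <- mean(sub[[paste0("rank_min_", m)]])
      entry[[paste0("top1_", m)]] <- mean(sub[[paste0("rank_", m)]] <= 1)
    }
    out[[bl]] <- entry
  }
  out
}

#' Matched differential-size accuracy
#'
#' For each vignette with differential size `k`, scores a hit when the true
#' disease is in that vignette's top `k`; the cutoff varies per vignette,
#' mirroring how clinicians vary the size of a differential with their
#' uncertainty.
#'
#' @param cohort a `cohort_result` whose vignettes carry `k`.
#' @param measures measures to score (default: all evaluated).
#' @return Named numeric vector of accuracies per measure.
#' @export
matched_differential_evaluation <- function(cohort, measures = NULL) {
  measures <- measures %||% cohort$measures
  per <- cohort$per_vignette
  if (anyNA(per$k))
    stop("vignettes missing differential size k: ",
         paste(per$id[is.na(per$k)], collapse = ", "), call. = FALSE)
  vapply(measures, function(m) mean(per[[paste0("rank_", m)]] <= per$k), 0)
}
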