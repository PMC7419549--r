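#' Clinical evidence for one diagnostic query
#'
#' Evidence is a (possibly partial) assignment of risk factors plus two
#' disjoint symptom sets: positively evidenced symptoms (observed present)
#' and negatively evidenced symptoms (observed absent).  Symptoms in neither
#' set are unobserved and are marginalised by inference — they are never
#' treated as absent, because case vignettes list a non-exhaustive subset of
#' what is true of the patient.
#'
#' @param risk named 0/1 vector (or logical) of observed risk factors; may be
#'   empty or partial, unobserved risk factors are marginalised under their
#'   priors.
#' @param positive character vector of symptom ids observed present.
#' @param negative character vector of symptom ids observed absent.
#' @return An object of class `evidence`.
#' @examples
#' ev <- evidence(positive = "S")
#' @export
evidence <- function(risk = integer(), positive = character(),
                     negative = character()) {
  if (is.logical(risk)) risk <- stats::setNames(as.integer(risk), names(risk))
  risk <- .named_int(risk)
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  both <- intersect(positive, negative)
  if (length(both))
    .stop_schema(paste0("symptoms listed as both present and absent: ",
                        paste(both, collapse = ", ")))
  if (length(risk) && any(!risk %in% c(0L, 1L)))
    .stop_schema("risk evidence values must be 0/1")
  structure(list(risk = risk, positive = positive, negative = negative),
            class = "evidence")
}

#' @export
print.evidence <- function(x, ...) {
  rk <- if (length(x$risk))
    paste(sprintf("%s=%d", names(x$risk), x$risk), collapse = ", ") else "(none)"
  cat("<evidence>\n",
      "  risk factors: ", rk, "\n",
      "  present symptoms: ", if (length(x$positive)) paste(x$positive, collapse = ", ") else "(none)", "\n",
      "  absent symptoms:  ", if (length(x$negative)) paste(x$negative, collapse = ", ") else "(none)", "\n",
      sep = "")
  invisible(x)
}

.check_evidence <- function(network, ev) {
  if (!inherits(ev, "evidence")) ev <- do.call(evidence, ev)
  bad_risk <- setdiff(names(ev$risk), risk_ids(network))
  if (length(bad_risk))
    .stop_schema(paste0("risk evidence for unknown risk factor(s): ",
                        paste(bad_risk, collapse = ", ")))
  bad_sym <- setdiff(c(ev$positive, ev$negative), symptom_ids(network))
  if (length(bad_sym))
    .stop_schema(paste0("symptom evidence for unknown symptom(s): ",
                        paste(bad_sym, collapse = ", ")))
  ev
}
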