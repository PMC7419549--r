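#' Read and write disease-model files
#'
#' Models are stored as strict UTF-8 JSON:
#' `{"nodes": [{"id", "layer", "label"?}], "risk_priors": {id: p},
#'   "cpts": [{"child", "parents": {id: lambda}, "leak_failure": l0}]}`.
#' Node states elsewhere in the toolchain are JSON booleans.  Ids are the only
#' keys; there is no positional meaning.  `read_model(write_model(net))` is a
#' field-for-field identity.
#'
#' @param path file path.
#' @param network a valid [noisy_or_network()].
#' @param strict if `TRUE` (default) unknown fields are an error; otherwise a
#'   warning.
#' @return `read_model` returns a [noisy_or_network()]; `write_model` returns
#'   `path` invisibly.
#' @export
read_model <- function(path, strict = TRUE) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .stop_schema(paste0("not valid JSON: ", conditionMessage(e)), "$"))
  .check_fields(doc, c("nodes", "risk_priors", "cpts"), "$", strict,
                required = c("nodes", "cpts"))
  if (is.null(doc$nodes) || !length(doc$nodes)) .stop_schema("no nodes", "$.nodes")

  nodes <- do.call(rbind, lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    jp <- sprintf("$.nodes[%d]", i)
    .check_fields(nd, c("id", "layer", "label"), jp, strict, required = c("id", "layer"))
    data.frame(id = as.character(nd$id), layer = as.character(nd$layer),
               label = as.character(nd$label %||% nd$id))
  }))
  if (anyDuplicated(nodes$id))
    .stop_schema(paste0("duplicate node id: ",
                        paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")),
                 "$.nodes")

  priors <- vapply(doc$risk_priors %||% list(), as.numeric, 0)
  dis <- nodes$id[nodes$layer == "disease"]
  cpts <- list()
  for (i in seq_along(doc$cpts)) {
    cpt <- doc$cpts[[i]]
    jp <- sprintf("$.cpts[%d]", i)
    .check_fields(cpt, c("child", "parents", "leak_failure"), jp, strict,
                  required = c("child", "leak_failure"))
    if (is.null(cpt$leak_failure))
      .stop_schema("missing required field 'leak_failure'", jp)
    child <- as.character(cpt$child)
    if (child %in% names(cpts)) .stop_schema(paste0("duplicate CPT for '", child, "'"), jp)
    cpts[[child]] <- list(parents = vapply(cpt$parents %||% list(), as.numeric, 0),
                          leak_failure = as.numeric(cpt$leak_failure))
  }
  net <- noisy_or_network(nodes, risk_priors = priors,
                          disease_cpts = cpts[names(cpts) %in% dis],
                          symptom_cpts = cpts[!names(cpts) %in% dis])
  v <- validate_network(net)
  if (length(v)) .stop_schema(paste0("model violates invariants: ", paste(v, collapse = "; ")), "$")
  net
}

.check_fields <- function(obj, known, json_path, strict, required = character()) {
  miss <- setdiff(required, names(obj))
  if (length(miss))
    .stop_schema(paste0("missing required field '", miss[1], "'"), json_path)
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    msg <- paste0("unknown field(s): ", paste(extra, collapse = ", "))
    if (strict) .stop_schema(msg, json_path) else warning(msg, call. = FALSE)
  }
  invisible(obj)
}

#' @rdname read_model
#' @export
write_model <- function(network, path) {
  .assert_valid(network)
  nm_obj <- function(x) {
    if (length(x) == 0) return(structure(list(), names = character(0)))
    as.list(x)
  }
  cpt_entry <- function(child, cpt)
    list(child = child, parents = nm_obj(cpt$parents), leak_failure = cpt$leak_failure)
  doc <- list(
    nodes = lapply(seq_len(nrow(network$nodes)), function(i)
      list(id = network$nodes$id[i], layer = network$nodes$layer[i],
           label = network$nodes$label[i])),
    risk_priors = nm_obj(network$risk_priors),
    cpts = c(lapply(names(network$disease_cpts), function(d)
               cpt_entry(d, network$disease_cpts[[d]])),
             lapply(names(network$symptom_cpts), function(s)
               cpt_entry(s, network$symptom_cpts[[s]]))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write vignette cohorts
#'
#' A cohort file is a JSON array of vignettes:
#' `{"id", "true_disease", "risk_evidence": {id: bool},
#'   "symptoms": {"positive": [ids], "negative": [ids]}, "k"?: int,
#'   "provenance"?: {...}}`.  Field order is fixed so identical cohorts are
#' byte-identical on disk.
#'
#' @param path file path.
#' @param cohort list of vignettes as produced by [generate_cohort()].
#' @return `read_cohort` returns a list of `clinical_vignette` objects; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .stop_schema(paste0("not valid JSON: ", conditionMessage(e)), "$"))
  lapply(seq_along(doc), function(i) {
    vg <- doc[[i]]
    jp <- sprintf("$[%d]", i)
    .check_fields(vg, c("id", "true_disease", "risk_evidence", "symptoms", "k",
                        "provenance"), jp, strict = TRUE,
                  required = c("id", "true_disease", "symptoms"))
    risk <- vapply(vg$risk_evidence %||% list(), function(b) as.integer(isTRUE(b) || identical(b, 1L)), 0L)
    ev <- evidence(risk = risk,
                   positive = unlist(vg$symptoms$positive) %||% character(0),
                   negative = unlist(vg$symptoms$negative) %||% character(0))
    structure(list(id = vg$id, true_disease = vg$true_disease, evidence = ev,
                   k = if (is.null(vg$k)) NA_integer_ else as.integer(vg$k),
                   provenance = vg$provenance),
              class = "clinical_vignette")
  })
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  doc <- lapply(cohort, function(vg) {
    out <- list(
      id = vg$id,
      true_disease = vg$true_disease,
      risk_evidence = if (length(vg$evidence$risk))
        lapply(as.list(vg$evidence$risk), function(v) v == 1L)
      else structure(list(), names = character(0)),
      symptoms = list(positive = as.list(vg$evidence$positive),
                      negative = as.list(vg$evidence$negative)))
    if (!is.null(vg$k) && !is.na(vg$k)) out$k <- vg$k
    if (!is.null(vg$provenance)) out$provenance <- vg$provenance
    out
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
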