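`%||%` <- function(a, b) if (is.null(a)) b else a

# input / schema problems -> exit code 2 in the CLI
.stop_schema <- function(msg, json_path = NULL) {
  if (!is.null(json_path)) msg <- sprintf("%s (at %s)", msg, json_path)
  stop(structure(class = c("cfdiag_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# inference-domain problems (e.g. conditioning on a null event) -> exit code 3
.stop_domain <- function(msg) {
  stop(structure(class = c("cfdiag_domain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.fmt6 <- function(x) formatC(x, digits = 6, format = "f")

# iterate over all subsets of a character vector, calling f(subset, size)
.subset_apply <- function(items, f) {
  m <- length(items)
  if (m > 16L)
    stop("subset enumeration over positive symptoms is capped at 16 (got ", m, ")",
         call. = FALSE)
  n <- bitwShiftL(1L, m)
  out <- vector("list", n)
  for (mask in 0:(n - 1L)) {
    sel <- items[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    out[[mask + 1L]] <- f(sel, length(sel))
  }
  out
}
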