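# Operation counters: formal floating-point operation counts of the
# rate-determining contraction steps, used by the scaling probes.  Counts,
# not wall time.

.counters <- new.env(parent = emptyenv())

#' Reset all operation counters
#' @export
counters_reset <- function() {
  rm(list = ls(.counters), envir = .counters)
  invisible(NULL)
}

ctr_add <- function(name, n) {
  n <- as.numeric(n)          # counts exceed integer range quickly
  cur <- .counters[[name]]
  .counters[[name]] <- if (is.null(cur)) n else cur + n
  invisible(NULL)
}

#' Read the operation counters
#' @return named numeric vector of accumulated operation counts
#' @export
counters_get <- function() {
  nm <- ls(.counters)
  stats::setNames(vapply(nm, function(x) .counters[[x]], numeric(1)), nm)
}
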