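# Typed conditions: every validation failure raises a classed error so
# callers (and tests) can distinguish format, parse, validation, fit and
# insufficient-data failures without matching message strings.

ns_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "normsense_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ns_format_error     <- function(msg, ...) ns_stop("ns_format_error", msg, ...)
ns_parse_error      <- function(msg, ...) ns_stop("ns_parse_error", msg, ...)
ns_validation_error <- function(msg, ...) ns_stop("ns_validation_error", msg, ...)
ns_fit_error        <- function(msg, ...) ns_stop("ns_fit_error", msg, ...)
ns_io_error         <- function(msg, ...) ns_stop("ns_io_error", msg, ...)
ns_insufficient_data_error <- function(msg, ...)
  ns_stop("ns_insufficient_data_error", msg, ...)

# Seed scoping: run code under a given seed and restore the caller's RNG
# state afterwards, so simulators are deterministic without side effects.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    ns_validation_error("a single integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
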