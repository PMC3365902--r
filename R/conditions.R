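# Classed conditions so callers can distinguish recoverable situations
# (censored lengths, insufficient data) from genuine misuse.

pd_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "polypdemog_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_domain <- function(msg) pd_stop(msg, "pd_domain_error")
stop_config <- function(msg) pd_stop(msg, "pd_config_error")
stop_insufficient <- function(msg) pd_stop(msg, "pd_insufficient_data_error")
stop_request <- function(msg) pd_stop(msg, "pd_request_error")
stop_schema <- function(msg) pd_stop(msg, "pd_schema_error")
stop_censored <- function(msg) pd_stop(msg, "pd_censored_length")
stop_nonconvergent <- function(msg) pd_stop(msg, "pd_nonconvergent_growth_error")
stop_design <- function(msg) pd_stop(msg, "pd_design_error")
stop_missing_mass <- function(msg) pd_stop(msg, "pd_missing_mass_error")
stop_undefined <- function(msg) pd_stop(msg, "pd_undefined_summary_error")
stop_coverage <- function(msg) pd_stop(msg, "pd_coverage_error")
stop_overlap <- function(msg) pd_stop(msg, "pd_insufficient_overlap_error")
stop_correlation <- function(msg) pd_stop(msg, "pd_undefined_correlation_error")

# Evaluate `code` under a fixed RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
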