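#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish recoverable situations
## (incomplete years, insufficient data) from genuine misuse.

gw_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "gw_error")))
}

gw_format_error <- function(message, ...) gw_abort(message, "gw_format_error", ...)
gw_integrity_error <- function(message, ...) gw_abort(message, "gw_integrity_error", ...)
gw_incomplete_year <- function(message, ...) gw_abort(message, "gw_incomplete_year", ...)
gw_insufficient_data <- function(message, ...) gw_abort(message, "gw_insufficient_data", ...)
gw_domain_error <- function(message, ...) gw_abort(message, "gw_domain_error", ...)
gw_fit_error <- function(message, ...) gw_abort(message, "gw_fit_error", ...)
gw_assembly_error <- function(message, ...) gw_abort(message, "gw_assembly_error", ...)
gw_config_error <- function(message, ...) gw_abort(message, "gw_config_error", ...)

## Run a block under a temporary RNG state derived from `seed`, restoring the
## caller's stream afterwards. Keeps every generator a pure function of its seed.
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  code
}
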