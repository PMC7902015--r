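# Typed conditions: every malformed input raises a classed error so callers
# (and tests) can distinguish format, parse, consistency, config, validation
# and I/O failures without matching message text.

bsig_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bsig_error"), call = call))
}

format_error      <- function(msg) bsig_error(msg, "bsig_format_error")
parse_error       <- function(msg) bsig_error(msg, "bsig_parse_error")
consistency_error <- function(msg) bsig_error(msg, "bsig_consistency_error")
config_error      <- function(msg) bsig_error(msg, "bsig_config_error")
validation_error  <- function(msg) bsig_error(msg, "bsig_validation_error")
io_error          <- function(msg) bsig_error(msg, "bsig_io_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
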