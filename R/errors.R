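# Condition classes so callers (and the CLI) can map error families to
# distinct exit codes: config errors (bad parameters/flags), data errors
# (malformed or inconsistent inputs), compute errors (a stage failed).

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfet_config_error", "rfet_error")))
}

abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfet_data_error", "rfet_error")))
}

abort_compute <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfet_compute_error", "rfet_error")))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
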