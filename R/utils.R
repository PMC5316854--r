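`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical symbol normalization applied at every ingress: trim + uppercase.
# No alias or orthologue resolution is performed.
norm_symbols <- function(x) toupper(trimws(as.character(x)))

stop_config <- function(...) {
  stop(structure(class = c("haptrig_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("haptrig_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("haptrig_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Seeds derived for sub-streams must stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
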