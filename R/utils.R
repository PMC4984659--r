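# internal helpers shared across modules

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# state. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a top-level seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + offset) %% 2147483647
}

runif_log10 <- function(n, range) {
  stopifnot(length(range) == 2L, all(range > 0), range[1] <= range[2])
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up, used where "round()" banker's rounding would be surprising
round_half_up <- function(x) floor(x + 0.5)

tdrp_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "tdrp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
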