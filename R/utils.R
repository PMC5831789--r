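# internal helpers shared across modules

#' @importFrom stats plogis predict rbinom runif setNames
#' @importFrom utils head read.delim write.table
NULL

# classed errors so callers can distinguish failure modes
gpcr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gpcr_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All package randomness flows through this so a root seed fully determines output.
with_seed <- function(seed, code) {
  if (!is_count(seed)) gpcr_stop("seed must be a single non-negative integer", "gpcr_config_error")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage seed from a root seed; keeps values in 32-bit integer range
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + as.integer(stage) * 12347L) %% 2147483587L
}

# byte-wise (C locale) sort / order, locale-independent
csort <- function(x) sort(x, method = "radix")
corder <- function(...) order(..., method = "radix")
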