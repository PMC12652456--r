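#' @importFrom rlang abort warn %||% .data
#' @importFrom stats predict coef
NULL

# Run `code` under a locally-set RNG seed, restoring global RNG state after.
# seed = NULL runs with the current RNG stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive a deterministic child seed for a named pipeline stage so that stages
# consume independent streams while everything traces back to one global seed.
derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + as.numeric(index) * 7919) %% 2147483587)
}

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
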