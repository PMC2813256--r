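# Internal helpers shared across modules.

# Seed handling: every stochastic function takes `seed`; NULL means "use the
# current RNG state" so orchestration code can scope one seed over many calls.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# Derive a stage-specific seed from a master seed, staying inside 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + stage) %% .Machine$integer.max)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lower && x < upper else x >= lower && x <= upper) &&
    (!integerish || x == round(x))
  if (!ok) {
    abort(sprintf(
      "`%s` must be a %s number %s [%s, %s]; got %s.",
      name, if (integerish) "whole" else "finite",
      if (open) "strictly inside" else "in",
      format(lower), format(upper), deparse(x)
    ))
  }
  invisible(x)
}

# sign() with an optional dead zone: |x| <= dz maps to 0.
signum <- function(x, dead_zone = 0) {
  s <- sign(x)
  s[abs(x) <= dead_zone] <- 0
  s
}

rmse <- function(x) sqrt(mean(x^2))
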