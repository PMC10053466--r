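# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-facing seed is split into
# independent substreams keyed by stage (and optionally an id string), so
# stages can be re-run in isolation without perturbing each other's draws.
# All arithmetic stays below 2^31 - 1.
seed_for <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  base <- abs(as.integer(seed)) %% 1000003L
  h <- hash_string(key)
  as.integer((as.double(base) * 32749 + h) %% 2147483647)
}

# Small deterministic string hash (position-weighted code-point sum).
hash_string <- function(x) {
  v <- utf8ToInt(x)
  as.integer(sum(as.double(v) * seq_along(v)) %% 1000003)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}
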