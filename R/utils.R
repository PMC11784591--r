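# Internal helpers: seeding and common validation.

#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a fixed seed, restoring the RNG state afterwards.
# A NULL seed means "use the current RNG stream" (no isolation).
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  withr::with_seed(seed, force(code))
}

# Derive `n` independent sub-seeds from a master seed, in a fixed order.
# Downstream stages each get their own stream, so e.g. adding traits or
# switching between random and explicit causal sites does not perturb
# draws in the other stages. NULL master seed -> list of NULLs.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(vector("list", n))
  }
  as.list(withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# sample() without the length-1 surprise (sample(5, 1) != 5).
.sample_vec <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, prob = prob)]
}

.check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < (if (positive) 1 else 0)) {
    abort(sprintf("`%s` must be a single %s integer.", name,
                  if (positive) "positive" else "non-negative"))
  }
  as.integer(x)
}

.check_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  as.numeric(x)
}
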