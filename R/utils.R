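# Internal helpers: classed errors, argument checks, seeded evaluation.

abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "boldvar_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_degenerate <- function(msg) abort2(msg, "boldvar_degenerate_design")

chk_num <- function(x, name, len = 1L, lower = -Inf, upper = Inf,
                    integerish = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || !all(is.finite(x))) {
    abort2(sprintf("field '%s' must be %d finite numeric value(s)", name, len),
           "boldvar_bad_field")
  }
  if (any(x < lower) || any(x > upper)) {
    abort2(sprintf("field '%s' must lie in [%s, %s]", name,
                   format(lower), format(upper)),
           "boldvar_bad_field")
  }
  if (integerish && any(x != round(x))) {
    abort2(sprintf("field '%s' must be integer-valued", name),
           "boldvar_bad_field")
  }
  x
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds (kept under 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
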