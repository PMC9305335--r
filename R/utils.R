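# Internal helpers shared across modules.

# Default tolerances. NORM_TOL governs state/basis validation; COLLAPSE_TOL is
# the probability below which conditioning on an outcome is undefined;
# COMMUTE_TOL is the projector-commutator threshold for the compatibility
# verdict. PRINT_SLACK bounds how far a vector stored at 4-decimal precision
# may deviate from unit length before renormalization is refused.
.qp_tol <- list(
  norm     = 1e-6,
  collapse = 1e-12,
  commute  = 1e-9,
  print_slack = 1e-3
)

# Signal a classed condition so callers can branch on error type.
qp_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "qpcog_error", "error")))
}

is_complexish <- function(x) is.complex(x) && any(Im(x) != 0)

# Squared modulus that works for numeric and complex alike.
mod2 <- function(x) Re(Conj(x) * x)

# Drop a zero imaginary part so purely real models stay numeric end to end.
simplify_amplitudes <- function(x) {
  if (is.complex(x) && all(Im(x) == 0)) Re(x) else x
}

# Rotate a vector by a global phase so its largest-modulus entry is real and
# nonnegative. Probabilities are phase-blind; this fixes the representation.
canonical_phase <- function(x) {
  k <- which.max(mod2(x))
  a <- x[k]
  if (Mod(a) == 0) return(x)
  simplify_amplitudes(x * Conj(a) / Mod(a))
}

fmt_num <- function(x, digits = 4) {
  if (is.complex(x) && any(Im(x) != 0)) {
    paste0(formatC(Re(x), format = "f", digits = digits),
           ifelse(Im(x) < 0, "-", "+"),
           formatC(abs(Im(x)), format = "f", digits = digits), "i")
  } else {
    formatC(Re(x), format = "f", digits = digits)
  }
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
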