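# Shared fixtures and independent oracles for the test suite.

# The packaged worked example, without renormalization notices.
fix <- function() fixture_model(quiet = TRUE)

ev <- function(model, spec) parse_event(model, spec)

# Printed 4-decimal values are reproduced to within this tolerance.
PRINT_TOL <- 1e-3

# Absolute-tolerance comparison for values quoted at 4-decimal precision.
expect_within <- function(object, expected, tol = PRINT_TOL) {
  expect_lt(max(abs(object - expected)), tol)
}

# Independent oracle for rank-1 sequential paths: the product of squared
# inner products along the chain of outcome vectors, computed directly from
# reference-frame coordinates (no collapse machinery).
oracle_ray_path <- function(state_ref, ray_vectors_ref) {
  prev <- state_ref
  p <- 1
  for (r in ray_vectors_ref) {
    amp <- sum(Conj(r) * prev)
    p <- p * Re(Conj(amp) * amp)
    prev <- r
  }
  p
}

# Reference-frame vector of ray `i` of context `ctx`.
ray_vec <- function(ctx, i) ctx$basis[, i]

state_ref_coords <- function(model) {
  drop(model$state$frame$basis %*% model$state$coords)
}
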