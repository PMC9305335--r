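# Pure states, events, Born-rule probabilities, Lueders collapse, and
# Monte-Carlo outcome sampling.

#' Construct a pure state
#'
#' A pure state is a unit-length amplitude vector together with the
#' measurement context whose basis the coordinates refer to. States whose
#' squared norm deviates from 1 by more than `tol` are rejected; smaller
#' deviations (typical of amplitudes copied at 4-decimal precision, when a
#' larger `tol` is passed) are renormalized with a message, so downstream
#' probabilities always sum to one.
#'
#' @param coords Numeric or complex amplitude vector of length N >= 2.
#' @param frame The [build_context] object the coordinates refer to.
#' @param tol Maximum tolerated `|norm^2 - 1|` before rejection.
#' @return An object of class `pure_state`.
#' @examples
#' P <- build_context("P", diag(2), reference = TRUE)
#' s <- pure_state(c(0.2269, 0.9739), P, tol = 1e-3)
#' @export
pure_state <- function(coords, frame, tol = .qp_tol$norm) {
  if (length(coords) == 0)
    qp_abort("malformed_state", "state has an empty coordinate vector")
  stopifnot(inherits(frame, "measurement_context"))
  if (length(coords) != frame$dimension)
    qp_abort("malformed_state",
             "state has %d coordinates but frame '%s' has dimension %d",
             length(coords), frame$id, frame$dimension)
  n2 <- sum(mod2(coords))
  if (abs(n2 - 1) > tol)
    qp_abort("malformed_state",
             "state squared norm %s deviates from 1 by more than %g",
             fmt_num(n2, 7), tol)
  if (abs(n2 - 1) > .qp_tol$norm)
    message(sprintf("state renormalized (|norm^2 - 1| = %.2e)", abs(n2 - 1)))
  new_pure_state(simplify_amplitudes(coords / sqrt(n2)), frame)
}

# Internal constructor: coordinates already unit length.
new_pure_state <- function(coords, frame) {
  structure(list(coords = coords, frame = frame), class = "pure_state")
}

# Coordinates of the state in the model's reference frame.
state_in_reference <- function(state) {
  drop(state$frame$basis %*% state$coords)
}

#' @export
print.pure_state <- function(x, ...) {
  cat(sprintf("<pure state in frame '%s'>\n", x$frame$id))
  cat(paste0("  ", x$frame$labels, ": ", fmt_num(x$coords), collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a state's normalization
#'
#' @param state A [pure_state] (or a raw coordinate vector plus any frame).
#' @param tol Tolerance on `|norm^2 - 1|`.
#' @return A list with `pass` (logical), `norm2` (the measured squared
#'   norm) and `tol`.
#' @export
validate_state <- function(state, tol = .qp_tol$norm) {
  coords <- if (inherits(state, "pure_state")) state$coords else state
  if (length(coords) == 0)
    qp_abort("malformed_state", "state has an empty coordinate vector")
  n2 <- sum(mod2(coords))
  list(pass = abs(n2 - 1) <= tol, norm2 = n2, tol = tol)
}

#' Define an event as outcomes of one context
#'
#' An event subspace is a nonempty set of outcomes of a single measurement
#' context: one outcome is a ray, several are the union of orthogonal rays
#' (their span). Outcomes may be given as 1-based indices or as outcome
#' labels such as `"E2"`.
#'
#' @param context A [build_context] object.
#' @param outcomes Integer indices or character labels of the outcomes.
#' @return An object of class `event_subspace`.
#' @export
event_subspace <- function(context, outcomes) {
  stopifnot(inherits(context, "measurement_context"))
  if (is.character(outcomes)) {
    idx <- match(outcomes, context$labels)
    if (anyNA(idx))
      qp_abort("invalid_context", "unknown outcome label(s) %s in context '%s'",
               paste(outcomes[is.na(idx)], collapse = ", "), context$id)
    outcomes <- idx
  }
  outcomes <- as.integer(outcomes)
  if (length(outcomes) == 0)
    qp_abort("invalid_context", "event needs at least one outcome")
  if (anyDuplicated(outcomes) || any(outcomes < 1 | outcomes > context$dimension))
    qp_abort("invalid_context",
             "outcome indices must be distinct and within 1..%d", context$dimension)
  structure(list(context = context, outcomes = outcomes),
            class = "event_subspace")
}

#' @export
print.event_subspace <- function(x, ...) {
  cat(sprintf("<event %s:{%s}>\n", x$context$id,
              paste(x$context$labels[x$outcomes], collapse = ",")))
  invisible(x)
}

event_label <- function(event) {
  paste0(event$context$id, ":",
         paste(event$context$labels[event$outcomes], collapse = "+"))
}

# Amplitudes <C_k|S> of the state on each outcome vector of the event.
event_amplitudes <- function(state, event) {
  if (state$frame$dimension != event$context$dimension)
    qp_abort("incompatible_model",
             "state (dim %d) and event context '%s' (dim %d) differ",
             state$frame$dimension, event$context$id, event$context$dimension)
  v <- state_in_reference(state)
  drop(Conj(t(event$context$basis[, event$outcomes, drop = FALSE])) %*% v)
}

#' Transition amplitude onto a single ray
#'
#' The inner product between the event's outcome basis vector and the state;
#' its squared magnitude is the Born probability of that outcome.
#'
#' @param state A [pure_state].
#' @param event A single-ray [event_subspace].
#' @return The (real or complex) amplitude.
#' @examples
#' m <- fixture_model()
#' transition_amplitude(m$state, event_subspace(m$contexts$P, "P1")) # ~0.2269
#' @export
transition_amplitude <- function(state, event) {
  stopifnot(inherits(event, "event_subspace"))
  if (length(event$outcomes) != 1)
    qp_abort("invalid_context",
             "transition amplitudes are defined for single rays; event %s spans %d outcomes",
             event_label(event), length(event$outcomes))
  simplify_amplitudes(event_amplitudes(state, event))
}

#' Born-rule probability of an event
#'
#' The squared length of the projection of the state onto the span of the
#' event's basis vectors. Because the rays of one context are orthogonal,
#' the probability of a union event equals the sum of the per-ray
#' probabilities, and the probabilities over a complete context sum to 1.
#'
#' @param state A [pure_state].
#' @param event An [event_subspace] (ray or union of rays).
#' @return A probability in \[0, 1\].
#' @examples
#' m <- fixture_model()
#' born_probability(m$state, event_subspace(m$contexts$P, "P1")) # ~0.0515
#' @export
born_probability <- function(state, event) {
  stopifnot(inherits(state, "pure_state"), inherits(event, "event_subspace"))
  a <- event_amplitudes(state, event)
  min(1, sum(mod2(a)))
}

#' Collapse a state onto an observed event
#'
#' Projective (Lueders) measurement update: the state is projected onto the
#' event's subspace and the projection is rescaled to unit length. This is
#' the quantum analogue of Bayesian conditioning; within a single context it
#' reproduces classical renormalization exactly. After collapsing on a ray
#' the state *is* that basis vector (up to a phase, fixed here to be real
#' and nonnegative).
#'
#' @param state A [pure_state].
#' @param event The observed [event_subspace].
#' @param tol Outcomes with Born probability at or below `tol` cannot be
#'   conditioned on (an `impossible_outcome` error).
#' @return The post-measurement `pure_state`, expressed in the event's
#'   context frame.
#' @examples
#' m <- fixture_model()
#' post <- collapse(m$state, event_subspace(m$contexts$E, "E2"))
#' change_frame(post, m$contexts$P)  # approx (0.8994, 0.4372)
#' @export
collapse <- function(state, event, tol = .qp_tol$collapse) {
  stopifnot(inherits(state, "pure_state"), inherits(event, "event_subspace"))
  a <- event_amplitudes(state, event)
  p <- sum(mod2(a))
  if (p <= tol)
    qp_abort("impossible_outcome",
             "event %s has probability %.3e <= %.1e: collapse is undefined",
             event_label(event), p, tol)
  coords <- rep(if (is.complex(a)) 0i else 0, event$context$dimension)
  coords[event$outcomes] <- a / sqrt(p)
  new_pure_state(canonical_phase(coords), event$context)
}

#' Sample measurement outcomes from the Born distribution
#'
#' Draws `n` independent complete measurements of `state` in `context` and
#' tabulates outcome frequencies. The caller's RNG state is left untouched;
#' the same seed always reproduces the same table.
#'
#' @param state A [pure_state].
#' @param context The [build_context] measured.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A data.frame with columns `context`, `outcome`, `probability`
#'   (Born), `count`, and `frequency`.
#' @export
sample_outcome <- function(state, context, n, seed) {
  stopifnot(inherits(state, "pure_state"),
            inherits(context, "measurement_context"))
  if (n < 1) qp_abort("usage_error", "n must be >= 1")
  probs <- probability_table(state, context)$probability
  draws <- with_preserved_seed(seed, {
    sample.int(context$dimension, size = n, replace = TRUE, prob = probs)
  })
  counts <- tabulate(draws, nbins = context$dimension)
  data.frame(context = context$id, outcome = context$labels,
             probability = probs, count = counts, frequency = counts / n,
             stringsAsFactors = FALSE)
}

#' Born probabilities of every outcome of a context
#'
#' @param state A [pure_state].
#' @param context A [build_context] object.
#' @return A data.frame with columns `context`, `outcome`, `probability`.
#' @export
probability_table <- function(state, context) {
  p <- vapply(seq_len(context$dimension), function(i) {
    born_probability(state, event_subspace(context, i))
  }, numeric(1))
  data.frame(context = context$id, outcome = context$labels, probability = p,
             stringsAsFactors = FALSE)
}
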