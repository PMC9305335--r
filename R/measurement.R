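# Sequential measurements: path probabilities through iterated collapse,
# question order effects, reciprocity, compatibility diagnostics, and the
# interference term against the classical law of total probability.

#' Probability of a sequential measurement path
#'
#' Runs the measurements in `steps` in order, starting from `state`. Each
#' step records the Born probability of its event given the state reached so
#' far, then collapses the state onto it; the path probability is the
#' *product* of the step probabilities (the multiplicative chain rule). For
#' single-ray steps this equals the product of squared transition amplitudes
#' between consecutive outcome vectors. Step probabilities are never added:
#' a sum of conditional probabilities is not a path probability and can
#' exceed 1.
#'
#' Steps spanning several outcomes (coarse events) are handled by the same
#' project-and-renormalize rule and flagged `coarse = TRUE` in the result,
#' since transition probabilities between coarse events lack the simple
#' squared-amplitude form.
#'
#' If some step has probability at or below `tol`, the path is impossible:
#' the returned probability is 0, `impossible = TRUE`, and `post_state` is
#' `NULL`.
#'
#' @param state The initial [pure_state].
#' @param steps A list of [event_subspace] objects (a single event is
#'   accepted), measured in order.
#' @param tol Threshold below which a step is treated as impossible.
#' @return A `path_result`: `steps` (labels), `step_probabilities`,
#'   `path_probability`, `post_state`, `rule = "product"`, and flags
#'   `impossible`, `coarse`.
#' @examples
#' m <- fixture_model()
#' path_probability(m$state, list(event_subspace(m$contexts$E, "E2"),
#'                                event_subspace(m$contexts$P, "P1")))
#' @export
path_probability <- function(state, steps, tol = .qp_tol$collapse) {
  if (inherits(steps, "event_subspace")) steps <- list(steps)
  if (length(steps) < 1) qp_abort("usage_error", "need at least one step")
  stopifnot(all(vapply(steps, inherits, logical(1), "event_subspace")))

  labels <- vapply(steps, event_label, character(1))
  probs <- numeric(length(steps))
  cur <- state
  impossible <- FALSE
  for (k in seq_along(steps)) {
    p <- born_probability(cur, steps[[k]])
    probs[k] <- p
    if (p <= tol) {
      impossible <- TRUE
      probs[k] <- 0
      if (k < length(steps)) probs[(k + 1):length(steps)] <- NA_real_
      cur <- NULL
      break
    }
    cur <- collapse(cur, steps[[k]], tol = tol)
  }
  structure(list(
    steps = labels,
    step_probabilities = probs,
    path_probability = if (impossible) 0 else prod(probs),
    post_state = cur,
    rule = "product",
    impossible = impossible,
    coarse = any(vapply(steps, function(e) length(e$outcomes) > 1, logical(1)))
  ), class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat("<sequential measurement path>\n")
  cat("  steps:", paste(x$steps, collapse = " -> "), "\n")
  cat("  step probabilities:",
      paste(ifelse(is.na(x$step_probabilities), "-",
                   fmt_num(x$step_probabilities)), collapse = ", "), "\n")
  cat(sprintf("  path probability (product of steps): %s\n",
              fmt_num(x$path_probability)))
  if (x$impossible) cat("  impossible path: a step had probability 0\n")
  if (x$coarse) cat("  note: includes coarse (multi-outcome) steps\n")
  invisible(x)
}

#' Question order effect between two events
#'
#' The signed difference `P(A then B) - P(B then A)`, each side computed by
#' iterated collapse. Nonzero order effects are the signature of
#' incompatible (non-commuting) measurement contexts; for events of a single
#' context, or of any compatible pair, the effect is exactly zero and
#' sequential measurement reduces to classical conditioning.
#'
#' @param state The initial [pure_state].
#' @param event_a,event_b [event_subspace] objects.
#' @return The signed probability difference.
#' @export
order_effect <- function(state, event_a, event_b) {
  p_ab <- path_probability(state, list(event_a, event_b))$path_probability
  p_ba <- path_probability(state, list(event_b, event_a))$path_probability
  p_ab - p_ba
}

#' Squared transition magnitudes between two contexts
#'
#' Entry (i, j) is the transition probability between ray i of `ctx_a` and
#' ray j of `ctx_b`. The report checks the law of reciprocity — the
#' probability is the same in either direction for rays — and double
#' stochasticity (every row and column sums to 1), which any unitary
#' transition matrix satisfies.
#'
#' @param ctx_a,ctx_b Measurement contexts of equal dimension.
#' @return A list with `matrix`, `reciprocity_max_error`,
#'   `row_sums`, `col_sums`, and `doubly_stochastic`.
#' @export
reciprocity_matrix <- function(ctx_a, ctx_b) {
  fwd <- mod2(transition_matrix(ctx_a, ctx_b)$entries)
  rev <- mod2(transition_matrix(ctx_b, ctx_a)$entries)
  structure(list(
    from_context = ctx_a$id, to_context = ctx_b$id,
    matrix = fwd,
    reciprocity_max_error = max(abs(fwd - t(rev))),
    row_sums = rowSums(fwd),
    col_sums = colSums(fwd),
    doubly_stochastic = max(abs(c(rowSums(fwd), colSums(fwd)) - 1)) <= .qp_tol$commute
  ), class = "reciprocity_report")
}

#' @export
print.reciprocity_report <- function(x, ...) {
  cat(sprintf("<transition probabilities %s -> %s>\n",
              x$from_context, x$to_context))
  print(round(x$matrix, 4))
  cat(sprintf("  reciprocity max error: %.2e; doubly stochastic: %s\n",
              x$reciprocity_max_error, x$doubly_stochastic))
  invisible(x)
}

# Rank-1 projector onto column i of a context basis, in the reference frame.
ray_projector <- function(ctx, i) {
  v <- ctx$basis[, i, drop = FALSE]
  v %*% Conj(t(v))
}

#' Compatibility of two measurement contexts
#'
#' Two contexts are compatible when every pair of their ray projectors
#' commutes; only then do the two measurements admit a single classical
#' sample space, order effects vanish, and quantum updating reduces to
#' Bayesian conditioning. The report gives the largest entrywise magnitude
#' over all pairwise projector commutators and, if a state is supplied, the
#' largest absolute order effect over all ray pairs for that state.
#'
#' @param ctx_a,ctx_b Measurement contexts of equal dimension.
#' @param state Optional [pure_state] at which order effects are evaluated.
#' @param tol Commutator norm at or below which the pair counts as
#'   compatible.
#' @return A `compatibility_report` with fields `contexts`,
#'   `max_projector_commutator_norm`, `compatible`, `max_order_effect`.
#' @export
compatibility_report <- function(ctx_a, ctx_b, state = NULL,
                                 tol = .qp_tol$commute) {
  if (ctx_a$dimension != ctx_b$dimension)
    qp_abort("incompatible_model", "contexts have different dimensions")
  n <- ctx_a$dimension
  cnorm <- 0
  for (i in seq_len(n)) {
    pi <- ray_projector(ctx_a, i)
    for (j in seq_len(n)) {
      qj <- ray_projector(ctx_b, j)
      cnorm <- max(cnorm, max(Mod(pi %*% qj - qj %*% pi)))
    }
  }
  max_oe <- NA_real_
  if (!is.null(state)) {
    max_oe <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      max_oe <- max(max_oe, abs(order_effect(state,
                                             event_subspace(ctx_a, i),
                                             event_subspace(ctx_b, j))))
    }
  }
  structure(list(contexts = c(ctx_a$id, ctx_b$id),
                 max_projector_commutator_norm = cnorm,
                 compatible = cnorm <= tol,
                 max_order_effect = max_oe),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("<compatibility of contexts %s, %s>\n",
              x$contexts[1], x$contexts[2]))
  cat(sprintf("  max projector commutator norm: %.3e -> %s\n",
              x$max_projector_commutator_norm,
              if (x$compatible) "compatible (classical/Bayesian limit)"
              else "incompatible (complementary)"))
  if (!is.na(x$max_order_effect))
    cat(sprintf("  max |order effect| at the model state: %s\n",
                fmt_num(x$max_order_effect)))
  invisible(x)
}

#' Interference against the law of total probability
#'
#' Classically, the probability of a final event decomposes over any
#' complete set of intermediate outcomes: P(F) = sum_i P(i) P(F | i). Under
#' incompatible contexts this law fails; the decomposition is computed here
#' as the sum of mediated path probabilities through each intermediate ray,
#' and the interference term is the direct probability minus that classical
#' sum. It vanishes when the contexts are compatible and is generally
#' nonzero otherwise — the direct probability can even be smaller than a
#' single mediated path.
#'
#' For a single-ray final event the report also checks the amplitude-level
#' completeness identity: the direct amplitude equals the sum over
#' intermediate rays of the products of transition amplitudes (amplitudes
#' add; probabilities need not).
#'
#' @param state The initial [pure_state].
#' @param intermediate_context The complete [build_context] measured in
#'   between.
#' @param final_event The final [event_subspace].
#' @return An `interference_report` with `direct_probability`,
#'   `mediated_probabilities`, `classical_sum`, `interference_term`, and
#'   `amplitude_identity_error` (NA for coarse final events).
#' @examples
#' m <- fixture_model()
#' total_probability_decomposition(m$state, m$contexts$E,
#'                                 event_subspace(m$contexts$P, "P1"))
#' @export
total_probability_decomposition <- function(state, intermediate_context,
                                            final_event) {
  stopifnot(inherits(intermediate_context, "measurement_context"),
            inherits(final_event, "event_subspace"))
  direct <- born_probability(state, final_event)
  n <- intermediate_context$dimension
  mediated <- numeric(n)
  for (i in seq_len(n)) {
    mediated[i] <- path_probability(
      state, list(event_subspace(intermediate_context, i), final_event)
    )$path_probability
  }
  names(mediated) <- intermediate_context$labels

  amp_err <- NA_real_
  if (length(final_event$outcomes) == 1) {
    f <- final_event$context$basis[, final_event$outcomes]
    v <- state_in_reference(state)
    total <- 0
    for (i in seq_len(n)) {
      b <- intermediate_context$basis[, i]
      total <- total + sum(Conj(f) * b) * sum(Conj(b) * v)
    }
    amp_err <- Mod(total - sum(Conj(f) * v))
  }

  structure(list(
    final_event = event_label(final_event),
    intermediate_context = intermediate_context$id,
    direct_probability = direct,
    mediated_probabilities = mediated,
    classical_sum = sum(mediated),
    interference_term = direct - sum(mediated),
    amplitude_identity_error = amp_err
  ), class = "interference_report")
}

#' @export
print.interference_report <- function(x, ...) {
  cat(sprintf("<total-probability decomposition of %s via context %s>\n",
              x$final_event, x$intermediate_context))
  cat(sprintf("  direct probability:  %s\n", fmt_num(x$direct_probability)))
  cat("  mediated paths:     ",
      paste(sprintf("%s: %s", names(x$mediated_probabilities),
                    fmt_num(x$mediated_probabilities)), collapse = ", "), "\n")
  cat(sprintf("  classical sum:       %s\n", fmt_num(x$classical_sum)))
  cat(sprintf("  interference term:   %s\n", fmt_num(x$interference_term)))
  invisible(x)
}

#' Classical-conditioning check within a context
#'
#' Within a single context (or any compatible pair) quantum measurement is
#' classical: collapsing on a union event U and then measuring reproduces
#' Bayes' rule, P(ray j | U) = P(ray j) / P(U) for j in U and 0 otherwise.
#' This function computes both sides and reports their largest discrepancy.
#'
#' @param state A [pure_state].
#' @param context The [build_context] measured.
#' @param outcomes Outcomes (indices or labels) forming the conditioning
#'   union; defaults to the full context.
#' @param tol Agreement tolerance for the verdict.
#' @return A list with `conditional` (quantum, via collapse), `classical`
#'   (Bayes ratio), `max_abs_diff`, and `pass`.
#' @export
bayes_equivalence_check <- function(state, context,
                                    outcomes = seq_len(context$dimension),
                                    tol = .qp_tol$commute) {
  u <- event_subspace(context, outcomes)
  p_u <- born_probability(state, u)
  if (p_u <= .qp_tol$collapse)
    qp_abort("impossible_outcome",
             "conditioning union %s has probability %.3e", event_label(u), p_u)
  post <- collapse(state, u)
  quantum <- probability_table(post, context)$probability
  prior <- probability_table(state, context)$probability
  classical <- numeric(context$dimension)
  classical[u$outcomes] <- prior[u$outcomes] / p_u
  names(quantum) <- names(classical) <- context$labels
  d <- max(abs(quantum - classical))
  list(conditional = quantum, classical = classical,
       max_abs_diff = d, pass = d <= tol)
}
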