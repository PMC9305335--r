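# Measurement contexts (ordered orthonormal bases) and unitary changes of
# frame between them. Every context stores its basis vectors as the COLUMNS
# of an N x N matrix expressed in the model's reference frame, so inner
# products between contexts are plain (conjugated) matrix products.

#' Build a measurement context
#'
#' A measurement context is an ordered orthonormal basis whose rays are the
#' elementary outcomes of a measurement (for example a prediction basis
#' `P1`, `P2` or an evidence basis `E1`, `E2`). Basis vectors are given in
#' the coordinates of the model's reference frame, one vector per row of
#' `vectors` (matching the on-disk model schema) or as a list of vectors.
#'
#' Orthonormality is checked against the identity Gram matrix at tolerance
#' `tol` and violations are rejected, not repaired: silently
#' re-orthogonalizing a basis would move the probabilities the user wrote
#' down. The one sanctioned repair, `normalize = TRUE`, rescales each
#' vector's *length* to 1 (it never touches directions), which accommodates
#' amplitudes stored at 4-decimal precision; the rescale is refused if a
#' squared norm is off by more than 1e-3.
#'
#' @param id Short label for the context, e.g. `"P"`.
#' @param vectors Matrix with one basis vector per row, or a list of
#'   numeric/complex vectors, in reference-frame coordinates.
#' @param labels Outcome labels, one per basis vector. Defaults to
#'   `id` followed by 1..N, e.g. `"P1"`, `"P2"`.
#' @param reference Logical; is this the model's reference frame? A
#'   reference context must have the canonical (identity) basis.
#' @param normalize Rescale basis vectors to unit length before validation.
#' @param tol Gram-matrix deviation tolerance.
#' @return An object of class `measurement_context`.
#' @examples
#' evidence <- build_context("E", rbind(c(-0.4372, 0.8994),
#'                                      c( 0.8994, 0.4372)),
#'                           normalize = TRUE)
#' @export
build_context <- function(id, vectors, labels = NULL, reference = FALSE,
                          normalize = FALSE, tol = .qp_tol$norm) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  n <- ncol(vectors)
  if (nrow(vectors) != n || n < 2)
    qp_abort("invalid_context",
             "context '%s': need N >= 2 vectors of length N, got %d x %d",
             id, nrow(vectors), n)
  basis <- t(vectors)            # columns = outcome vectors
  storage <- if (is.complex(basis)) basis else basis * 1.0

  if (normalize) {
    lens2 <- colSums(mod2(storage))
    if (any(abs(lens2 - 1) > .qp_tol$print_slack))
      qp_abort("invalid_context",
               "context '%s': basis vector squared norms %s too far from 1 to renormalize",
               id, paste(fmt_num(lens2, 6), collapse = ", "))
    if (any(abs(lens2 - 1) > .qp_tol$norm)) {
      message(sprintf("context '%s': basis vectors renormalized (max |norm^2 - 1| = %.2e)",
                      id, max(abs(lens2 - 1))))
    }
    storage <- sweep(storage, 2, sqrt(lens2), "/")
  }

  gram <- Conj(t(storage)) %*% storage
  dev <- max(Mod(gram - diag(n)))
  if (dev > tol)
    qp_abort("invalid_context",
             "context '%s' is not orthonormal: max Gram deviation %.3e > %.1e",
             id, dev, tol)
  if (reference && max(Mod(storage - diag(n))) > tol)
    qp_abort("invalid_context",
             "reference context '%s' must have the canonical basis", id)

  if (is.null(labels)) labels <- paste0(id, seq_len(n))
  if (length(labels) != n || anyDuplicated(labels))
    qp_abort("invalid_context", "context '%s': need %d distinct labels", id, n)

  structure(list(id = id, dimension = n,
                 basis = simplify_amplitudes(storage),
                 labels = as.character(labels),
                 reference = isTRUE(reference)),
            class = "measurement_context")
}

#' @export
print.measurement_context <- function(x, ...) {
  cat(sprintf("<measurement context '%s'%s: %d outcomes>\n",
              x$id, if (x$reference) " (reference frame)" else "",
              x$dimension))
  m <- t(x$basis)
  rownames(m) <- x$labels
  print(round(Re(m) + if (is.complex(m)) 1i * round(Im(m), 4) else 0, 4))
  invisible(x)
}

#' Unitary transition matrix between two contexts
#'
#' Entry (i, j) is the transition amplitude from the i-th outcome vector of
#' `ctx_a` to the j-th outcome vector of `ctx_b`. The matrix is unitary, and
#' its entrywise squared-magnitude matrix is doubly stochastic: each row and
#' each column sums to 1, which in two dimensions is the symmetry the law of
#' reciprocity predicts between cross-basis outcome pairs.
#'
#' @param ctx_a,ctx_b Measurement contexts of equal dimension sharing a
#'   reference frame.
#' @return An object of class `transition_matrix` wrapping the N x N
#'   amplitude matrix (`$entries`).
#' @export
transition_matrix <- function(ctx_a, ctx_b) {
  stopifnot(inherits(ctx_a, "measurement_context"),
            inherits(ctx_b, "measurement_context"))
  if (ctx_a$dimension != ctx_b$dimension)
    qp_abort("incompatible_model",
             "contexts '%s' (dim %d) and '%s' (dim %d) have different dimensions",
             ctx_a$id, ctx_a$dimension, ctx_b$id, ctx_b$dimension)
  entries <- simplify_amplitudes(Conj(t(ctx_a$basis)) %*% ctx_b$basis)
  dimnames(entries) <- list(ctx_a$labels, ctx_b$labels)
  structure(list(from_context = ctx_a$id, to_context = ctx_b$id,
                 entries = entries),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition matrix %s -> %s>\n", x$from_context, x$to_context))
  print(round(x$entries, 4))
  invisible(x)
}

#' Re-express a state in another context's coordinates
#'
#' The physical state is unchanged; only its coordinates are rewritten in
#' the target basis via the unitary transition matrix, so the Born
#' probability of every fixed event is preserved exactly (up to floating
#' point) and a round trip returns the original coordinates.
#'
#' @param state A [pure_state].
#' @param to_context Target [build_context] object.
#' @return A `pure_state` whose `frame` is `to_context`.
#' @examples
#' m <- fixture_model()
#' change_frame(m$state, m$contexts$E)  # coordinates approx (0.7767, 0.6299)
#' @export
change_frame <- function(state, to_context) {
  stopifnot(inherits(state, "pure_state"),
            inherits(to_context, "measurement_context"))
  if (state$frame$dimension != to_context$dimension)
    qp_abort("incompatible_model", "state (dim %d) and context '%s' (dim %d) differ",
             state$frame$dimension, to_context$id, to_context$dimension)
  v <- state_in_reference(state)
  coords <- simplify_amplitudes(drop(Conj(t(to_context$basis)) %*% v))
  new_pure_state(coords, to_context)
}

#' Are two contexts the same measurement up to per-ray phase?
#'
#' Two ordered contexts are ray-equivalent when each outcome vector of one
#' equals the corresponding outcome vector of the other times a unit-modulus
#' phase (for real models, a sign flip). Such contexts assign identical
#' probabilities to every state. Order matters: permuting the basis relabels
#' the outcomes and is *not* ray-equivalent, because outcome labels carry
#' meaning.
#'
#' @param ctx_a,ctx_b Measurement contexts of equal dimension.
#' @param tol Amplitude tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
ray_equivalent <- function(ctx_a, ctx_b, tol = .qp_tol$norm) {
  if (ctx_a$dimension != ctx_b$dimension) return(FALSE)
  for (i in seq_len(ctx_a$dimension)) {
    a <- ctx_a$basis[, i]
    b <- ctx_b$basis[, i]
    phase <- sum(Conj(a) * b)
    if (abs(Mod(phase) - 1) > tol) return(FALSE)
    if (max(Mod(b - phase * a)) > tol) return(FALSE)
  }
  TRUE
}
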