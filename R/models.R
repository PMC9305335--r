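# Model container, the packaged worked example, the seeded synthetic
# generator, and JSON/YAML (de)serialization.
#
# On-disk schema (JSON canonical, YAML accepted):
#   {"dimension": N, "reference": "<ctx id>",
#    "contexts": [{"id", "labels", "vectors"}, ...],   # vectors: row/outcome
#    "state": {"frame": "<ctx id>", "coords": [...]},
#    "metadata": {...}}
# Amplitudes are decimal numbers; complex amplitudes are [re, im] pairs.
# All basis vectors are expressed in the reference frame.

#' Assemble a model from contexts and a state
#'
#' @param contexts List of [build_context] objects (one flagged
#'   `reference = TRUE`); may be named, otherwise names are taken from ids.
#' @param state The model's [pure_state]; its frame must be one of the
#'   contexts.
#' @param metadata Optional list (name, seed, provenance notes).
#' @return An object of class `qp_model` with fields `dimension`,
#'   `reference`, `contexts` (named list), `state`, `metadata`.
#' @export
qp_model <- function(contexts, state, metadata = list()) {
  stopifnot(is.list(contexts), length(contexts) >= 1,
            inherits(state, "pure_state"))
  ids <- vapply(contexts, function(c) c$id, character(1))
  if (anyDuplicated(ids))
    qp_abort("invalid_model", "duplicate context ids: %s",
             paste(ids[duplicated(ids)], collapse = ", "))
  names(contexts) <- ids
  dims <- vapply(contexts, function(c) c$dimension, integer(1))
  if (length(unique(dims)) != 1)
    qp_abort("invalid_model", "contexts have mixed dimensions: %s",
             paste(dims, collapse = ", "))
  refs <- vapply(contexts, function(c) isTRUE(c$reference), logical(1))
  if (sum(refs) != 1)
    qp_abort("invalid_model", "exactly one reference context required, found %d",
             sum(refs))
  if (!state$frame$id %in% ids)
    qp_abort("invalid_model", "state frame '%s' is not a context of the model",
             state$frame$id)
  structure(list(dimension = unname(dims[1]), reference = unname(ids[refs]),
                 contexts = contexts, state = state, metadata = metadata),
            class = "qp_model")
}

#' @export
print.qp_model <- function(x, ...) {
  nm <- x$metadata$name
  cat(sprintf("<quantum measurement model%s: dim %d, %d context(s), reference '%s'>\n",
              if (!is.null(nm)) paste0(" '", nm, "'") else "",
              x$dimension, length(x$contexts), x$reference))
  for (ctx in x$contexts) print(ctx)
  print(x$state)
  invisible(x)
}

#' Retrieve a context of a model by id
#' @param model A [qp_model].
#' @param id Context id string.
#' @return The [build_context] object.
#' @export
get_context <- function(model, id) {
  ctx <- model$contexts[[id]]
  if (is.null(ctx))
    qp_abort("invalid_model", "model has no context '%s' (has: %s)",
             id, paste(names(model$contexts), collapse = ", "))
  ctx
}

#' Parse an event written as "CONTEXT:LABEL"
#'
#' Unions of rays are written with `+`, e.g. `"P:P1+P2"`.
#'
#' @param model A [qp_model].
#' @param spec Event string such as `"E:E2"`.
#' @return An [event_subspace].
#' @export
parse_event <- function(model, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2]))
    qp_abort("parse_error", "event '%s' is not of the form CONTEXT:LABEL", spec)
  ctx <- get_context(model, parts[1])
  event_subspace(ctx, strsplit(parts[2], "+", fixed = TRUE)[[1]])
}

#' The packaged two-outcome worked example
#'
#' A 2-dimensional model with a prediction context `P` (the reference frame,
#' canonical basis, outcomes `P1`, `P2`), an evidence context `E` whose
#' basis vectors are (-0.4372, 0.8994) and (0.8994, 0.4372) in the `P`
#' frame, and the state (0.2269, 0.9739) in `P` coordinates. The two
#' contexts are incompatible: the model exhibits order effects and a
#' negative interference term for the first prediction outcome.
#'
#' Amplitudes are stored exactly as printed at 4-decimal precision, so the
#' state and basis are renormalized on construction (a message is emitted);
#' probabilities derived from the model agree with the printed values to
#' within 0.001.
#'
#' @param quiet Suppress the renormalization messages.
#' @return A [qp_model].
#' @examples
#' m <- fixture_model(quiet = TRUE)
#' probability_table(m$state, m$contexts$P)
#' @export
fixture_model <- function(quiet = FALSE) {
  build <- function() {
    p_ctx <- build_context("P", diag(2), labels = c("P1", "P2"),
                           reference = TRUE)
    e_ctx <- build_context("E", rbind(c(-0.4372, 0.8994),
                                      c( 0.8994, 0.4372)),
                           labels = c("E1", "E2"), normalize = TRUE)
    s <- pure_state(c(0.2269, 0.9739), p_ctx, tol = .qp_tol$print_slack)
    qp_model(list(p_ctx, e_ctx), s,
             metadata = list(name = "two-outcome worked example"))
  }
  if (quiet) suppressMessages(build()) else build()
}

#' Seeded random model generator
#'
#' Generates a synthetic model for property testing: the first context is
#' the canonical reference frame; each further context is obtained by
#' QR-orthonormalizing a standard-normal matrix, with the sign convention
#' that the R factor has a nonnegative diagonal (so the result is
#' reproducible across platforms). The state is a normalized standard-normal
#' vector in the reference frame. Identical seeds give identical models; the
#' caller's RNG state is untouched.
#'
#' @param dimension State-space dimension N >= 2.
#' @param n_contexts Number of contexts >= 1 (the first is the reference).
#' @param seed Integer seed.
#' @return A [qp_model].
#' @export
random_model <- function(dimension, n_contexts, seed) {
  if (dimension < 2) qp_abort("invalid_model", "dimension must be >= 2")
  if (n_contexts < 1) qp_abort("invalid_model", "n_contexts must be >= 1")
  with_preserved_seed(seed, {
    ids <- paste0("C", seq_len(n_contexts))
    contexts <- vector("list", n_contexts)
    contexts[[1]] <- build_context(ids[1], diag(dimension), reference = TRUE)
    for (k in seq_len(n_contexts)[-1]) {
      qrd <- qr(matrix(stats::rnorm(dimension^2), dimension))
      q <- qr.Q(qrd)
      q <- q %*% diag(sign(diag(qr.R(qrd))), dimension)
      contexts[[k]] <- build_context(ids[k], t(q))
    }
    v <- stats::rnorm(dimension)
    s <- new_pure_state(v / sqrt(sum(v^2)), contexts[[1]])
    qp_model(contexts, s,
             metadata = list(name = "random synthetic model", seed = seed))
  })
}

#' A rotated 2-D measurement context
#'
#' Basis ((cos theta, sin theta), (-sin theta, cos theta)) in the reference
#' frame: the reference context rotated counter-clockwise by `theta`. For a
#' state at angle `alpha` the Born probability of the first outcome is
#' cos^2(alpha - theta), which gives an analytic family for testing and for
#' exploring how incompatibility grows with the angle between contexts.
#'
#' @param theta Rotation angle in radians.
#' @param id Context id (default `"R"`).
#' @param labels Optional outcome labels.
#' @return A [build_context] object.
#' @export
rotation_context_2d <- function(theta, id = "R", labels = NULL) {
  build_context(id, rbind(c(cos(theta), sin(theta)),
                          c(-sin(theta), cos(theta))), labels = labels)
}

# ---- serialization ----------------------------------------------------------

encode_amp_vec <- function(x) {
  if (is_complexish(x)) lapply(x, function(z) c(Re(z), Im(z)))
  else as.numeric(Re(x))
}

decode_amp_vec <- function(node, field) {
  if (is.null(node) || length(node) == 0)
    qp_abort("parse_error", "field '%s' is missing or empty", field)
  vals <- lapply(node, function(el) {
    el <- unlist(el)
    if (!is.numeric(el) || !length(el) %in% 1:2 || anyNA(el))
      qp_abort("parse_error", "field '%s': amplitudes must be numbers or [re, im] pairs",
               field)
    if (length(el) == 2) complex(real = el[1], imaginary = el[2]) else el
  })
  simplify_amplitudes(unlist(vals))
}

model_to_list <- function(model) {
  list(
    dimension = model$dimension,
    reference = unname(model$reference),
    contexts = lapply(unname(model$contexts), function(ctx) {
      list(id = ctx$id, labels = as.list(ctx$labels),
           vectors = lapply(seq_len(ctx$dimension),
                            function(i) encode_amp_vec(ctx$basis[, i])))
    }),
    state = list(frame = model$state$frame$id,
                 coords = encode_amp_vec(model$state$coords)),
    metadata = if (length(model$metadata)) model$metadata else NULL
  )
}

model_from_list <- function(node) {
  for (field in c("dimension", "reference", "contexts", "state")) {
    if (is.null(node[[field]]))
      qp_abort("parse_error", "model file is missing field '%s'", field)
  }
  n <- as.integer(node$dimension)
  contexts <- lapply(node$contexts, function(cn) {
    for (field in c("id", "vectors")) {
      if (is.null(cn[[field]]))
        qp_abort("parse_error", "context entry is missing field '%s'", field)
    }
    vectors <- lapply(cn$vectors, decode_amp_vec, field = "vectors")
    if (any(lengths(vectors) != n) || length(vectors) != n)
      qp_abort("parse_error", "context '%s': expected %d vectors of length %d",
               cn$id, n, n)
    build_context(cn$id, vectors,
                  labels = if (!is.null(cn$labels)) unlist(cn$labels),
                  reference = identical(cn$id, node$reference),
                  normalize = TRUE)
  })
  names(contexts) <- vapply(contexts, function(c) c$id, character(1))
  frame <- contexts[[node$state$frame]]
  if (is.null(frame))
    qp_abort("parse_error", "state frame '%s' does not name a context",
             node$state$frame)
  coords <- decode_amp_vec(node$state$coords, "state$coords")
  state <- pure_state(coords, frame, tol = .qp_tol$print_slack)
  meta <- node$metadata
  qp_model(contexts, state, metadata = if (is.null(meta)) list() else meta)
}

#' Save / load a model as JSON or YAML
#'
#' JSON is the canonical format; files ending in `.yaml`/`.yml` are written
#' and read as YAML. A save/load round trip reproduces the model amplitudes
#' to full double precision, and all invariants (orthonormal contexts,
#' normalized state, one reference frame) are re-validated on load.
#'
#' @param model A [qp_model].
#' @param path File path; format chosen by extension.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   [qp_model].
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qp_model"))
  node <- model_to_list(model)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(node, path, precision = 17)
  } else {
    jsonlite::write_json(node, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    qp_abort("parse_error", "model file '%s' does not exist", path)
  node <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  model_from_list(node)
}
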