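#' Build a context ensemble
#'
#' Creates the synthetic attribute universe: a uniform random set of
#' `N_gen` "general" attributes (common to every context that will be
#' added) drawn from the `N_ctx` possible attributes. Contexts are added
#' afterwards with [add_context()].
#'
#' Attributes are integer indices in `1..N_ctx`.
#'
#' @param p A [fear_params()] object.
#' @param seed Integer seed; the same seed reproduces the ensemble.
#' @return An object of class `context_ensemble` with fields
#'   `general_attrs`, `contexts` (named list), `params`, `seed`.
#' @export
build_ensemble <- function(p, seed = 1L) {
  p <- validate_params(p)
  set.seed(seed)
  ens <- list(
    general_attrs = sort(sample.int(p$N_ctx, p$N_gen)),
    contexts = list(),
    params = p,
    seed = as.integer(seed)
  )
  class(ens) <- "context_ensemble"
  ens
}

#' Add a context to an ensemble
#'
#' A context is a set of exactly `N_A` attributes containing all the
#' general attributes. Without a similarity constraint the `N_A - N_gen`
#' non-general attributes are drawn uniformly from the non-general pool,
#' so two unconstrained contexts share the general core plus whatever
#' unique attributes collide by chance ("maximally different" contexts).
#'
#' With `similar_to`, the new context shares exactly
#' `round(similarity * N_A)` attributes with the reference: all the
#' general attributes plus a uniform choice of the reference's unique
#' attributes, the remainder drawn fresh from the non-general pool
#' excluding the reference's uniques, so the realized similarity is
#' exact rather than in expectation.
#'
#' @param ens A `context_ensemble`.
#' @param id Character label for the context.
#' @param similar_to Optional id of a context already in the ensemble.
#' @param similarity Fraction of attributes shared with the reference;
#'   `similarity * N_A` must be a whole number and at least `N_gen`
#'   (contexts always share the general core).
#' @param seed Optional integer seed for this draw.
#' @return The updated ensemble.
#' @export
add_context <- function(ens, id, similar_to = NULL, similarity = NULL,
                        seed = NULL) {
  stopifnot(inherits(ens, "context_ensemble"))
  p <- ens$params
  if (!is.null(seed)) set.seed(seed)
  gen <- ens$general_attrs
  pool <- setdiff(seq_len(p$N_ctx), gen)
  if (is.null(similar_to)) {
    uniq <- sample(pool, p$N_A - p$N_gen)
  } else {
    ref <- ens$contexts[[similar_to]]
    if (is.null(ref)) stop("unknown reference context: ", similar_to)
    n_shared <- similarity * p$N_A
    if (abs(n_shared - round(n_shared)) > 1e-9)
      stop("similarity * N_A must be an integer")
    n_shared <- as.integer(round(n_shared))
    if (n_shared < p$N_gen)
      stop("similarity below N_gen/N_A is impossible: contexts always share the general core")
    ref_uniq <- setdiff(ref$attrs, gen)
    n_from_ref <- n_shared - p$N_gen
    if (n_from_ref > length(ref_uniq)) stop("similarity exceeds 1")
    shared_uniq <- if (n_from_ref > 0) sample(ref_uniq, n_from_ref) else integer(0)
    fresh_pool <- setdiff(pool, ref_uniq)
    n_fresh <- p$N_A - n_shared
    fresh <- if (n_fresh > 0) sample(fresh_pool, n_fresh) else integer(0)
    uniq <- c(shared_uniq, fresh)
  }
  ctx <- list(id = id, attrs = sort(c(gen, uniq)))
  class(ctx) <- "fear_context"
  ens$contexts[[id]] <- ctx
  ens
}

#' Similarity of two contexts
#'
#' @param a,b `fear_context` objects (or their ids looked up by the caller).
#' @param p A `fear_params` object supplying `N_A`.
#' @return `|attrs(a) n attrs(b)| / N_A`.
#' @export
context_similarity <- function(a, b, p) {
  length(intersect(a$attrs, b$attrs)) / p$N_A
}

#' Serial sampling stream over a context's attributes
#'
#' Attributes of a context are observed serially in uniformly random
#' order without replacement. The stream is a uniform random permutation
#' of the context's attributes plus a cursor.
#'
#' @param ctx A `fear_context`.
#' @param seed Optional integer seed for the permutation.
#' @return An object of class `sample_stream`.
#' @export
sample_stream <- function(ctx, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- new.env(parent = emptyenv())
  s$context_id <- ctx$id
  s$order <- sample(ctx$attrs)
  s$cursor <- 0L
  class(s) <- "sample_stream"
  s
}

#' Draw the next attribute from a stream
#'
#' @param stream A `sample_stream`.
#' @return The next attribute index; each attribute is emitted exactly once.
#' @export
stream_next <- function(stream) {
  if (stream$cursor >= length(stream$order))
    stop("sample stream exhausted: all attributes of context '",
         stream$context_id, "' have been observed")
  stream$cursor <- stream$cursor + 1L
  stream$order[stream$cursor]
}

#' @rdname stream_next
#' @export
stream_exhausted <- function(stream) stream$cursor >= length(stream$order)

#' Serialize / restore a context ensemble
#'
#' JSON round-trip of the ensemble (seed, general attributes, contexts).
#' Parameters are serialized alongside so a restored ensemble is
#' self-contained.
#'
#' @param ens A `context_ensemble`.
#' @param path File path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns the restored ensemble.
#' @export
write_ensemble <- function(ens, path) {
  obj <- list(
    seed = ens$seed,
    params = unclass(ens$params),
    general_attrs = ens$general_attrs,
    contexts = lapply(unname(ens$contexts), function(ctx)
      list(id = ctx$id, attrs = ctx$attrs))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- obj$params
  p <- do.call(fear_params, pars[setdiff(names(pars), character(0))])
  ens <- list(
    general_attrs = as.integer(obj$general_attrs),
    contexts = list(),
    params = p,
    seed = as.integer(obj$seed)
  )
  class(ens) <- "context_ensemble"
  if (length(obj$contexts)) {
    ids <- obj$contexts$id
    for (i in seq_along(ids)) {
      ctx <- list(id = ids[[i]], attrs = as.integer(obj$contexts$attrs[[i]]))
      class(ctx) <- "fear_context"
      ens$contexts[[ids[[i]]]] <- ctx
    }
  }
  ens
}
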