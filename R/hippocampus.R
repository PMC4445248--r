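#' Lesion configuration
#'
#' Switches that silence or freeze parts of the dentate pathway,
#' mirroring the inactivation experiments the model speaks to. The
#' flags are independent so that encoding-stage and recall-stage
#' suppression can be combined factorially.
#'
#' @param dg_off_encoding Dentate silent while a representation is being
#'   created: the CA3 winners are chosen by CA3's own KWTA acting on
#'   direct-path anatomical input, and no dentate synapses potentiate.
#' @param dg_off_recall Dentate transmission silent during recall: the
#'   pre-recurrent CA3 pattern is driven by the direct path alone
#'   (scaled by `dpf`).
#' @param dg_plasticity_off Dentate synapses never potentiate, but
#'   dentate still fires and selects winners.
#' @return A `lesion_config` object.
#' @export
lesion_config <- function(dg_off_encoding = FALSE, dg_off_recall = FALSE,
                          dg_plasticity_off = FALSE) {
  l <- list(dg_off_encoding = dg_off_encoding,
            dg_off_recall = dg_off_recall,
            dg_plasticity_off = dg_plasticity_off)
  class(l) <- "lesion_config"
  l
}

#' Build a hippocampal network
#'
#' Draws the anatomical wiring: each dentate cell and each CA3 cell
#' receives `F_aff` distinct entorhinal input afferents, chosen
#' uniformly and independently between the two layers. Dentate cell `i`
#' and CA3 cell `i` form a dedicated dyad. Every Hebbian synapse starts
#' unpotentiated (totally ineffective until potentiated); the recurrent
#' CA3 collaterals and the CA3-to-entorhinal-output projection are
#' anatomically complete but likewise silent until potentiated.
#'
#' The returned network is an environment: creation, update and
#' conditioning mutate it in place, which matches the persistent nature
#' of the synaptic state across sessions.
#'
#' @param p A [fear_params()] object.
#' @param seed Integer seed; the same seed reproduces the connectivity.
#' @return An object of class `hippocampal_net`.
#' @export
build_net <- function(p, seed = 1L) {
  p <- validate_params(p)
  set.seed(seed)
  net <- new.env(parent = emptyenv())
  net$p <- p
  net$seed <- as.integer(seed)
  # afferent index matrices, one row per cell
  draw <- function() t(vapply(seq_len(p$N_hipp),
                              function(i) sample.int(p$N_ctx, p$F_aff),
                              integer(p$F_aff)))
  net$dg_aff <- draw()
  net$ca3_aff <- draw()
  # potentiated entorhinal synapses: per-cell attribute index vectors,
  # weights implied equal at 1/length (normalized to sum 1)
  net$dg_pot <- vector("list", p$N_hipp)
  net$ca3_pot <- vector("list", p$N_hipp)
  # potentiated recurrent collaterals (binary, no self-pairs)
  net$rec <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  dims = c(p$N_hipp, p$N_hipp))
  # potentiated CA3 -> entorhinal-output synapses, per-cell attribute sets
  net$out_pot <- vector("list", p$N_hipp)
  net$reps <- list()
  net$amyg_w <- numeric(p$N_hipp)
  class(net) <- "hippocampal_net"
  net
}

#' @export
print.hippocampal_net <- function(x, ...) {
  cat(sprintf("<hippocampal_net> N_hipp=%d, %d representation(s), seed=%d\n",
              x$p$N_hipp, length(x$reps), x$seed))
  invisible(x)
}

#' Deep-copy a network
#'
#' Networks are environments and mutate in place; `clone_net` gives an
#' independent copy, used e.g. to run parallel test sessions from the
#' same trained state.
#'
#' @param net A `hippocampal_net`.
#' @return A new, independent `hippocampal_net`.
#' @export
clone_net <- function(net) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(net, all.names = TRUE)) assign(nm, get(nm, envir = net), envir = out)
  class(out) <- "hippocampal_net"
  out
}

# count, for every cell, how many of its anatomical afferents are active
afferent_counts <- function(aff, active_attrs, N_ctx) {
  act <- logical(N_ctx)
  act[active_attrs] <- TRUE
  .rowSums(act[aff], nrow(aff), ncol(aff))
}

# rate of each potentiated cell: fraction of its learned attributes active
potentiated_rates <- function(pot, active_attrs, N_ctx, N_hipp) {
  act <- logical(N_ctx)
  act[active_attrs] <- TRUE
  r <- numeric(N_hipp)
  cells <- which(lengths(pot) > 0L)
  for (i in cells) {
    s <- pot[[i]]
    r[i] <- sum(act[s]) / length(s)
  }
  r
}

# potentiate EC synapses on `cells` from the active attributes among each
# cell's anatomical afferents, renormalizing each cell's potentiated
# weights to sum 1 with equal per-synapse weights (stored as the set).
potentiate_ec <- function(pot, aff, cells, active_attrs) {
  act_set <- active_attrs
  for (i in cells) {
    new_syn <- intersect(aff[i, ], act_set)
    if (length(new_syn)) pot[[i]] <- union(pot[[i]], new_syn)
  }
  pot
}

#' Create a representation
#'
#' Creation mode: all anatomical synapses transmit irrespective of
#' potentiation, dentate KWTA is engaged, and the dentate-to-CA3 relay
#' is up-modulated so the CA3 winners are exactly the dyad partners of
#' the `K` dentate winners. Tie noise guarantees exactly `K` winners.
#' The winners' entorhinal synapses from the active attributes then
#' potentiate (weights renormalized to sum 1 per cell), all recurrent
#' collaterals among the winners potentiate, and every winner's synapse
#' onto the entorhinal output cell of every active attribute
#' potentiates. The winner set is registered as the permanent
#' representation; membership never changes afterwards.
#'
#' With the dentate silenced during encoding, the winners are instead
#' the `K` CA3 cells most excited through their direct anatomical
#' afferents, and no dentate synapse potentiates.
#'
#' @param net A `hippocampal_net` (mutated in place).
#' @param active_ec Integer set of active attribute indices; the caller
#'   (the session controller) is responsible for only creating once at
#'   least `Z0` attributes are active.
#' @param context_id Bookkeeping label recorded on the representation
#'   (never read by the algorithm).
#' @param lesion A [lesion_config()].
#' @return The new representation record (invisibly the net is updated):
#'   a list with `id`, `cells` (exactly `K` dyad indices),
#'   `created_at_Zcur`, `context_id`.
#' @export
create_representation <- function(net, active_ec, context_id = NA_character_,
                                  lesion = lesion_config()) {
  p <- net$p
  if (lesion$dg_off_encoding) {
    exc <- afferent_counts(net$ca3_aff, active_ec, p$N_ctx)
  } else {
    exc <- afferent_counts(net$dg_aff, active_ec, p$N_ctx)
  }
  winners <- kwta(exc, p$K, keep_ties = FALSE, noise_eps = p$noise_eps)
  if (length(winners) < p$K)
    stop("degenerate world: only ", length(winners),
         " cells with positive excitation during creation (need K = ", p$K, ")")
  winners <- sort(winners)

  if (!lesion$dg_off_encoding && !lesion$dg_plasticity_off)
    net$dg_pot <- potentiate_ec(net$dg_pot, net$dg_aff, winners, active_ec)
  net$ca3_pot <- potentiate_ec(net$ca3_pot, net$ca3_aff, winners, active_ec)

  # full recurrent clique among the winners (no self-pairs)
  pairs <- expand.grid(i = winners, j = winners)
  pairs <- pairs[pairs$i != pairs$j, ]
  clique <- Matrix::sparseMatrix(i = pairs$i, j = pairs$j,
                                 dims = c(p$N_hipp, p$N_hipp))
  net$rec <- net$rec | clique

  # every winner potentiates onto the output cell of every active attribute
  for (i in winners) net$out_pot[[i]] <- union(net$out_pot[[i]], active_ec)

  rep_id <- sprintf("rep%03d", length(net$reps) + 1L)
  record <- list(id = rep_id, cells = winners,
                 created_at_Zcur = length(active_ec),
                 context_id = context_id)
  net$reps[[rep_id]] <- record
  invisible(record)
}

#' One recall cycle
#'
#' Recall mode: no plasticity; potentiated synapses transmit at their
#' learned weights. Dentate cells fire at rates proportional to their
#' excitation (no KWTA), each CA3 cell receives its dyad partner's rate
#' plus `dpf` times its direct potentiated input, and CA3's strict KWTA
#' produces the pre-recurrent pattern. If fewer than `K0` cells are
#' active the cycle extinguishes (no recurrent processing, silent
#' output). Otherwise the recurrent collaterals iterate
#' `n_recurrent_iters` times with ties kept, so an exact evidence tie
#' leaves more than `K` cells active, in which case downstream output
#' is suppressed. A final pattern of at most `K` cells drives the
#' entorhinal output layer: an output cell fires if at least
#' `thrsh_ctx` of the active CA3 cells have potentiated synapses onto
#' it. The active representation is the registered one whose cell set
#' equals the final pattern exactly, if any.
#'
#' Recall never mutates the network.
#'
#' @param net A `hippocampal_net`.
#' @param active_ec Integer set of currently active attribute indices.
#' @param lesion A [lesion_config()].
#' @return A list of class `recall_result`: `ptrn_o`, `x_po`,
#'   `ptrn_fnl`, `ecout_active`, `active_rep` (id or `NA`).
#' @export
recall_cycle <- function(net, active_ec, lesion = lesion_config()) {
  p <- net$p
  if (length(active_ec) == 0L) {
    return(structure(list(ptrn_o = integer(0), x_po = 0L,
                          ptrn_fnl = integer(0), ecout_active = integer(0),
                          active_rep = NA_character_),
                     class = "recall_result"))
  }
  dg_rate <- if (lesion$dg_off_recall) numeric(p$N_hipp) else
    potentiated_rates(net$dg_pot, active_ec, p$N_ctx, p$N_hipp)
  exc <- dg_rate
  if (p$dpf > 0) {
    direct <- potentiated_rates(net$ca3_pot, active_ec, p$N_ctx, p$N_hipp)
    exc <- exc + p$dpf * direct
  }
  ptrn_o <- sort(kwta(exc, p$K, keep_ties = FALSE, noise_eps = p$noise_eps))
  x_po <- length(ptrn_o)
  if (x_po < p$K0) {
    return(structure(list(ptrn_o = ptrn_o, x_po = x_po,
                          ptrn_fnl = integer(0), ecout_active = integer(0),
                          active_rep = NA_character_),
                     class = "recall_result"))
  }
  pattern <- ptrn_o
  for (it in seq_len(p$n_recurrent_iters)) {
    rexc <- Matrix::colSums(net$rec[pattern, , drop = FALSE])
    pattern <- kwta(rexc, p$K, keep_ties = TRUE)
  }
  ptrn_fnl <- sort(pattern)
  if (length(ptrn_fnl) > p$K || length(ptrn_fnl) == 0L) {
    ecout <- integer(0)
  } else {
    counts <- tabulate(unlist(net$out_pot[ptrn_fnl]), nbins = p$N_ctx)
    ecout <- which(counts >= p$thrsh_ctx)
  }
  active_rep <- NA_character_
  for (r in net$reps) {
    if (length(r$cells) == length(ptrn_fnl) && all(r$cells == ptrn_fnl)) {
      active_rep <- r$id
      break
    }
  }
  structure(list(ptrn_o = ptrn_o, x_po = x_po, ptrn_fnl = ptrn_fnl,
                 ecout_active = ecout, active_rep = active_rep),
            class = "recall_result")
}

#' Update a representation
#'
#' Update mode: the representation's dyads are reactivated through the
#' backward CA3-to-dentate path, every attribute currently sampled or
#' recalled is active in both entorhinal layers, and plasticity is
#' re-enabled -- so each representation cell potentiates its synapses
#' from any target attribute among its anatomical afferents (weights
#' renormalized per cell to an equal-weight sum of 1), and every
#' representation cell acquires output synapses onto all target
#' attributes. The cell membership of the representation never changes.
#' Updating with already-associated attributes is a no-op.
#'
#' @param net A `hippocampal_net` (mutated in place).
#' @param rep_id Id of a registered representation.
#' @param sampled Integer set of currently sampled attributes.
#' @param recalled Integer set of currently recalled attributes.
#' @param lesion A [lesion_config()].
#' @return The net, invisibly.
#' @export
update_representation <- function(net, rep_id, sampled,
                                  recalled = integer(0),
                                  lesion = lesion_config()) {
  rec <- net$reps[[rep_id]]
  if (is.null(rec)) stop("representation not registered: ", rep_id)
  target <- union(sampled, recalled)
  cells <- rec$cells
  if (!lesion$dg_plasticity_off)
    net$dg_pot <- potentiate_ec(net$dg_pot, net$dg_aff, cells, target)
  net$ca3_pot <- potentiate_ec(net$ca3_pot, net$ca3_aff, cells, target)
  for (i in cells) net$out_pot[[i]] <- union(net$out_pot[[i]], target)
  invisible(net)
}

#' Overlap of two representations
#'
#' @param net A `hippocampal_net`.
#' @param rep_a,rep_b Representation ids.
#' @return Fraction of shared cells, `|cells_a n cells_b| / K`.
#' @export
representation_overlap <- function(net, rep_a, rep_b) {
  a <- net$reps[[rep_a]]; b <- net$reps[[rep_b]]
  if (is.null(a) || is.null(b)) stop("both representations must be registered")
  length(intersect(a$cells, b$cells)) / net$p$K
}

#' Attributes associated with a representation
#'
#' The attributes whose entorhinal output cells the representation can
#' drive, i.e. those with potentiated synapses from at least
#' `thrsh_ctx` of the representation's cells. Immediately after
#' creation or update this equals the set of attributes that were
#' active, and its size is the recalled count the representation will
#' produce.
#'
#' @param net A `hippocampal_net`.
#' @param rep_id A representation id.
#' @return Integer vector of attribute indices.
#' @export
representation_attrs <- function(net, rep_id) {
  rec <- net$reps[[rep_id]]
  if (is.null(rec)) stop("representation not registered: ", rep_id)
  counts <- tabulate(unlist(net$out_pot[rec$cells]), nbins = net$p$N_ctx)
  which(counts >= net$p$thrsh_ctx)
}
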