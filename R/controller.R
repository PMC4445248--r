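#' Begin a session (one visit to one context)
#'
#' Sets up the working memory for a visit: an empty set of sampled
#' attributes, a fresh random sampling stream over the context's
#' attributes, and an empty per-representation evidence history. The
#' network (synaptic state, amygdala weights) persists across sessions;
#' the session state does not.
#'
#' @param net A `hippocampal_net`.
#' @param ctx A `fear_context`.
#' @param seed Optional integer seed for the sampling order.
#' @param lesion A [lesion_config()] applied to every cycle of the
#'   session.
#' @return A `fear_session` environment.
#' @export
begin_session <- function(net, ctx, seed = NULL, lesion = lesion_config()) {
  s <- new.env(parent = emptyenv())
  s$net <- net
  s$ctx <- ctx
  s$lesion <- lesion
  s$stream <- sample_stream(ctx, seed)
  s$active_ec <- integer(0)
  s$created_this_session <- FALSE
  s$created_rep <- NA_character_
  s$rep_history <- list()   # per rep id: list(max_b, suppressing, released)
  s$trace <- list()
  class(s) <- "fear_session"
  s
}

#' Decide the operating mode for the current cycle
#'
#' Update if a representation was created earlier this session (it is
#' valid by construction for the rest of the visit), or if the evidence
#' for the active representation reaches `B_add` (virtual certainty).
#' Otherwise creation is considered once at least `Z0` attributes have
#' been sampled, at most once per session, and only while no
#' previously-probably-valid representation still dictates suppression:
#' it triggers either on strong negative evidence (`B < B_new`) or on a
#' persistently silent hippocampus (pre-recurrent pattern below `K0`).
#' Otherwise the cycle is plain recall.
#'
#' @param b Current weight of evidence.
#' @param z_cur Number of attributes sampled so far.
#' @param x_po Size of the pre-recurrent CA3 pattern.
#' @param session A `fear_session`.
#' @return One of `"recall"`, `"create"`, `"update"`.
#' @export
decide_mode <- function(b, z_cur, x_po, session) {
  p <- session$net$p
  if (session$created_this_session) return("update")
  if (b >= p$B_add) return("update")
  suppressed <- any(vapply(session$rep_history,
                           function(h) h$suppressing && !h$released, logical(1)))
  if (z_cur >= p$Z0 && !suppressed && (b < p$B_new || x_po < p$K0))
    return("create")
  "recall"
}

#' Advance a session by one sampled attribute
#'
#' The full per-sample cycle: draw the next attribute into working
#' memory; run a recall cycle; compute the recalled and common counts
#' and the weight of evidence (zero if the output layer is silent);
#' update the per-representation evidence bookkeeping that implements
#' creation-suppression; decide and execute the mode (create / update /
#' recall); derive conditionability and fear from the governing
#' evidence value -- the expected evidence at `z_rec = z_cur` on
#' creation sessions, the computed evidence otherwise; and apply the
#' unconditioned stimulus if one is scheduled on this sample.
#'
#' @param session A `fear_session` (mutated in place).
#' @param us `TRUE` to deliver an unconditioned stimulus on this sample.
#' @return A one-row data frame (also appended to the session trace)
#'   with columns `sample`, `z_cur`, `x_po`, `n_fnl`, `z_rec`, `z_com`,
#'   `b_rep`, `b_used`, `mode`, `active_rep`, `cnd`, `fear`, `us`.
#' @export
step_sample <- function(session, us = FALSE) {
  net <- session$net
  p <- net$p
  lesion <- session$lesion

  attr_new <- stream_next(session$stream)
  session$active_ec <- c(session$active_ec, attr_new)
  z_cur <- length(session$active_ec)

  rc <- recall_cycle(net, session$active_ec, lesion)
  z_rec <- length(rc$ecout_active)
  z_com <- length(intersect(session$active_ec, rc$ecout_active))
  silent <- z_rec == 0L
  b <- b_rep(z_cur, z_rec, z_com, p, ecout_silent = silent)

  # evidence bookkeeping for the representation controlling the output
  if (!is.na(rc$active_rep)) {
    h <- session$rep_history[[rc$active_rep]]
    if (is.null(h)) h <- list(max_b = -Inf, suppressing = FALSE, released = FALSE)
    h$max_b <- max(h$max_b, b)
    if (b >= p$B_pv) h$suppressing <- TRUE
    if (h$suppressing && b < p$B_new) h$released <- TRUE
    session$rep_history[[rc$active_rep]] <- h
  }

  mode <- decide_mode(b, z_cur, rc$x_po, session)
  active_cells <- rc$ptrn_fnl
  if (mode == "create") {
    rec <- create_representation(net, session$active_ec,
                                 context_id = session$ctx$id, lesion = lesion)
    session$created_this_session <- TRUE
    session$created_rep <- rec$id
    active_cells <- rec$cells
  } else if (mode == "update") {
    rep_id <- if (session$created_this_session) session$created_rep else rc$active_rep
    if (!is.na(rep_id))
      update_representation(net, rep_id, session$active_ec, rc$ecout_active,
                            lesion)
    if (session$created_this_session && !is.na(session$created_rep))
      active_cells <- net$reps[[session$created_rep]]$cells
  }

  b_used <- if (session$created_this_session)
    expected_b_rep(z_cur, z_cur, p) else b
  cnd <- linsig(b_used, p$B_old, p$B_add)
  fear <- fear_expression(net, active_cells, b_used)
  if (us) condition_us(net, active_cells, cnd)

  row <- data.frame(
    sample = length(session$trace) + 1L, z_cur = z_cur,
    x_po = rc$x_po, n_fnl = length(rc$ptrn_fnl),
    z_rec = z_rec, z_com = z_com, b_rep = b, b_used = b_used,
    mode = mode, active_rep = rc$active_rep,
    cnd = cnd, fear = fear, us = us,
    stringsAsFactors = FALSE
  )
  session$trace[[length(session$trace) + 1L]] <- row
  row
}

#' Condition the amygdala with an unconditioned stimulus
#'
#' Each synapse from an active CA3 cell onto the amygdala fear unit is
#' strengthened by `alpha * Cnd`. Nothing changes when no cells are
#' active or conditionability is zero; weights only ever grow (there is
#' deliberately no extinction).
#'
#' @param net A `hippocampal_net` (mutated in place).
#' @param active_cells Integer indices of the active CA3 cells.
#' @param cnd Conditionability in `[0, 1]`.
#' @return The net, invisibly.
#' @export
condition_us <- function(net, active_cells, cnd) {
  if (length(active_cells) && cnd > 0)
    net$amyg_w[active_cells] <- net$amyg_w[active_cells] + net$p$alpha * cnd
  invisible(net)
}

#' Fear expression
#'
#' The conductance the active CA3 cells exert on the amygdala fear unit
#' is the sum of their potentiated weights, gated multiplicatively by
#' the evidence (rising from zero evidence -- better to err on the side
#' of being afraid -- and saturating at `B_add`); the expressed fear is
#' the resulting depolarization `Ge' / (1 + Ge')`.
#'
#' @param net A `hippocampal_net`.
#' @param active_cells Integer indices of the active CA3 cells.
#' @param b_used Governing weight of evidence.
#' @return Fear in `[0, 1)`.
#' @export
fear_expression <- function(net, active_cells, b_used) {
  p <- net$p
  ge <- if (length(active_cells)) sum(net$amyg_w[active_cells]) else 0
  ge_eff <- linsig(b_used, 0, p$B_add) * ge
  membrane_potential(ge_eff, 0, 1)
}

#' Run a full session
#'
#' Convenience driver: begins a session, advances it `n_samples` times
#' (delivering unconditioned stimuli at the listed samples), and
#' returns the trace.
#'
#' @param net A `hippocampal_net` (mutated in place).
#' @param ctx A `fear_context`.
#' @param n_samples Number of attributes to sample (at most `N_A`).
#' @param us_at Integer vector of sample indices at which an
#'   unconditioned stimulus is delivered.
#' @param seed Optional integer seed for the sampling order.
#' @param lesion A [lesion_config()].
#' @return A data frame, one row per sample (see [step_sample()]).
#' @export
run_session <- function(net, ctx, n_samples, us_at = integer(0),
                        seed = NULL, lesion = lesion_config()) {
  session <- begin_session(net, ctx, seed = seed, lesion = lesion)
  for (t in seq_len(n_samples)) step_sample(session, us = t %in% us_at)
  session_trace(session)
}

#' Collect a session's trace as a data frame
#'
#' @param session A `fear_session`.
#' @return A data frame, one row per completed sample.
#' @export
session_trace <- function(session) {
  do.call(rbind, session$trace)
}
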