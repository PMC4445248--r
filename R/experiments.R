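#' Familiarize a network with a context to a target recalled count
#'
#' Establishes a representation whose associated attribute set has
#' exactly `z_target` attributes: a representation is created from `Z0`
#' randomly sampled attributes of the context and then updated with a
#' random `z_target`-superset. Any schedule of visits reaching the same
#' associated count is equivalent for later behavior, so this compressed
#' schedule stands in for repeated visits.
#'
#' @param net A `hippocampal_net` (mutated in place).
#' @param ctx A `fear_context`.
#' @param z_target Target associated-attribute count (`Z0 <=
#'   z_target <= N_A`).
#' @param seed Optional integer seed for the attribute draws.
#' @return The representation id.
#' @export
familiarize <- function(net, ctx, z_target, seed = NULL) {
  p <- net$p
  stopifnot(z_target >= p$Z0, z_target <= p$N_A)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(ctx$attrs)
  rec <- create_representation(net, perm[seq_len(p$Z0)], context_id = ctx$id)
  if (z_target > p$Z0)
    update_representation(net, rec$id, perm[seq_len(z_target)])
  rec$id
}

#' Pattern separation across replicate networks
#'
#' For each replicate, draws a fresh attribute universe, two contexts
#' at the stated similarity, and a fresh network, then creates both
#' representations -- either with every attribute of each context
#' active (`"full"`) or with only `Z0` randomly sampled attributes
#' each (`"partial"`) -- and records the overlap of the two winner
#' sets.
#'
#' @param p A [fear_params()] object.
#' @param similarity Attribute similarity of the two contexts (>=
#'   `N_gen / N_A`).
#' @param sampling `"full"` or `"partial"`.
#' @param n_reps Number of replicate networks.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Numeric vector of per-replicate overlap fractions in `[0, 1]`.
#' @export
run_pattern_separation <- function(p, similarity = 0.9,
                                   sampling = c("full", "partial"),
                                   n_reps = 100L, seed = 1L) {
  sampling <- match.arg(sampling)
  vapply(seq_len(n_reps), function(r) {
    s <- seed + r
    ens <- build_ensemble(p, seed = s)
    ens <- add_context(ens, "A")
    ens <- add_context(ens, "B", similar_to = "A", similarity = similarity)
    net <- build_net(p, seed = s + 100003L)
    active <- function(ctx) {
      if (sampling == "full") ctx$attrs else sample(ctx$attrs, p$Z0)
    }
    ra <- create_representation(net, active(ens$contexts$A), "A")
    rb <- create_representation(net, active(ens$contexts$B), "B")
    representation_overlap(net, ra$id, rb$id)
  }, numeric(1))
}

#' Evidence-threshold calibration scan
#'
#' Two deterministic constants characterize the evidence model under a
#' given parameter set:
#' * `min_useful`: the smallest recalled count `z` such that the
#'   evidence at full sampling, `b_rep(z_com = z | z_cur = N_A, z_rec =
#'   z)`, reaches `B_old` -- the smallest representation that could ever
#'   support conditioning.
#' * `operational`: the smallest `z` such that the expected evidence on
#'   the `z_cur = z_rec = z` diagonal reaches `B_add` -- the point at
#'   which a re-entered, just-created representation would again permit
#'   updating.
#'
#' @param p A [fear_params()] object.
#' @return A list with integer elements `min_useful` and `operational`.
#' @export
run_z0_calibration <- function(p) {
  bs <- vapply(seq_len(p$N_A), function(z) b_rep(p$N_A, z, z, p), numeric(1))
  min_useful <- which(bs >= p$B_old)[1]
  eb <- vapply(seq_len(p$N_A), function(z) expected_b_rep(z, z, p), numeric(1))
  operational <- which(eb >= p$B_add)[1]
  if (is.na(min_useful) || is.na(operational))
    stop("calibration failure: no threshold crossing in 1..N_A under the '",
         p$diff_model, "' diff model")
  list(min_useful = as.integer(min_useful),
       operational = as.integer(operational))
}

#' Expected conditionability curve
#'
#' Conditionability along a session entered with a fixed recalled count,
#' computed from the expected evidence (deterministic).
#'
#' @param p A [fear_params()] object.
#' @param z_rec Recalled count at session entry.
#' @return A data frame with columns `z_cur` and `cnd`.
#' @export
conditionability_curve <- function(p, z_rec) {
  z <- seq_len(p$N_A)
  cnd <- vapply(z, function(zc)
    linsig(expected_b_rep(zc, z_rec, p), p$B_old, p$B_add), numeric(1))
  data.frame(z_cur = z, cnd = cnd)
}

#' Recall dynamics with a similar competitor
#'
#' The network is familiarized with two contexts A and B at a given
#' similarity (to recalled counts `zrec_a` and `zrec_b`), then probed
#' with a recall-only test in A, recording for each sample how many
#' cells of each representation appear in the pre-recurrent and final
#' CA3 patterns. Conditions share connectivity, familiarization draws
#' and sampling order within a replicate (a paired design), and differ
#' only in the recall pathway configuration:
#' `"indirect"` (dentate only, `dpf = 0`), `"direct"` (dentate silenced
#' in recall, direct path only), and `"mixed"` (both, with the given
#' `dpf`).
#'
#' @param p A [fear_params()] object.
#' @param similarity Attribute similarity of A and B.
#' @param zrec_a,zrec_b Familiarization targets for A and B.
#' @param dpf_mixed Direct-path factor of the mixed condition.
#' @param n_reps Number of paired replicate sets.
#' @param n_test Number of test samples per probe session.
#' @param seed Base seed.
#' @return A data frame with one row per (replicate, condition, sample):
#'   columns `rep`, `condition`, `sample`, `n_a_po`, `n_b_po`,
#'   `n_a_fnl`, `n_b_fnl`.
#' @export
run_recall_dynamics <- function(p, similarity = 0.93, zrec_a = 95L,
                                zrec_b = 80L, dpf_mixed = 0.15,
                                n_reps = 24L, n_test = 100L, seed = 1L) {
  conds <- list(
    indirect = list(dpf = 0, lesion = lesion_config()),
    direct = list(dpf = 1, lesion = lesion_config(dg_off_recall = TRUE)),
    mixed = list(dpf = dpf_mixed, lesion = lesion_config())
  )
  out <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 17L * r
    ens <- build_ensemble(p, seed = s)
    ens <- add_context(ens, "A")
    ens <- add_context(ens, "B", similar_to = "A", similarity = similarity)
    for (cn in names(conds)) {
      pc <- p; pc$dpf <- conds[[cn]]$dpf
      net <- build_net(pc, seed = s + 1L)
      ra <- familiarize(net, ens$contexts$A, zrec_a, seed = s + 2L)
      rb <- familiarize(net, ens$contexts$B, zrec_b, seed = s + 3L)
      cells_a <- net$reps[[ra]]$cells
      cells_b <- net$reps[[rb]]$cells
      stream <- sample_stream(ens$contexts$A, seed = s + 4L)
      active <- integer(0)
      for (t in seq_len(n_test)) {
        active <- c(active, stream_next(stream))
        rc <- recall_cycle(net, active, conds[[cn]]$lesion)
        out[[length(out) + 1L]] <- data.frame(
          rep = r, condition = cn, sample = t,
          n_a_po = length(intersect(rc$ptrn_o, cells_a)),
          n_b_po = length(intersect(rc$ptrn_o, cells_b)),
          n_a_fnl = length(intersect(rc$ptrn_fnl, cells_a)),
          n_b_fnl = length(intersect(rc$ptrn_fnl, cells_b)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Generalization of conditioned fear to a similar context
#'
#' Three-phase protocol: pre-exposure (95 samples) to either the
#' generalization test context A (`prefam = "test"`) or a maximally
#' different context D (`prefam = "different"`); conditioning (80
#' samples, unconditioned stimulus on the last) in a novel context B at
#' the given similarity to A; then a test session (99 samples) in A
#' recording the fear trace.
#'
#' @param p A [fear_params()] object.
#' @param similarity Similarity of the test context to the
#'   conditioning context.
#' @param prefam `"test"` or `"different"`.
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param n_prefam,n_cond,n_test Phase lengths in samples.
#' @return A data frame with columns `rep`, `sample`, `fear`, `mode`.
#' @export
run_generalization <- function(p, similarity = 0.9,
                               prefam = c("test", "different"),
                               n_reps = 30L, seed = 1L,
                               n_prefam = 95L, n_cond = 80L, n_test = 99L) {
  prefam <- match.arg(prefam)
  out <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 23L * r
    ens <- build_ensemble(p, seed = s)
    ens <- add_context(ens, "B")
    ens <- add_context(ens, "A", similar_to = "B", similarity = similarity)
    ens <- add_context(ens, "D")
    net <- build_net(p, seed = s + 1L)
    pre_ctx <- if (prefam == "test") ens$contexts$A else ens$contexts$D
    run_session(net, pre_ctx, n_prefam, seed = s + 2L)
    run_session(net, ens$contexts$B, n_cond, us_at = n_cond, seed = s + 3L)
    tr <- run_session(net, ens$contexts$A, n_test, seed = s + 4L)
    out[[length(out) + 1L]] <- data.frame(rep = r, sample = tr$sample,
                                          fear = tr$fear, mode = tr$mode,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fear misattribution with a familiar similar context
#'
#' Pre-exposure (60 samples) to context A, then a conditioning session
#' in a novel 95%-similar context B whose length sets the
#' unconditioned-stimulus timing: 75 samples (`"early"`), 88
#' (`"middle"`) or 95 (`"late"`), with the stimulus on the final
#' sample. Fear is then tested with independent sessions in A and in B
#' (each on its own copy of the trained network) and summarized as the
#' mean fear over the test session.
#'
#' @param p A [fear_params()] object.
#' @param timing `"early"`, `"middle"` or `"late"`.
#' @param prefam `"similar"` (pre-expose to A) or `"different"`
#'   (pre-expose to a maximally different context D).
#' @param similarity Similarity of A and B.
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param n_test Test-session length in samples.
#' @return A data frame with one row per replicate: columns `rep`,
#'   `fear_a`, `fear_b`.
#' @export
run_misattribution <- function(p, timing = c("early", "middle", "late"),
                               prefam = c("similar", "different"),
                               similarity = 0.95, n_reps = 30L, seed = 1L,
                               n_test = 60L) {
  timing <- match.arg(timing)
  prefam <- match.arg(prefam)
  n_cond <- switch(timing, early = 75L, middle = 88L, late = 95L)
  out <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 31L * r
    ens <- build_ensemble(p, seed = s)
    ens <- add_context(ens, "A")
    ens <- add_context(ens, "B", similar_to = "A", similarity = similarity)
    ens <- add_context(ens, "D")
    net <- build_net(p, seed = s + 1L)
    pre_ctx <- if (prefam == "similar") ens$contexts$A else ens$contexts$D
    run_session(net, pre_ctx, 60L, seed = s + 2L)
    run_session(net, ens$contexts$B, n_cond, us_at = n_cond, seed = s + 3L)
    ta <- run_session(clone_net(net), ens$contexts$A, n_test, seed = s + 4L)
    tb <- run_session(clone_net(net), ens$contexts$B, n_test, seed = s + 5L)
    out[[length(out) + 1L]] <- data.frame(rep = r, fear_a = mean(ta$fear),
                                          fear_b = mean(tb$fear))
  }
  do.call(rbind, out)
}

#' Dentate lesion suite
#'
#' Factorial dentate manipulations around a conditioning/test protocol.
#' Each replicate first familiarizes two distinct background contexts
#' with the dentate intact (so previously potentiated dentate synapses
#' exist, as they would in any experienced animal), then runs a
#' conditioning session (75 samples, stimulus at the end) in a novel
#' context and a test session in the same context, under one of:
#' `intact`; `enc_off` (dentate silenced during the conditioning
#' session only); `both_off` (dentate silenced during conditioning and
#' test); `plast_off` (dentate plasticity absent throughout, firing
#' intact). A second test in a 90%-similar novel context gives a
#' discrimination measure. Recall runs with a weak direct path
#' (`dpf`) so that direct-path routing is available to the lesioned
#' conditions, as it is in the intact circuit.
#'
#' @param p A [fear_params()] object; its `dpf` is overridden by `dpf`.
#' @param dpf Direct-path factor used in all conditions.
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param conditions Character subset of the four conditions.
#' @return A data frame with one row per (replicate, condition):
#'   columns `rep`, `condition`, `fear_cond_ctx`, `fear_similar`,
#'   `discrimination` (their difference).
#' @export
run_lesion_suite <- function(p, dpf = 0.15, n_reps = 10L, seed = 1L,
                             conditions = c("intact", "enc_off",
                                            "both_off", "plast_off")) {
  pc <- p; pc$dpf <- dpf
  out <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 41L * r
    ens <- build_ensemble(pc, seed = s)
    ens <- add_context(ens, "D1")
    ens <- add_context(ens, "D2")
    ens <- add_context(ens, "A")
    ens <- add_context(ens, "C", similar_to = "A", similarity = 0.9)
    for (cn in conditions) {
      plast <- cn == "plast_off"
      les_enc <- lesion_config(
        dg_off_encoding = cn %in% c("enc_off", "both_off"),
        dg_off_recall = cn == "both_off",
        dg_plasticity_off = plast)
      les_test <- lesion_config(dg_off_recall = cn == "both_off",
                                dg_plasticity_off = plast)
      les_bg <- lesion_config(dg_plasticity_off = plast)
      net <- build_net(pc, seed = s + 1L)
      ses <- begin_session(net, ens$contexts$D1, seed = s + 2L, lesion = les_bg)
      for (t in 1:75) step_sample(ses)
      ses <- begin_session(net, ens$contexts$D2, seed = s + 3L, lesion = les_bg)
      for (t in 1:75) step_sample(ses)
      ses <- begin_session(net, ens$contexts$A, seed = s + 4L, lesion = les_enc)
      for (t in 1:75) step_sample(ses, us = t == 75L)
      ta <- run_session(clone_net(net), ens$contexts$A, 60L,
                        seed = s + 5L, lesion = les_test)
      tc <- run_session(clone_net(net), ens$contexts$C, 60L,
                        seed = s + 6L, lesion = les_test)
      out[[length(out) + 1L]] <- data.frame(
        rep = r, condition = cn,
        fear_cond_ctx = mean(ta$fear), fear_similar = mean(tc$fear),
        discrimination = mean(ta$fear) - mean(tc$fear),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
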