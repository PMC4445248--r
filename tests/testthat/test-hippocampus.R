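test_that("network wiring has the stated fan-in and is seed-reproducible", {
  p <- small_params()
  net <- build_net(p, seed = 11)
  expect_identical(dim(net$dg_aff), c(200L, 24L))
  expect_identical(dim(net$ca3_aff), c(200L, 24L))
  expect_true(all(apply(net$dg_aff, 1, anyDuplicated) == 0))
  net2 <- build_net(p, seed = 11)
  expect_identical(net2$dg_aff, net$dg_aff)
  expect_identical(net2$ca3_aff, net$ca3_aff)
  expect_false(identical(build_net(p, seed = 12)$dg_aff, net$dg_aff))
  expect_error(build_net(fear_params(F_aff = 2000)), "F_aff <= N_ctx")
})

test_that("creation selects K winners whose afferent sampling is enriched", {
  p <- fear_params()
  net <- build_net(p, seed = 13)
  ens <- add_context(build_ensemble(p, seed = 13), "A")
  set.seed(14)
  active <- sample(ens$contexts$A$attrs, 45)
  # population expectation: 45 active of 1000, 60 afferents -> 2.7 per cell
  pop <- mean(apply(net$dg_aff, 1, function(a) sum(a %in% active)))
  expect_lt(abs(pop - 2.7), 0.15)
  rec <- create_representation(net, active, "A")
  expect_length(rec$cells, 60)
  pots <- lengths(net$dg_pot[rec$cells])
  expect_true(all(pots >= 1))
  # winners are selected for dense innervation: ~7-8 potentiated synapses,
  # well above the 2.7 population mean
  expect_gt(mean(pots), 6)
  expect_lt(mean(pots), 10)
  # the registered representation is immutable bookkeeping of exactly K dyads
  expect_identical(net$reps[[rec$id]]$cells, rec$cells)
})

test_that("a perfect probe completes the stored representation", {
  p <- small_params()
  w <- two_context_world(p, seed = 15)
  attrs <- w$ens$contexts$A$attrs
  rec <- create_representation(w$net, attrs, "A")
  rc <- recall_cycle(w$net, attrs)
  expect_identical(rc$ptrn_fnl, rec$cells)
  expect_identical(rc$active_rep, rec$id)
  expect_true(all(attrs %in% rc$ecout_active))
})

test_that("recall is read-only and extinguishes below the recurrent threshold", {
  p <- small_params()
  w <- two_context_world(p, seed = 16)
  attrs <- w$ens$contexts$A$attrs
  create_representation(w$net, attrs, "A")
  snap <- list(dg = w$net$dg_pot, ca3 = w$net$ca3_pot, out = w$net$out_pot,
               rec = w$net$rec, amyg = w$net$amyg_w)
  rc0 <- recall_cycle(w$net, integer(0))
  expect_identical(rc0$x_po, 0L)
  expect_identical(rc0$ecout_active, integer(0))
  for (i in 1:10) recall_cycle(w$net, sample(attrs, 8))
  expect_identical(w$net$dg_pot, snap$dg)
  expect_identical(w$net$ca3_pot, snap$ca3)
  expect_identical(w$net$out_pot, snap$out)
  expect_identical(w$net$amyg_w, snap$amyg)
  # a probe activating fewer than K0 pattern cells is extinguished
  one <- recall_cycle(w$net, attrs[1])
  if (one$x_po < p$K0) {
    expect_identical(one$ptrn_fnl, integer(0))
    expect_identical(one$ecout_active, integer(0))
  }
})

test_that("recurrent completion matches a brute-force iterator exhaustively", {
  p <- small_params()
  for (seed in 1:6) {
    w <- two_context_world(p, similarity = 0.75, seed = 100 + seed)
    ra <- create_representation(w$net, w$ens$contexts$A$attrs, "A")
    rb <- create_representation(w$net, w$ens$contexts$B$attrs, "B")
    set.seed(seed)
    for (k in c(6, 12, 18, 24)) {
      probe <- sample(w$ens$contexts$A$attrs, k)
      rc <- recall_cycle(w$net, probe)
      if (rc$x_po < p$K0) next
      oracle <- brute_recurrent(w$net$reps, rc$ptrn_o, p$K,
                                p$n_recurrent_iters, p$N_hipp)
      expect_identical(rc$ptrn_fnl, oracle)
      # plurality completion: a strict plurality wins outright
      na <- length(intersect(rc$ptrn_o, ra$cells))
      nb <- length(intersect(rc$ptrn_o, rb$cells))
      shared <- intersect(ra$cells, rb$cells)
      if (na > nb && all(intersect(rc$ptrn_o, rb$cells) %in% shared))
        expect_identical(rc$ptrn_fnl, ra$cells)
    }
  }
})

test_that("an exact evidence tie leaves more than K cells and silences output", {
  p <- fear_params(N_hipp = 20L, K = 6L, K0 = 2L, thrsh_ctx = 5L,
                   N_ctx = 50L, N_A = 20L, N_gen = 10L, F_aff = 10L, Z0 = 10L)
  net <- build_net(p, seed = 17)
  # two overlapping representations installed directly: cells 5 and 6 shared
  install <- function(cells, id) {
    net$reps[[id]] <- list(id = id, cells = cells, created_at_Zcur = 10L,
                           context_id = id)
    pairs <- expand.grid(i = cells, j = cells)
    pairs <- pairs[pairs$i != pairs$j, ]
    net$rec <- net$rec | Matrix::sparseMatrix(i = pairs$i, j = pairs$j,
                                              dims = c(p$N_hipp, p$N_hipp))
  }
  install(1:6, "repA")
  install(5:10, "repB")
  # drive a pre-recurrent pattern with three cells of each, none shared
  for (i in c(1:3, 7:9)) net$dg_pot[[i]] <- 1L
  rc <- recall_cycle(net, 1L)
  expect_setequal(rc$ptrn_o, c(1:3, 7:9))
  expect_gt(length(rc$ptrn_fnl), p$K)
  expect_identical(rc$ecout_active, integer(0))
  expect_identical(rc$active_rep, NA_character_)
})

test_that("updating associates new attributes without changing membership", {
  p <- small_params()
  w <- two_context_world(p, seed = 18)
  attrs <- w$ens$contexts$A$attrs
  set.seed(19)
  first <- sample(attrs, p$Z0)
  rec <- create_representation(w$net, first, "A")
  expect_setequal(representation_attrs(w$net, rec$id), first)
  # idempotent on already-associated attributes
  before <- list(w$net$dg_pot, w$net$ca3_pot, w$net$out_pot)
  update_representation(w$net, rec$id, first)
  expect_identical(list(w$net$dg_pot, w$net$ca3_pot, w$net$out_pot), before)
  # enlarging the association enlarges the recalled set to the full target
  update_representation(w$net, rec$id, attrs)
  expect_setequal(representation_attrs(w$net, rec$id), attrs)
  expect_identical(w$net$reps[[rec$id]]$cells, rec$cells)
  rc <- recall_cycle(w$net, attrs[1:8])
  if (rc$active_rep %in% rec$id)
    expect_identical(length(rc$ecout_active), length(attrs))
})

test_that("potentiated weight sets stay consistent under create/update sequences", {
  # weights are stored as per-cell sets with implied equal weights 1/m,
  # so the sum-to-one invariant holds by construction; what must hold is
  # that sets only contain anatomical afferents and never shrink
  p <- small_params()
  w <- two_context_world(p, similarity = 0.75, seed = 20)
  ra <- create_representation(w$net, w$ens$contexts$A$attrs[1:12], "A")
  rb <- create_representation(w$net, w$ens$contexts$B$attrs[1:14], "B")
  sizes0 <- lengths(w$net$dg_pot)
  set.seed(21)
  for (i in 1:5) {
    update_representation(w$net, ra$id, sample(w$ens$contexts$A$attrs, 10))
    update_representation(w$net, rb$id, sample(w$ens$contexts$B$attrs, 10))
  }
  expect_true(all(lengths(w$net$dg_pot) >= sizes0))
  for (i in seq_len(p$N_hipp)) {
    if (is.null(w$net$dg_pot[[i]])) next
    expect_true(all(w$net$dg_pot[[i]] %in% w$net$dg_aff[i, ]))
    expect_identical(anyDuplicated(w$net$dg_pot[[i]]), 0L)
  }
})

test_that("representation overlap is a fraction of shared dyads", {
  p <- small_params()
  w <- two_context_world(p, similarity = 0.5, seed = 22)
  ra <- create_representation(w$net, w$ens$contexts$A$attrs, "A")
  rb <- create_representation(w$net, w$ens$contexts$B$attrs, "B")
  expect_identical(representation_overlap(w$net, ra$id, ra$id), 1)
  ov <- representation_overlap(w$net, ra$id, rb$id)
  expect_gte(ov, 0)
  expect_lte(ov, 1)
  expect_equal(ov, length(intersect(ra$cells, rb$cells)) / p$K)
})

test_that("silencing the dentate during encoding reroutes winner selection", {
  p <- small_params()
  w <- two_context_world(p, seed = 23)
  attrs <- w$ens$contexts$A$attrs
  les <- lesion_config(dg_off_encoding = TRUE)
  rec <- create_representation(w$net, attrs, "A", lesion = les)
  # winners are now the most densely innervated CA3 cells, dentate silent
  expect_true(all(lengths(w$net$dg_pot[rec$cells]) == 0))
  expect_true(all(lengths(w$net$ca3_pot[rec$cells]) >= 1))
  direct_counts <- apply(w$net$ca3_aff, 1, function(a) sum(a %in% attrs))
  expect_gte(min(direct_counts[rec$cells]), sort(direct_counts, decreasing = TRUE)[p$K] - 1)
})
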