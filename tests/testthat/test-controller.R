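test_that("sessions start with empty working memory and preserve the net", {
  p <- small_params()
  w <- two_context_world(p, seed = 30)
  s1 <- begin_session(w$net, w$ens$contexts$A, seed = 31)
  expect_length(s1$active_ec, 0)
  expect_length(s1$rep_history, 0)
  step_sample(s1)
  s2 <- begin_session(w$net, w$ens$contexts$A, seed = 32)
  expect_false(identical(s2$stream$order, s1$stream$order))
  expect_identical(s2$net, w$net)
})

test_that("a distinctive novel context triggers creation exactly at Z0", {
  p <- fear_params()
  ens <- add_context(build_ensemble(p, seed = 33), "A")
  net <- build_net(p, seed = 34)
  tr <- run_session(net, ens$contexts$A, 60, seed = 35)
  expect_identical(which(tr$mode == "create"), p$Z0)
  expect_true(all(tr$mode[seq_len(p$Z0 - 1)] == "recall"))
  expect_true(all(tr$mode[(p$Z0 + 1):60] == "update"))
  expect_true(all(tr$x_po[seq_len(p$Z0 - 1)] < p$K0))
  # immediate shock deficit: no conditionability before creation,
  # a gradual rise afterwards
  expect_true(all(tr$cnd[seq_len(p$Z0 - 1)] == 0))
  after <- tr$cnd[p$Z0:60]
  expect_true(all(diff(after) >= -1e-12))
  expect_gt(after[1], 0)
  expect_lt(after[1], 0.2)
})

test_that("mode decisions follow the evidence thresholds and suppression", {
  p <- fear_params()
  net <- build_net(small_params(), seed = 36)  # only params are consulted
  net$p <- p
  fake_session <- function(hist = list(), created = FALSE) {
    s <- new.env(parent = emptyenv())
    s$net <- net; s$rep_history <- hist; s$created_this_session <- created
    s
  }
  # strong negative evidence with enough samples: create
  expect_identical(decide_mode(-3.5, 50, 60, fake_session()), "create")
  # silent hippocampus at Z0: create
  expect_identical(decide_mode(0, 45, 3, fake_session()), "create")
  # not enough samples yet: recall
  expect_identical(decide_mode(-3.5, 30, 3, fake_session()), "recall")
  # a probably-valid representation earlier in the session suppresses creation
  hist <- list(rep001 = list(max_b = 5, suppressing = TRUE, released = FALSE))
  expect_identical(decide_mode(-3.5, 50, 60, fake_session(hist)), "recall")
  # once the suppressor itself collapses below B_new, creation is allowed
  hist$rep001$released <- TRUE
  expect_identical(decide_mode(-3.5, 50, 60, fake_session(hist)), "create")
  # virtual certainty: update
  expect_identical(decide_mode(16, 50, 60, fake_session()), "update")
  # a representation created this session is updated unconditionally
  expect_identical(decide_mode(-10, 50, 3, fake_session(created = TRUE)), "update")
})

test_that("conditioning increments follow the learning rule arithmetic", {
  p <- fear_params()
  net <- build_net(small_params(), seed = 37)
  net$p <- p
  net$amyg_w <- numeric(200)
  cells <- 1:60
  condition_us(net, cells, cnd = 0)
  expect_identical(sum(net$amyg_w), 0)
  condition_us(net, cells, cnd = 1)
  # total added strength alpha * K = 0.025 * 60 = 1.5
  expect_equal(sum(net$amyg_w), 1.5)
  condition_us(net, cells, cnd = 1)
  expect_equal(unique(net$amyg_w[cells]), 0.05)
  condition_us(net, integer(0), cnd = 1)
  expect_equal(sum(net$amyg_w), 3)
  # weights never decrease: there is no extinction
  expect_true(all(net$amyg_w >= 0))
})

test_that("fear expression is evidence-gated and saturates as derived", {
  p <- fear_params()
  net <- build_net(small_params(), seed = 38)
  net$p <- p
  net$amyg_w <- numeric(200)
  cells <- 1:60
  expect_identical(fear_expression(net, cells, b_used = 20), 0)  # untrained
  net$amyg_w[cells] <- p$alpha  # one full-strength conditioning event
  # zero or negative evidence expresses nothing, whatever the weights
  expect_identical(fear_expression(net, cells, b_used = 0), 0)
  expect_identical(fear_expression(net, cells, b_used = -5), 0)
  # at certainty the conductance 1.5 gives fear 1.5/2.5 = 0.6
  expect_equal(fear_expression(net, cells, b_used = p$B_add), 0.6)
  expect_equal(fear_expression(net, cells, b_used = 2 * p$B_add), 0.6)
  # partial evidence scales the conductance down
  expect_lt(fear_expression(net, cells, b_used = 5), 0.6)
})

test_that("a shock in an unrecognized context conditions nothing", {
  p <- fear_params()
  ens <- add_context(build_ensemble(p, seed = 39), "A")
  net <- build_net(p, seed = 40)
  tr <- run_session(net, ens$contexts$A, 10, us_at = 10, seed = 41)
  expect_identical(tr$cnd[10], 0)
  expect_identical(sum(net$amyg_w), 0)
})

test_that("updating first engages when evidence reaches B_add and recall grows", {
  p <- fear_params()
  ens <- add_context(build_ensemble(p, seed = 42), "A")
  net <- build_net(p, seed = 43)
  run_session(net, ens$contexts$A, 70, seed = 44)
  tr <- run_session(net, ens$contexts$A, 80, seed = 45)
  first_up <- which(tr$mode == "update")[1]
  expect_false(is.na(first_up))
  expect_gte(tr$b_rep[first_up], p$B_add)
  expect_true(all(tr$b_rep[seq_len(first_up - 1)] < p$B_add))
  # the update associates everything sampled or recalled, so the recalled
  # count jumps to at least the sampled count on the next cycle
  expect_gte(tr$z_rec[first_up + 1], tr$z_cur[first_up + 1])
  expect_gt(tr$z_rec[first_up + 1], tr$z_rec[first_up])
})
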