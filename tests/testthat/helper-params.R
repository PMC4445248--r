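# reduced-scale parameter set for fast network tests: same structural
# ratios as the default operating point, 50x fewer cells
small_params <- function(...) {
  fear_params(N_ctx = 120L, N_hipp = 200L, N_A = 24L, N_gen = 12L,
              F_aff = 24L, K = 12L, K0 = 4L, Z0 = 10L, thrsh_ctx = 8L, ...)
}

# two-context ensemble + fresh net at the given scale
two_context_world <- function(p, similarity = NULL, seed = 1L) {
  ens <- build_ensemble(p, seed = seed)
  ens <- add_context(ens, "A")
  ens <- if (is.null(similarity)) add_context(ens, "B") else
    add_context(ens, "B", similar_to = "A", similarity = similarity)
  list(ens = ens, net = build_net(p, seed = seed + 1L))
}

# independent brute-force recurrent iterator: dense adjacency built
# directly from the representation cliques, plain loops, ties kept
brute_recurrent <- function(reps, ptrn_o, K, n_iters, n_cells) {
  adj <- matrix(FALSE, n_cells, n_cells)
  for (r in reps) for (i in r$cells) for (j in r$cells)
    if (i != j) adj[i, j] <- TRUE
  pattern <- ptrn_o
  for (it in seq_len(n_iters)) {
    exc <- integer(n_cells)
    for (j in seq_len(n_cells)) exc[j] <- sum(adj[pattern, j])
    pos <- which(exc > 0)
    if (length(pos) <= K) { pattern <- pos; next }
    cutoff <- sort(exc[pos], decreasing = TRUE)[K]
    pattern <- pos[exc[pos] >= cutoff]
  }
  sort(pattern)
}
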