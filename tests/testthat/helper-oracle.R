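# Independent re-evaluation of the rate equations, written as explicit
# per-cell loops over the literal formulas (no shared code with
# network_step).  Used as the oracle for the vectorized implementation.
oracle_step <- function(y_mf, y_go_prev, masks, weights, sigma = 8,
                        mu = 0.5) {
  sig <- function(x) 1 / (1 + exp(-sigma * (x - mu)))
  n_gc <- ncol(masks$m_mf_gc)
  n_go <- ncol(masks$m_mf_go)
  n_ba <- ncol(masks$m_pf_ba)

  x_gc <- numeric(n_gc)
  for (j in seq_len(n_gc)) {
    s <- 0
    for (i in seq_along(y_mf))
      s <- s + y_mf[i] * masks$m_mf_gc[i, j] * weights$w_mf_gc[i, j]
    for (g in seq_along(y_go_prev))
      s <- s + y_go_prev[g] * masks$m_go_gc[g, j] * weights$w_go_gc[g, j]
    x_gc[j] <- s
  }
  y_pf <- sig(x_gc)

  x_go <- numeric(n_go)
  for (j in seq_len(n_go)) {
    s <- 0
    for (i in seq_along(y_mf))
      s <- s + y_mf[i] * masks$m_mf_go[i, j] * weights$w_mf_go[i, j]
    for (g in seq_len(n_gc))
      s <- s + y_pf[g] * masks$m_pf_go[g, j] * weights$w_pf_go[g, j]
    x_go[j] <- s
  }
  y_go <- sig(x_go)

  x_ba <- numeric(n_ba)
  for (j in seq_len(n_ba)) {
    s <- 0
    for (g in seq_len(n_gc))
      s <- s + y_pf[g] * masks$m_pf_ba[g, j] * weights$w_pf_ba[g, j]
    x_ba[j] <- s
  }
  y_ba <- sig(x_ba)

  x_pc <- 0
  for (g in seq_len(n_gc)) x_pc <- x_pc + y_pf[g] * weights$w_pf_pc[g]
  for (b in seq_len(n_ba)) x_pc <- x_pc + y_ba[b] * weights$w_ba_pc[b, 1]
  y_pc <- sig(x_pc) - 0.5

  list(y_pf = y_pf, y_go = y_go, y_ba = y_ba, y_pc = y_pc)
}

# toy fixture with randomized (seeded) weights inside the legal ranges
random_toy <- function(seed, n_mf = 2L, n_gc = 3L, n_go = 1L, n_ba = 1L) {
  toy <- make_toy_network(n_mf, n_gc, n_go, n_ba)
  set.seed(seed)
  rand_fill <- function(m, lo, hi)
    matrix(runif(length(m), lo, hi), nrow(m), ncol(m))
  toy$weights$w_mf_gc <- rand_fill(toy$weights$w_mf_gc, 0.05, 1)
  toy$weights$w_go_gc <- rand_fill(toy$weights$w_go_gc, -1, -0.05)
  toy$weights$w_mf_go <- rand_fill(toy$weights$w_mf_go, 0.05, 1)
  toy$weights$w_pf_go <- rand_fill(toy$weights$w_pf_go, 0.05, 1)
  toy$weights$w_pf_ba <- rand_fill(toy$weights$w_pf_ba, 0.05, 1)
  toy$weights$w_ba_pc <- rand_fill(toy$weights$w_ba_pc, -1, -0.05)
  toy$weights$w_pf_pc <- runif(n_gc, 0.05, 1)
  toy
}

# small configuration for fast closed-loop tests
fast_config <- function(...) flocculus_config(...)
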