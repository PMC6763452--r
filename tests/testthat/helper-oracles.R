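# Independent brute-force oracles.  These deliberately share no code with
# the package: payoffs come from an explicit 2x2 matrix lookup and
# neighbourhoods from modular coordinate arithmetic over all site pairs.

bf_pair_payoff <- function(sx, sy, b) {
  # rows: focal strategy (D = 1, C = 2); cols: opponent strategy
  M <- rbind(c(0, b),  # D vs D -> P = 0, D vs C -> T = b
             c(0, 1))  # C vs D -> S = 0, C vs C -> R = 1
  M[sx + 1L, sy + 1L]
}

# periodic von Neumann adjacency decided per pair of coordinates
bf_adjacent <- function(L, r1, c1, r2, c2) {
  dr <- abs(r1 - r2); dr <- min(dr, L - dr)
  dc <- abs(c1 - c2); dc <- min(dc, L - dc)
  (dr + dc) == 1
}

bf_total_payoff <- function(world, r, c, b) {
  L <- world$L
  acc <- 0
  for (r2 in seq_len(L)) for (c2 in seq_len(L)) {
    if (bf_adjacent(L, r, c, r2, c2))
      acc <- acc + bf_pair_payoff(world$strategy[r, c],
                                  world$strategy[r2, c2], b)
  }
  acc
}

bf_env_avg <- function(world, r, c, b,
                       comparison = c("all", "same", "different")) {
  comparison <- match.arg(comparison)
  L <- world$L
  vals <- c()
  for (r2 in seq_len(L)) for (c2 in seq_len(L)) {
    if (!bf_adjacent(L, r, c, r2, c2)) next
    keep <- switch(comparison,
      all = TRUE,
      same = world$strategy[r2, c2] == world$strategy[r, c],
      different = world$strategy[r2, c2] != world$strategy[r, c])
    if (keep) vals <- c(vals, bf_total_payoff(world, r2, c2, b))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

random_test_world <- function(L, seed) {
  set.seed(seed)
  s <- matrix(sample(c(0L, 1L), L * L, replace = TRUE), L, L)
  # rounding keeps every w exactly representable at the grid format's
  # six decimals, so text round-trips are bit-exact
  w <- matrix(round(sample(seq(0.1, 1, by = 0.05), L * L, replace = TRUE),
                    6), L, L)
  new_world(s, w)
}

# one-sided permutation test that mean(x) - mean(y) > 0
perm_test_greater <- function(x, y, n_perm = 2000, seed = 99) {
  set.seed(seed)
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  stat <- replicate(n_perm, {
    idx <- sample.int(length(pool), nx)
    mean(pool[idx]) - mean(pool[-idx])
  })
  mean(c(stat, obs) >= obs)
}
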