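p105 <- game_params(b = 1.05, d = 0.05)

test_that("pairwise payoffs follow the weak-dilemma parameterization", {
  expect_equal(pair_payoff("C", "C", p105), 1)     # R
  expect_equal(pair_payoff("C", "D", p105), 0)     # S
  expect_equal(pair_payoff("D", "C", p105), 1.05)  # T = b
  expect_equal(pair_payoff("D", "D", p105), 0)     # P
})

test_that("total payoffs sum over the neighbourhood", {
  allC <- new_world(matrix("C", 4, 4))
  expect_equal(total_payoff(allC, c(2, 2), p105), 4)
  oneD <- allC
  oneD$strategy[2, 2] <- 0L
  expect_equal(total_payoff(oneD, c(2, 2), p105), 4 * 1.05)
  allD <- new_world(matrix("D", 4, 4))
  allD$strategy[3, 3] <- 1L
  expect_equal(total_payoff(allD, c(3, 3), p105), 0)
  expect_error(total_payoff(allC, c(5, 1), p105), "out of range")
})

test_that("payoffs and environment averages match the brute-force oracle", {
  for (seed in 1:100) {
    w <- random_test_world(4, seed)
    r <- sample.int(4, 1); c <- sample.int(4, 1)
    expect_equal(total_payoff(w, c(r, c), p105),
                 bf_total_payoff(w, r, c, 1.05))
    expect_equal(environment_average_payoff(w, c(r, c), p105),
                 bf_env_avg(w, r, c, 1.05, "all"))
  }
})

test_that("restricted comparison sets match the oracle, empty set -> NA", {
  p_same <- game_params(b = 1.05, comparison_set = "same_strategy")
  p_diff <- game_params(b = 1.05, comparison_set = "different_strategy")
  for (seed in 1:30) {
    w <- random_test_world(4, seed + 500)
    r <- sample.int(4, 1); c <- sample.int(4, 1)
    expect_equal(environment_average_payoff(w, c(r, c), p_same),
                 bf_env_avg(w, r, c, 1.05, "same"))
    expect_equal(environment_average_payoff(w, c(r, c), p_diff),
                 bf_env_avg(w, r, c, 1.05, "different"))
  }
  # a cooperator surrounded by defectors has no same-strategy neighbour
  w <- new_world(matrix("D", 4, 4))
  w$strategy[2, 2] <- 1L
  expect_true(is.na(environment_average_payoff(w, c(2, 2), p_same)))
})

test_that("Fermi adoption probability has the right values and bounds", {
  expect_equal(adoption_probability(2, 2, w_x = 1, K = 0.1), 0.5)
  expect_equal(adoption_probability(2, 2, w_x = 0.5, K = 0.1), 0.25)
  expect_equal(adoption_probability(4, 0, w_x = 1, K = 0.1),
               1 / (1 + exp(40)))
  # monotone increasing in P_y - P_x, bounded by (0, w_x)
  py <- seq(-4, 4, by = 0.5)
  pr <- adoption_probability(0, py, w_x = 0.7, K = 0.1)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr > 0 & pr <= 0.7))  # saturates to w_x at large gaps
  # extreme payoff gaps saturate smoothly instead of overflowing
  expect_equal(adoption_probability(1e6, 0, 1, 0.1), 0)
  expect_equal(adoption_probability(0, 1e6, 0.9, 0.1), 0.9)
})

test_that("rule gating enables w evolution for the right strategy class", {
  expect_true(is_w_evolution_enabled("I", "C"))
  expect_true(is_w_evolution_enabled("I", "D"))
  expect_true(is_w_evolution_enabled("II", "C"))
  expect_false(is_w_evolution_enabled("II", "D"))
  expect_false(is_w_evolution_enabled("III", "C"))
  expect_true(is_w_evolution_enabled("III", "D"))
})

test_that("winner-weaken-loser-strengthen update and its clamps", {
  expect_equal(evolve_learning_ability(0.5, 1, 2, d = 0.05), 0.55)
  # tie counts as winning: decrease
  expect_equal(evolve_learning_ability(0.5, 2, 2, d = 0.05), 0.45)
  expect_equal(evolve_learning_ability(0.12, 3, 1, d = 0.05), 0.1)
  expect_equal(evolve_learning_ability(0.98, 0, 1, d = 0.05), 1)
  expect_equal(evolve_learning_ability(0.5, 0, 1, d = 0), 0.5)
  # empty-environment sentinel leaves w untouched
  expect_equal(evolve_learning_ability(0.5, 1, NA_real_, d = 0.05), 0.5)
})

test_that("an elementary update is exactly reproducible from its seed", {
  w <- random_test_world(4, seed = 3)
  p <- game_params(b = 1.3, d = 0.05, rule = "I")
  set.seed(42); a <- elementary_update(w, p)
  set.seed(42); b <- elementary_update(w, p)
  expect_identical(a, b)
})

test_that("the compiled step agrees with the R operation surface", {
  # Predict the full outcome of the compiled elementary update from the
  # documented draw protocol (site, neighbour, acceptance) using only the
  # exported R operations, then compare, over many seeds and rules.
  for (seed in 1:60) {
    rule <- c("I", "II", "III")[seed %% 3 + 1]
    p <- game_params(b = 1.25, K = 0.5, d = 0.05, rule = rule)
    w0 <- random_test_world(4, seed = seed + 1000)
    N <- 16L

    set.seed(seed)
    u <- runif(3)
    x <- as.integer(floor(u[1] * N) + 1)
    nb <- pdcoev:::site_neighbours(w0, x)
    y <- as.integer(nb[floor(u[2] * 4) + 1])
    sx <- ifelse(w0$strategy == 1L, "C", "D")
    px <- total_payoff(w0, x, p)
    py <- total_payoff(w0, y, p)
    adopted <- u[3] < adoption_probability(px, py, w0$w[x], p$K)
    s_post <- if (adopted) sx[y] else sx[x]
    expected <- w0
    expected$strategy[x] <- as.integer(s_post == "C")
    if (is_w_evolution_enabled(rule, s_post)) {
      pbar <- environment_average_payoff(w0, x, p)
      expected$w[x] <- evolve_learning_ability(w0$w[x], px, pbar, p$d)
    }

    set.seed(seed)
    got <- elementary_update(w0, p)
    expect_identical(got$outcome$site, x)
    expect_identical(got$outcome$neighbour, y)
    expect_identical(got$outcome$adopted, adopted)
    expect_equal(got$outcome$payoff_focal, px)
    expect_equal(got$outcome$payoff_neighbour, py)
    expect_equal(got$world$strategy, expected$strategy)
    expect_equal(got$world$w, expected$w)
  }
})

test_that("at most one site changes and it copies the chosen neighbour", {
  p <- game_params(b = 1.25, K = 0.5, d = 0.05)
  for (seed in 1:40) {
    w0 <- random_test_world(4, seed = seed + 2000)
    set.seed(seed)
    res <- elementary_update(w0, p)
    ds <- which(res$world$strategy != w0$strategy)
    dw <- which(res$world$w != w0$w)
    expect_lte(length(ds), 1)
    expect_lte(length(dw), 1)
    if (length(ds)) {
      expect_identical(ds, res$outcome$site)
      expect_true(res$outcome$adopted)
      expect_identical(res$world$strategy[ds],
                       w0$strategy[res$outcome$neighbour])
    }
    expect_true(res$outcome$w_after %in%
      c(res$outcome$w_before,
        min(max(res$outcome$w_before + p$d, p$w_min), p$w_max),
        min(max(res$outcome$w_before - p$d, p$w_min), p$w_max)))
  }
})

test_that("uniform populations are strategy-absorbing; w drains to w_min", {
  p <- game_params(b = 1.2, d = 0.05, rule = "I")
  allD <- new_world(matrix("D", 6, 6))
  st <- allD
  set.seed(1)
  for (i in 1:20) st <- full_mc_step(st, p)$world
  expect_true(all(st$strategy == 0L))
  expect_true(all(st$w <= 1 - 0.05))  # P_x = Pbar = 0 ties push w down

  allC <- new_world(matrix("C", 6, 6))
  run <- run_to_stationarity(allC, p,
                             schedule(80, 10,
                                      early_stop_on_absorption = FALSE),
                             seed = 2)
  expect_true(all(run$world$strategy == 1L))
  expect_equal(run$stationary_f_C, 1)
  expect_true(all(run$world$w == 0.1))
})

test_that("d = 0 reproduces the homogeneous game: w stays exactly 1", {
  p <- game_params(b = 1.2, d = 0)
  run <- run_to_stationarity(random_initial(12, seed = 4), p,
                             schedule(60, 10), seed = 4)
  expect_true(all(run$world$w == 1))
})

test_that("a full MC step performs L^2 elementary draws", {
  # with the documented 3-uniforms-per-update protocol, one MC step on an
  # LxL lattice advances the RNG stream by exactly 3 L^2 draws
  w0 <- random_initial(5, seed = 9)
  p <- game_params(b = 1.3, d = 0.05)
  set.seed(7); invisible(full_mc_step(w0, p)); after_step <- runif(1)
  set.seed(7); invisible(runif(3 * 25)); expect_identical(runif(1), after_step)
})
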