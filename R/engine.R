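#' Pairwise payoff of the weak prisoner's dilemma
#'
#' Payoff earned by the focal strategy `s_x` against opponent `s_y`:
#' R = 1 for mutual cooperation, T = b for defecting against a
#' cooperator, and S = P = 0 otherwise.
#'
#' @param s_x,s_y Strategies, `"C"` or `"D"` (vectorized).
#' @param params A [game_params()] object supplying `b`.
#' @return Numeric payoff(s).
#' @examples
#' p <- game_params(b = 1.05)
#' pair_payoff("D", "C", p)  # temptation b
#' @export
pair_payoff <- function(s_x, s_y, params) {
  x <- s_x == "C"
  y <- s_y == "C"
  ifelse(x & y, 1, ifelse(!x & y, params$b, 0))
}

#' Total payoff of one site against its neighbourhood
#'
#' Sum of pairwise payoffs of the site's strategy against each of its
#' neighbours (four on the default lattice).
#'
#' @param world A `pd_world`.
#' @param site `(row, col)` pair (1-based) or a linear site index.
#' @param params A [game_params()] object.
#' @return The site's total payoff.
#' @export
total_payoff <- function(world, site, params) {
  i <- site_index(world, site)
  nb <- site_neighbours(world, i)
  s <- ifelse(world$strategy == 1, "C", "D")
  sum(pair_payoff(s[i], s[nb], params))
}

#' Average payoff of a site's environment
#'
#' Mean total payoff over the selected neighbours of the site.  With the
#' default `comparison_set = "all_neighbors"` all k neighbours enter; the
#' restricted variants average only over neighbours holding the same
#' (resp. a different) strategy as the focal site and return `NA` when
#' that set is empty (no comparison possible).
#'
#' @inheritParams total_payoff
#' @return Mean neighbour payoff, or `NA_real_` for an empty comparison
#'   set.
#' @export
environment_average_payoff <- function(world, site, params) {
  i <- site_index(world, site)
  nb <- site_neighbours(world, i)
  sel <- switch(params$comparison_set,
    all_neighbors = nb,
    same_strategy = nb[world$strategy[nb] == world$strategy[i]],
    different_strategy = nb[world$strategy[nb] != world$strategy[i]])
  if (length(sel) == 0) return(NA_real_)
  mean(vapply(sel, function(j) total_payoff(world, j, params), numeric(1)))
}

#' Fermi strategy-adoption probability
#'
#' Probability that the focal player copies the selected neighbour's
#' strategy: `w_x / (1 + exp((P_x - P_y) / K))`.  The learning ability
#' w_x scales the whole probability, so a conservative player (low w)
#' rarely imitates even a much richer neighbour.  The exponent is clipped
#' at +/- 700 so the value saturates smoothly to 0 or `w_x`.
#'
#' @param P_x,P_y Total payoffs of the focal player and the neighbour.
#' @param w_x Focal player's learning ability.
#' @param K Adoption noise (> 0).
#' @return Probability in (0, `w_x`); vectorized.
#' @examples
#' adoption_probability(2, 2, w_x = 1, K = 0.1)  # 0.5 at equal payoffs
#' @export
adoption_probability <- function(P_x, P_y, w_x, K) {
  z <- pmin(pmax((P_x - P_y) / K, -700), 700)
  w_x / (1 + exp(z))
}

#' Is learning-ability evolution enabled for a strategy under a rule?
#'
#' Rule I lets both strategy classes evolve w, rule II only cooperators,
#' rule III only defectors.
#'
#' @param rule `"I"`, `"II"` or `"III"` (or a [game_params()] object).
#' @param strategy `"C"` or `"D"`.
#' @return Logical.
#' @export
is_w_evolution_enabled <- function(rule, strategy) {
  if (inherits(rule, "pd_params")) rule <- rule$rule
  switch(rule,
         I = rep(TRUE, length(strategy)),
         II = strategy == "C",
         III = strategy == "D",
         stop("`rule` must be one of \"I\", \"II\", \"III\"", call. = FALSE))
}

#' Winner-weaken-loser-strengthen update of the learning ability
#'
#' A player earning less than the average payoff of its environment
#' raises its learning ability by `d` (loser strengthens); a player
#' earning at least the average lowers it by `d` (winner weakens, ties
#' included).  The result is clamped to `[w_min, w_max]`.  An `NA`
#' environment average (empty comparison set) leaves w unchanged.
#'
#' @param w_x Current learning ability.
#' @param P_x Focal player's total payoff.
#' @param Pbar_x Average payoff of the environment, or `NA`.
#' @param d Increment in \[0, 1\].
#' @param w_min,w_max Clamp bounds.
#' @return Updated learning ability; vectorized.
#' @examples
#' evolve_learning_ability(0.5, P_x = 1, Pbar_x = 2, d = 0.05)  # 0.55
#' @export
evolve_learning_ability <- function(w_x, P_x, Pbar_x, d,
                                    w_min = 0.1, w_max = 1) {
  out <- ifelse(P_x < Pbar_x, w_x + d, w_x - d)
  out <- pmin(pmax(out, w_min), w_max)
  ifelse(is.na(Pbar_x), w_x, out)
}

#' One elementary (asynchronous) update
#'
#' Performs a single update of the Monte Carlo dynamics, consuming
#' exactly three uniform draws from the current RNG stream in this
#' order: focal site, neighbour, acceptance.  The focal site x and one
#' of its neighbours y are drawn uniformly; with probability
#' [adoption_probability()] the focal site copies s_y.  All payoffs are
#' evaluated on the pre-adoption configuration; if the rule (judged on
#' the gating strategy, post-adoption by default) enables w evolution
#' for x, its learning ability is then updated against the environment
#' average via [evolve_learning_ability()].  At most one site's strategy
#' and one site's w change.
#'
#' @param world A `pd_world`.
#' @param params A [game_params()] object.
#' @return A list with the updated `world` and an `outcome` list holding
#'   `site` and `neighbour` (linear 1-based indices), `adopted`,
#'   `payoff_focal`, `payoff_neighbour`, `env_avg` (`NA` if the
#'   comparison set was empty), `w_before` and `w_after`.
#' @export
elementary_update <- function(world, params) {
  validate_params(params)
  topo <- world_topology(world)
  res <- elementary_update_cpp(as.integer(world$strategy),
                               as.numeric(world$w),
                               topo$nbr, topo$ptr,
                               params_for_engine(params))
  out <- world
  n <- length(world$strategy)
  dm <- dim(world$strategy)
  out$strategy <- matrix(res$strategy, dm[1], dm[2])
  out$w <- matrix(res$w, dm[1], dm[2])
  list(world = out,
       outcome = list(site = res$site + 1L,
                      neighbour = res$neighbour + 1L,
                      adopted = res$adopted,
                      payoff_focal = res$payoff_focal,
                      payoff_neighbour = res$payoff_neighbour,
                      env_avg = res$env_avg,
                      w_before = res$w_before,
                      w_after = res$w_after))
}

#' One full Monte Carlo step
#'
#' Performs N = L^2 elementary updates (random sequential, selection
#' with replacement), so that every player gets a chance to update
#' strategy and learning ability once on average.
#'
#' @inheritParams elementary_update
#' @return A list with the advanced `world` and the step summary:
#'   `f_C`, `mean_w_C`, `mean_w_D` (NA when the class is extinct).
#' @export
full_mc_step <- function(world, params) {
  validate_params(params)
  topo <- world_topology(world)
  res <- run_mc_cpp(as.integer(world$strategy), as.numeric(world$w),
                    topo$nbr, topo$ptr, params_for_engine(params),
                    n_steps = 1L, record_every = 1L, average_window = 1L,
                    early_stop = FALSE)
  out <- world
  dm <- dim(world$strategy)
  out$strategy <- matrix(res$strategy, dm[1], dm[2])
  out$w <- matrix(res$w, dm[1], dm[2])
  k <- length(res$f_C)
  list(world = out, f_C = res$f_C[k],
       mean_w_C = res$mean_w_C[k], mean_w_D = res$mean_w_D[k])
}
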