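#' Simulation schedule
#'
#' Desk-scale defaults: 2e4 MC steps with the stationary density taken
#' as the mean cooperation density over the trailing 2e3 steps.  Longer
#' schedules (e.g. 5e4-1e5 steps with a 5e3-step window, as used for
#' full-scale reproduction runs) are set here.
#'
#' @param max_steps Total MC steps to run.
#' @param average_window Trailing steps averaged for the stationary
#'   density; must be smaller than `max_steps`.
#' @param record_every Trajectory sampling stride (>= 1).  The trailing
#'   average always uses every step regardless of the stride.
#' @param early_stop_on_absorption Stop as soon as the population is
#'   all-C or all-D (strategy dynamics are absorbing there); the
#'   stationary density is then the absorbed value.
#' @return An object of class `pd_schedule`.
#' @export
schedule <- function(max_steps = 20000, average_window = 2000,
                     record_every = 10, early_stop_on_absorption = TRUE) {
  if (average_window >= max_steps)
    stop("`average_window` must be smaller than `max_steps`", call. = FALSE)
  if (record_every < 1) stop("`record_every` must be >= 1", call. = FALSE)
  structure(list(max_steps = as.integer(max_steps),
                 average_window = as.integer(average_window),
                 record_every = as.integer(record_every),
                 early_stop_on_absorption = isTRUE(early_stop_on_absorption)),
            class = "pd_schedule")
}

#' Cooperation density
#'
#' Fraction of cooperators in the population.
#'
#' @param world A `pd_world`.
#' @return A number in \[0, 1\].
#' @export
cooperation_density <- function(world) mean(world$strategy == 1L)

#' Run the dynamics to the stationary state
#'
#' Advances the world by full MC steps for `schedule$max_steps` steps
#' (or until absorption when early stopping is enabled) and returns the
#' sampled trajectory plus the stationary cooperation density: the mean
#' f_C over the trailing `average_window` steps, or the absorbed value.
#'
#' @param world Initial `pd_world`.
#' @param params A [game_params()] object.
#' @param schedule A [schedule()] object.
#' @param seed Optional integer seed for the whole run.
#' @return An object of class `pd_run`: list with `trajectory` (a
#'   data.frame with columns `t`, `f_C`, `mean_w_C`, `mean_w_D`, `seed`),
#'   `stationary_f_C`, `absorbed_step` (`NA` if never absorbed), the
#'   final `world`, and `empty_comparison` (count of elementary steps
#'   whose restricted comparison set was empty).
#' @examples
#' run <- run_to_stationarity(random_initial(20, seed = 1),
#'                            game_params(b = 1.02, d = 0),
#'                            schedule(200, 50), seed = 1)
#' run$stationary_f_C
#' @export
run_to_stationarity <- function(world, params, schedule = schedule(),
                                seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  topo <- world_topology(world)
  res <- run_mc_cpp(as.integer(world$strategy), as.numeric(world$w),
                    topo$nbr, topo$ptr, params_for_engine(params),
                    n_steps = schedule$max_steps,
                    record_every = schedule$record_every,
                    average_window = schedule$average_window,
                    early_stop = schedule$early_stop_on_absorption)
  out <- world
  dm <- dim(world$strategy)
  out$strategy <- matrix(res$strategy, dm[1], dm[2])
  out$w <- matrix(res$w, dm[1], dm[2])
  traj <- data.frame(t = res$t, f_C = res$f_C,
                     mean_w_C = res$mean_w_C, mean_w_D = res$mean_w_D,
                     seed = if (is.null(seed)) NA_integer_ else seed)
  structure(list(trajectory = traj,
                 stationary_f_C = res$stationary_f_C,
                 absorbed_step = if (res$absorbed_step < 0) NA_integer_
                                 else res$absorbed_step,
                 world = out,
                 empty_comparison = res$empty_comparison),
            class = "pd_run")
}

#' @export
print.pd_run <- function(x, ...) {
  cat(sprintf("pd_run: %d recorded samples, stationary f_C = %.4f%s\n",
              nrow(x$trajectory), x$stationary_f_C,
              if (is.na(x$absorbed_step)) ""
              else sprintf(", absorbed at step %d", x$absorbed_step)))
  invisible(x)
}

# Internal: deterministic child seeds for replicate sets.  One top-level
# seed spawns the whole vector up front, so replicate r always receives
# the same child seed no matter in which order replicates execute.
split_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Estimate the extinction threshold b_C of cooperation
#'
#' Scans a grid of temptation values; at each b, `reps` independently
#' seeded replicates are run from the initial condition.  A grid point
#' is declared extinct when the stationary cooperation density falls
#' below `eps` in all replicates.  The threshold estimate is the
#' midpoint of the bracket between the largest surviving and the
#' smallest extinct grid point.  A surviving point isolated above an
#' extinct one (replicate noise) is re-resolved by majority over its
#' replicates; remaining interleavings are cut at the first transition.
#'
#' If every grid point is extinct the bracket is open at the lower edge
#' and the estimate is the midpoint between the weak-dilemma limit
#' `b_floor = 1` (where defection has no payoff advantage) and the
#' smallest tested b.  If every point survives the bracket is open at
#' the upper edge and `b_C` is `NA`.
#'
#' @param params A [game_params()] object; its `b` is overridden by the
#'   grid values.
#' @param b_grid Increasing temptation values in (1, 2].
#' @param reps Replicates per grid point (>= 1).
#' @param seed Top-level seed; per-replicate child seeds are spawned
#'   deterministically from it.
#' @param L Lattice side for the built-in initializers.
#' @param schedule A [schedule()] object.
#' @param init `"random"`, `"four_bar"`, or a function `(L, seed)`
#'   returning a `pd_world`.
#' @param eps Extinction criterion on the stationary density (default
#'   1e-3, i.e. below a handful of cooperators at L = 100).
#' @param b_floor Lower limit of the temptation range used to close the
#'   bracket when extinction already holds at the smallest grid point.
#' @return An object of class `pd_scan`: list with `rows` (data.frame
#'   with columns `rule`, `d`, `b`, `replicate`, `seed`,
#'   `stationary_f_C`, `absorbed_step`), `extinct` (named flag per b),
#'   `b_C`, `bracket` (length-2), `open` (`"none"`, `"lower"`,
#'   `"upper"`) and `cleanup` (messages from majority re-resolution).
#' @export
estimate_extinction_threshold <- function(params, b_grid, reps = 5,
                                          seed = 1, L = 100,
                                          schedule = schedule(),
                                          init = "random", eps = 1e-3,
                                          b_floor = 1) {
  stopifnot(reps >= 1, length(b_grid) >= 1)
  if (is.unsorted(b_grid, strictly = TRUE))
    stop("`b_grid` must be strictly increasing", call. = FALSE)
  init_fun <- if (is.function(init)) init
    else switch(init,
                random = function(L, seed) random_initial(L, seed),
                four_bar = function(L, seed) four_bar_initial(L),
                stop("unknown initializer", call. = FALSE))
  seeds <- matrix(split_seeds(seed, length(b_grid) * reps),
                  nrow = length(b_grid))
  rows <- vector("list", length(b_grid) * reps)
  k <- 0L
  for (i in seq_along(b_grid)) {
    p <- params
    p$b <- b_grid[i]
    p <- validate_params(p)
    for (r in seq_len(reps)) {
      s <- seeds[i, r]
      run <- run_to_stationarity(init_fun(L, s), p, schedule, seed = s)
      k <- k + 1L
      rows[[k]] <- data.frame(rule = params$rule, d = params$d,
                              b = b_grid[i], replicate = r, seed = s,
                              stationary_f_C = run$stationary_f_C,
                              absorbed_step = run$absorbed_step)
    }
  }
  rows <- do.call(rbind, rows)
  scan_summary(rows, b_grid, eps, b_floor)
}

# Internal: turn scan rows into extinction flags, bracket and b_C.
scan_summary <- function(rows, b_grid, eps = 1e-3, b_floor = 1) {
  ext <- vapply(b_grid, function(b)
    all(rows$stationary_f_C[rows$b == b] < eps), logical(1))
  cleanup <- character(0)
  # majority re-resolution of survivals isolated above an extinct point
  if (any(ext)) {
    first_ext <- which(ext)[1]
    for (i in seq_along(b_grid)) {
      if (i > first_ext && !ext[i]) {
        fc <- rows$stationary_f_C[rows$b == b_grid[i]]
        ext[i] <- mean(fc < eps) > 0.5
        cleanup <- c(cleanup, sprintf(
          "b = %g above extinct b = %g re-resolved by majority: %s",
          b_grid[i], b_grid[first_ext],
          if (ext[i]) "extinct" else "surviving"))
      }
    }
  }
  names(ext) <- format(b_grid)
  if (!any(ext)) {
    out <- list(rows = rows, extinct = ext, b_C = NA_real_,
                bracket = c(b_grid[length(b_grid)], NA_real_),
                open = "upper", cleanup = cleanup)
  } else if (all(ext)) {
    out <- list(rows = rows, extinct = ext,
                b_C = (b_floor + b_grid[1]) / 2,
                bracket = c(b_floor, b_grid[1]),
                open = "lower", cleanup = cleanup)
  } else {
    cut <- which(ext)[1]  # first extinct point after cleanup
    lo <- b_grid[cut - 1L]
    hi <- b_grid[cut]
    out <- list(rows = rows, extinct = ext, b_C = (lo + hi) / 2,
                bracket = c(lo, hi), open = "none", cleanup = cleanup)
  }
  structure(out, class = "pd_scan")
}

#' @export
print.pd_scan <- function(x, ...) {
  cat(sprintf("pd_scan: %d runs over %d temptation values\n",
              nrow(x$rows), length(x$extinct)))
  if (x$open == "none")
    cat(sprintf("  b_C = %.4f in [%g, %g]\n", x$b_C,
                x$bracket[1], x$bracket[2]))
  else
    cat(sprintf("  bracket open at the %s grid edge (b_C %s)\n", x$open,
                if (is.na(x$b_C)) "undetermined"
                else sprintf("= %.4f against the b = %g limit",
                             x$b_C, x$bracket[1])))
  invisible(x)
}

#' Enduring / expanding period decomposition of a trajectory
#'
#' The cooperation density of a surviving run typically first declines
#' while defectors exploit the initial configuration (enduring, END,
#' period) and then recovers as compact cooperator clusters expand
#' through network reciprocity (expanding, EXP, period).  The split
#' point is the global minimum of the smoothed f_C trajectory.
#'
#' @param trajectory Data frame with columns `t` and `f_C` (as produced
#'   by [run_to_stationarity()]), or a `pd_run`.
#' @param smooth_window Centered moving-average window, in recorded
#'   samples (default 50).  Trajectories shorter than the window are
#'   used unsmoothed, with `warning_short = TRUE` in the result.
#' @return A list with `t_min` (MC step of the minimum; earliest on
#'   ties), `f_C_min` (raw density there), `end_slope` and `exp_slope`
#'   (mean one-step change of f_C per recorded sample before/after the
#'   minimum), `recovered` (`f_C_min > 0`) and `warning_short`.
#' @export
decompose_end_exp <- function(trajectory, smooth_window = 50) {
  if (inherits(trajectory, "pd_run")) trajectory <- trajectory$trajectory
  fc <- trajectory$f_C
  tt <- trajectory$t
  n <- length(fc)
  if (n == 0) stop("trajectory is empty", call. = FALSE)
  warning_short <- n < smooth_window
  if (warning_short || smooth_window <= 1) {
    sm <- fc
  } else {
    # centered moving average with shrinking windows at the edges
    half <- smooth_window %/% 2
    cs <- cumsum(c(0, fc))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  # earliest tie wins; the 1e-12 guard absorbs cumulative-sum rounding
  imin <- which(sm <= min(sm) + 1e-12)[1]
  end_slope <- if (imin > 1) mean(diff(fc[1:imin])) else 0
  exp_slope <- if (imin < n) mean(diff(fc[imin:n])) else 0
  list(t_min = tt[imin], f_C_min = fc[imin],
       end_slope = end_slope, exp_slope = exp_slope,
       recovered = fc[imin] > 0, warning_short = warning_short)
}

#' Per-strategy learning-ability summary
#'
#' Summarises the learning ability of each strategy class present in
#' the world, overall and restricted to boundary players (players with
#' at least one neighbour of the opposite strategy).
#'
#' @param world A `pd_world`.
#' @return A data.frame with one row per strategy present: `strategy`,
#'   `count`, `mean_w`, `min_w`, `max_w`, `boundary_count`,
#'   `boundary_mean_w` (`NA` when there are no boundary players).
#' @export
learning_ability_stats <- function(world) {
  s <- as.integer(world$strategy)
  w <- as.numeric(world$w)
  topo <- world_topology(world)
  n <- length(s)
  deg <- diff(topo$ptr)
  opp <- vapply(seq_len(n), function(i) {
    nb <- topo$nbr[(topo$ptr[i] + 1L):topo$ptr[i + 1L]] + 1L
    any(s[nb] != s[i])
  }, logical(1))
  out <- lapply(c(C = 1L, D = 0L), function(v) {
    sel <- s == v
    if (!any(sel)) return(NULL)
    bd <- sel & opp
    data.frame(strategy = if (v == 1L) "C" else "D",
               count = sum(sel), mean_w = mean(w[sel]),
               min_w = min(w[sel]), max_w = max(w[sel]),
               boundary_count = sum(bd),
               boundary_mean_w = if (any(bd)) mean(w[bd]) else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Export a snapshot of a world
#'
#' Writes three aligned plain-text files: `<prefix>_grid.txt` (the grid
#' format of [write_grid()]), `<prefix>_strategy.txt` (0/1 matrix,
#' C = 1, D = 0) and `<prefix>_w.txt` (learning abilities), suitable
#' for heat-map rendering.
#'
#' @param world A lattice `pd_world`.
#' @param path_prefix Path prefix for the three files.
#' @return Character vector of the three paths, invisibly.
#' @export
export_snapshot <- function(world, path_prefix) {
  paths <- paste0(path_prefix, c("_grid.txt", "_strategy.txt", "_w.txt"))
  write_grid(world, paths[1])
  utils::write.table(world$strategy, paths[2], row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(format(world$w, nsmall = 6, trim = TRUE), paths[3],
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
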