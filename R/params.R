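#' Game and coevolution parameters
#'
#' Bundles the parameters of the weak prisoner's dilemma and of the
#' learning-ability coevolution rule.  The payoff matrix is fully
#' determined by the temptation `b`: T = b, R = 1, P = S = 0, with
#' 1 < b <= 2 so that T > R > P >= S.
#'
#' @param b Temptation to defect, in (1, 2].
#' @param K Noise (uncertainty) of strategy adoption; must be positive.
#'   Default 0.1.
#' @param d Learning-ability increment per update, in \[0, 1\].  `d = 0`
#'   recovers the classical homogeneous game.
#' @param w_min,w_max Clamp bounds for the learning ability w; defaults
#'   0.1 and 1.  The lower clamp avoids frozen states, the upper keeps
#'   the Fermi prefactor a valid probability weight.
#' @param rule Which strategy class evolves its learning ability:
#'   `"I"` (both), `"II"` (cooperators only) or `"III"` (defectors only).
#' @param gating_basis Whether rule eligibility is judged on the focal
#'   player's strategy after (`"post_adoption"`, default) or before
#'   (`"pre_adoption"`) the adoption attempt.
#' @param comparison_set Which neighbours enter the environment-average
#'   payoff: `"all_neighbors"` (default), `"same_strategy"` or
#'   `"different_strategy"` (the latter two restrict the comparison to
#'   neighbours sharing / not sharing the focal player's strategy).
#'
#' @return An object of class `pd_params` (a validated list).
#' @examples
#' p <- game_params(b = 1.05, d = 0.03)
#' p$b
#' @export
game_params <- function(b, K = 0.1, d = 0, w_min = 0.1, w_max = 1,
                        rule = c("I", "II", "III"),
                        gating_basis = c("post_adoption", "pre_adoption"),
                        comparison_set = c("all_neighbors", "same_strategy",
                                           "different_strategy")) {
  rule <- match.arg(rule)
  gating_basis <- match.arg(gating_basis)
  comparison_set <- match.arg(comparison_set)
  p <- structure(
    list(b = b, K = K, d = d, w_min = w_min, w_max = w_max, rule = rule,
         gating_basis = gating_basis, comparison_set = comparison_set),
    class = "pd_params")
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every invariant of [game_params()] and returns the parameters
#' unchanged if all hold; otherwise stops with a message naming the
#' violated bound.
#'
#' @param params A `pd_params` object (or an equivalently named list).
#' @return The validated `pd_params` object.
#' @export
validate_params <- function(params) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(is.numeric(params$b) && length(params$b) == 1 && !is.na(params$b),
      "`b` must be a single number")
  chk(params$b > 1 && params$b <= 2,
      sprintf("`b` = %g violates 1 < b <= 2", params$b))
  chk(is.numeric(params$K) && length(params$K) == 1 && params$K > 0,
      "`K` must be a single positive number (K > 0)")
  chk(is.numeric(params$d) && length(params$d) == 1 &&
        params$d >= 0 && params$d <= 1,
      sprintf("`d` = %g violates 0 <= d <= 1", params$d))
  chk(is.numeric(params$w_min) && params$w_min > 0,
      "`w_min` must satisfy 0 < w_min")
  chk(params$w_min <= params$w_max && params$w_max <= 1,
      sprintf("w bounds violate 0 < w_min <= w_max <= 1 (got [%g, %g])",
              params$w_min, params$w_max))
  chk(params$rule %in% c("I", "II", "III"),
      "`rule` must be one of \"I\", \"II\", \"III\"")
  chk(params$gating_basis %in% c("post_adoption", "pre_adoption"),
      "`gating_basis` must be \"post_adoption\" or \"pre_adoption\"")
  chk(params$comparison_set %in%
        c("all_neighbors", "same_strategy", "different_strategy"),
      "`comparison_set` must name a neighbour comparison set")
  if (!inherits(params, "pd_params")) class(params) <- "pd_params"
  params
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf(
    "weak PDG parameters: b = %g, K = %g | rule %s, d = %g, w in [%g, %g]\n",
    x$b, x$K, x$rule, x$d, x$w_min, x$w_max))
  if (x$gating_basis != "post_adoption" || x$comparison_set != "all_neighbors")
    cat(sprintf("  gating: %s, comparison set: %s\n",
                x$gating_basis, x$comparison_set))
  invisible(x)
}

# Internal: translate a pd_params object into the flat list the compiled
# engine expects.
params_for_engine <- function(params) {
  list(b = params$b, K = params$K, d = params$d,
       w_min = params$w_min, w_max = params$w_max,
       rule = match(params$rule, c("I", "II", "III")),
       gate_post = params$gating_basis == "post_adoption",
       cmp = match(params$comparison_set,
                   c("all_neighbors", "same_strategy",
                     "different_strategy")) - 1L)
}
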