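#' Uniform random initial configuration
#'
#' Each site is independently a cooperator or defector with probability
#' 1/2 and every player starts with the maximum learning ability w = 1.
#'
#' @param L Lattice side length (>= 2).
#' @param seed Optional integer seed; if given, the RNG is seeded before
#'   drawing so the world is reproducible.
#' @return A `pd_world`.
#' @examples
#' w <- random_initial(10, seed = 1)
#' @export
random_initial <- function(L, seed = NULL) {
  if (L < 2) stop("lattice side L must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- matrix(sample(c(0L, 1L), L * L, replace = TRUE), L, L)
  new_world(s, w = 1)
}

#' Specification of a four-bar initial configuration
#'
#' Describes four vertical bars (left to right), used to study the
#' boundary dynamics between blocks of cooperators and defectors whose
#' learning abilities start at the two clamp extremes.
#'
#' @param bar_strategies Character vector of 4 strategies, left to right.
#' @param left_w Learning ability of the two left bars (default 0.1, the
#'   minimum).
#' @param right_w Learning ability of the two right bars (default 1, the
#'   maximum).
#' @return An object of class `four_bar_spec`.
#' @export
four_bar_spec <- function(bar_strategies = c("C", "D", "C", "D"),
                          left_w = 0.1, right_w = 1.0) {
  if (length(bar_strategies) != 4 || !all(bar_strategies %in% c("C", "D")))
    stop("`bar_strategies` must be 4 values in {\"C\", \"D\"}",
         call. = FALSE)
  structure(list(bar_strategies = bar_strategies,
                 left_w = left_w, right_w = right_w),
            class = "four_bar_spec")
}

#' Four-bar initial configuration
#'
#' Splits the lattice into four vertical bars of width `floor(L/4)` (the
#' remainder joins the rightmost bar).  Strategies follow the spec's bar
#' order; the two left bars start at `left_w`, the two right bars at
#' `right_w`.  Deterministic: no random numbers are consumed.
#'
#' @param L Lattice side length (>= 8).
#' @param spec A [four_bar_spec()].
#' @return A `pd_world`.
#' @examples
#' w <- four_bar_initial(8)
#' cooperation_density(w)  # 0.5 whenever L is divisible by 4
#' @export
four_bar_initial <- function(L, spec = four_bar_spec()) {
  if (L < 8) stop("four-bar initialization needs L >= 8", call. = FALSE)
  if (!inherits(spec, "four_bar_spec")) stop("`spec` must be a four_bar_spec",
                                             call. = FALSE)
  wd <- L %/% 4L
  widths <- c(wd, wd, wd, L - 3L * wd)
  bar_of_col <- rep(1:4, times = widths)
  s <- matrix(0L, L, L)
  w <- matrix(0, L, L)
  for (cc in seq_len(L)) {
    bar <- bar_of_col[cc]
    s[, cc] <- as.integer(spec$bar_strategies[bar] == "C")
    w[, cc] <- if (bar <= 2) spec$left_w else spec$right_w
  }
  new_world(s, w)
}
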