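#' Construct a lattice world
#'
#' A world is an L x L population of players, each holding a strategy
#' ("C" or "D") and a learning ability w.  The default interaction
#' topology is the von Neumann 4-neighbourhood with periodic boundary
#' conditions; an arbitrary symmetric graph can be attached with
#' [world_from_graph()].
#'
#' @param strategy Character (or 0/1 integer) matrix of strategies;
#'   "C"/1 = cooperator, "D"/0 = defector.  Must be square.
#' @param w Numeric matrix of learning abilities, same shape as
#'   `strategy`, or a single number recycled to all sites.
#' @return An object of class `pd_world`: a list with elements `L`,
#'   `strategy` (integer matrix, 1 = C, 0 = D), `w` (numeric matrix) and
#'   `topology` (`NULL` for the default periodic lattice).
#' @examples
#' w <- new_world(matrix(c("C", "D", "D", "C"), 2, 2), w = 1)
#' cooperation_density(w)
#' @export
new_world <- function(strategy, w = 1) {
  if (is.character(strategy)) {
    if (!all(strategy %in% c("C", "D")))
      stop("strategies must be \"C\" or \"D\"", call. = FALSE)
    s <- matrix(as.integer(strategy == "C"), nrow(strategy), ncol(strategy))
  } else {
    if (!all(strategy %in% c(0L, 1L)))
      stop("integer strategies must be 0 (D) or 1 (C)", call. = FALSE)
    s <- matrix(as.integer(strategy), nrow(strategy), ncol(strategy))
  }
  if (nrow(s) != ncol(s)) stop("the lattice must be square", call. = FALSE)
  L <- nrow(s)
  if (L < 2) stop("lattice side L must be >= 2", call. = FALSE)
  if (length(w) == 1) w <- matrix(as.numeric(w), L, L)
  if (!identical(dim(w), dim(s)))
    stop("`w` must match the strategy matrix shape", call. = FALSE)
  structure(list(L = L, strategy = s, w = matrix(as.numeric(w), L, L),
                 topology = NULL),
            class = "pd_world")
}

#' Attach an arbitrary symmetric interaction graph to a population
#'
#' All dynamics consume only each player's neighbour list and degree, so
#' any symmetric graph is admissible in place of the default lattice.
#'
#' @param strategy Character or 0/1 vector of strategies, one per node.
#' @param w Numeric vector of learning abilities (or a single number).
#' @param neighbours List of integer vectors: `neighbours[[i]]` are the
#'   (1-based) neighbours of node `i`.  Must be symmetric and loop-free.
#' @return A `pd_world` whose sites are stored as an n x 1 column and
#'   whose `topology` holds the graph in compressed form.
#' @export
world_from_graph <- function(strategy, w, neighbours) {
  n <- length(strategy)
  if (length(neighbours) != n)
    stop("`neighbours` must have one entry per node", call. = FALSE)
  for (i in seq_len(n)) {
    for (j in neighbours[[i]]) {
      if (j == i) stop("self-loops are not allowed", call. = FALSE)
      if (!(i %in% neighbours[[j]]))
        stop(sprintf("graph is not symmetric at edge (%d, %d)", i, j),
             call. = FALSE)
    }
  }
  s <- if (is.character(strategy)) as.integer(strategy == "C")
       else as.integer(strategy)
  if (length(w) == 1) w <- rep(as.numeric(w), n)
  deg <- lengths(neighbours)
  if (any(deg == 0)) stop("every node needs at least one neighbour",
                          call. = FALSE)
  topo <- list(nbr = as.integer(unlist(neighbours) - 1L),
               ptr = as.integer(c(0L, cumsum(deg))))
  structure(list(L = NA_integer_, strategy = matrix(s, ncol = 1),
                 w = matrix(as.numeric(w), ncol = 1), topology = topo),
            class = "pd_world")
}

#' Von Neumann neighbour map of the periodic square lattice
#'
#' @param L Lattice side length (>= 2).
#' @return An `L^2` x 4 integer matrix of 1-based site indices (sites in
#'   column-major order), columns ordered up, down, left, right.
#' @export
lattice_neighbors <- function(L) {
  if (L < 2) stop("lattice side L must be >= 2", call. = FALSE)
  idx <- function(r, c) (c - 1L) * L + r  # column-major, 1-based
  r <- rep(seq_len(L), L)
  c <- rep(seq_len(L), each = L)
  up <- ifelse(r == 1L, L, r - 1L)
  dn <- ifelse(r == L, 1L, r + 1L)
  lf <- ifelse(c == 1L, L, c - 1L)
  rt <- ifelse(c == L, 1L, c + 1L)
  cbind(up = idx(up, c), down = idx(dn, c),
        left = idx(r, lf), right = idx(r, rt))
}

# Internal: topology in the CSR form the engine consumes (0-based).
world_topology <- function(world) {
  if (!is.null(world$topology)) return(world$topology)
  nb <- lattice_neighbors(world$L)
  list(nbr = as.integer(t(nb)) - 1L,
       ptr = as.integer(seq(0L, 4L * world$L^2, by = 4L)))
}

# Internal: 1-based neighbour indices of one site.
site_neighbours <- function(world, site) {
  topo <- world_topology(world)
  i <- site_index(world, site)
  topo$nbr[(topo$ptr[i] + 1L):topo$ptr[i + 1L]] + 1L
}

# Internal: (row, col) pair or linear index -> linear 1-based index.
site_index <- function(world, site) {
  n <- length(world$strategy)
  if (length(site) == 2 && !is.na(world$L)) {
    if (any(site < 1) || any(site > world$L))
      stop("site out of range", call. = FALSE)
    (site[2] - 1L) * world$L + site[1]
  } else {
    if (site < 1 || site > n) stop("site out of range", call. = FALSE)
    as.integer(site)
  }
}

#' @export
print.pd_world <- function(x, ...) {
  n <- length(x$strategy)
  cat(sprintf("pd_world: %s, f_C = %.3f, w in [%g, %g]\n",
              if (is.na(x$L)) sprintf("graph with %d nodes", n)
              else sprintf("%d x %d periodic lattice", x$L, x$L),
              mean(x$strategy), min(x$w), max(x$w)))
  invisible(x)
}

#' Write a world to the plain-text grid format
#'
#' The format is a header line `L=<int>` followed by L lines of L
#' whitespace-separated tokens `C:<w>` or `D:<w>`, with w printed to six
#' decimals.  [load_grid()] reads it back exactly.
#'
#' @param world A lattice `pd_world`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(world, path) {
  if (is.na(world$L))
    stop("only lattice worlds have a grid representation", call. = FALSE)
  L <- world$L
  tok <- matrix(sprintf("%s:%.6f", ifelse(world$strategy == 1, "C", "D"),
                        world$w), L, L)
  lines <- c(sprintf("L=%d", L),
             apply(tok, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a world from the plain-text grid format
#'
#' @param path File in the format written by [write_grid()].
#' @param w_min,w_max Admissible learning-ability bounds; tokens outside
#'   them are rejected.
#' @return A `pd_world`.
#' @export
load_grid <- function(path, w_min = 0.1, w_max = 1) {
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("^L=\\d+$", lines[1]))
    stop("line 1: expected header \"L=<int>\"", call. = FALSE)
  L <- as.integer(sub("^L=", "", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != L)
    stop(sprintf("expected %d grid rows, found %d", L, length(body)),
         call. = FALSE)
  s <- matrix(0L, L, L)
  w <- matrix(0, L, L)
  for (r in seq_len(L)) {
    tokens <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(tokens) != L)
      stop(sprintf("line %d: expected %d tokens, found %d",
                   r + 1L, L, length(tokens)), call. = FALSE)
    for (cc in seq_len(L)) {
      tk <- tokens[cc]
      if (!grepl("^[CD]:[0-9.]+$", tk))
        stop(sprintf("line %d, column %d: malformed token \"%s\"",
                     r + 1L, cc, tk), call. = FALSE)
      s[r, cc] <- as.integer(substr(tk, 1, 1) == "C")
      wv <- as.numeric(substring(tk, 3))
      if (is.na(wv) || wv < w_min || wv > w_max)
        stop(sprintf("line %d, column %d: w = %s outside [%g, %g]",
                     r + 1L, cc, substring(tk, 3), w_min, w_max),
             call. = FALSE)
      w[r, cc] <- wv
    }
  }
  new_world(s, w)
}
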