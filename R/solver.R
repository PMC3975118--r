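# Shortest-path machinery over the 36-state board graph.

# Per-session cache: distances/neighbors only depend on the rules, not data.
.tol_cache <- new.env(parent = emptyenv())

#' @keywords internal
.tol_graph <- function(balls = .TOL_BALLS) {
  key <- paste(sort(balls), collapse = ",")
  if (!is.null(.tol_cache[[key]])) return(.tol_cache[[key]])
  states <- enumerate_states(balls)
  keys <- vapply(states, state_key, "")
  idx <- seq_along(states)
  names(idx) <- keys
  nbr <- vector("list", length(states))
  for (i in idx) {
    mv <- legal_moves(states[[i]])
    nbr[[i]] <- vapply(seq_len(nrow(mv)),
                       function(r) idx[[state_key(apply_move(states[[i]], mv[r, ]))]],
                       integer(1))
  }
  # all-pairs shortest distances by BFS from every state
  n <- length(states)
  dist <- matrix(NA_integer_, n, n)
  for (s in idx) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in nbr[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        nxt <- c(nxt, w)
      }
      frontier <- nxt
    }
    dist[s, ] <- d
  }
  g <- list(states = states, keys = keys, idx = idx, nbr = nbr, dist = dist)
  .tol_cache[[key]] <- g
  g
}

#' @keywords internal
.tol_index <- function(state, graph) {
  validate_tol_state(state)
  k <- state_key(state)
  if (is.null(graph$idx[[k]]))
    stop("state not in the board graph (mismatched ball set?)", call. = FALSE)
  graph$idx[[k]]
}

#' Minimum number of moves between two board states
#'
#' Length of the shortest legal move sequence transforming `start` into
#' `goal`, by breadth-first search over the 36-state graph. Symmetric in its
#' arguments because every move is reversible.
#'
#' @param start,goal `tol_state` objects over the same ball set.
#' @return A non-negative integer.
#' @examples
#' min_moves(tol_state(c("red", "green", "blue")),
#'           tol_state(c("red", "green"), character(), "blue"))
#' @export
min_moves <- function(start, goal) {
  if (!identical(start$balls, goal$balls))
    stop("start and goal carry different ball sets", call. = FALSE)
  g <- .tol_graph(start$balls)
  unname(g$dist[.tol_index(start, g), .tol_index(goal, g)])
}

#' Count distinct optimal move sequences
#'
#' Number of distinct shortest move sequences from `start` to `goal`. Used
#' as the goal-hierarchy ambiguity metric: 1 means the order of moves is
#' fully forced ("unambiguous"). The zero-move problem has exactly one
#' optimal path (the empty path), by convention.
#'
#' @inheritParams min_moves
#' @return A positive integer.
#' @export
count_optimal_paths <- function(start, goal) {
  g <- .tol_graph(start$balls)
  if (!identical(start$balls, goal$balls))
    stop("start and goal carry different ball sets", call. = FALSE)
  s <- .tol_index(start, g); t <- .tol_index(goal, g)
  d <- g$dist[, t]  # distance of every state to the goal
  # dynamic program over the layered shortest-path DAG
  cnt <- function(v) {
    if (v == t) return(1)
    total <- 0
    for (w in g$nbr[[v]]) if (d[w] == d[v] - 1L) total <- total + cnt(w)
    total
  }
  as.integer(cnt(s))
}

# Enumerate all optimal move sequences as lists of (from,to) pairs.
#' @keywords internal
.optimal_paths <- function(start, goal) {
  g <- .tol_graph(start$balls)
  s <- .tol_index(start, g); t <- .tol_index(goal, g)
  d <- g$dist[, t]
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    mv <- legal_moves(g$states[[v]])
    for (r in seq_len(nrow(mv))) {
      w <- g$idx[[state_key(apply_move(g$states[[v]], mv[r, ]))]]
      if (d[w] == d[v] - 1L)
        walk(w, c(acc, list(c(from = mv$from[r], to = mv$to[r], state = w))))
    }
  }
  walk(s, list())
  paths
}

#' Does a problem require an intermediate move?
#'
#' Operationalizes search depth: `TRUE` iff every optimal solution contains
#' at least one move that places a ball on a peg that is not that ball's
#' final peg in the goal state. Zero-move problems are `FALSE` (the empty
#' solution has no intermediate move).
#'
#' @inheritParams min_moves
#' @return Logical scalar.
#' @export
requires_intermediate <- function(start, goal) {
  if (min_moves(start, goal) == 0L) return(FALSE)
  g <- .tol_graph(start$balls)
  goal_peg <- .ball_pegs(goal)
  paths <- .optimal_paths(start, goal)
  path_has_intermediate <- vapply(paths, function(p) {
    st <- start
    for (step in p) {
      ball <- st$stacks[[step["from"]]][length(st$stacks[[step["from"]]])]
      if (goal_peg[[ball]] != step["to"]) return(TRUE)
      st <- apply_move(st, step[c("from", "to")])
    }
    FALSE
  }, logical(1))
  all(path_has_intermediate)
}

# peg index of each ball in a state
#' @keywords internal
.ball_pegs <- function(state) {
  out <- integer()
  for (i in 1:3) for (b in state$stacks[[i]]) out[[b]] <- i
  out
}

#' Build a fully classified S-TOL problem
#'
#' Couples a start and goal configuration with its minimum-move count,
#' search-depth classification, optimal-path count and the correct yes/no
#' answer to the task question "Can you solve this in exactly two moves?"
#' ("yes" only for two-move problems).
#'
#' @inheritParams min_moves
#' @return An object of class `tol_problem` with fields `start`, `goal`,
#'   `min_moves`, `requires_intermediate`, `n_optimal_paths`,
#'   `correct_answer`.
#' @export
problem_spec <- function(start, goal) {
  mm <- min_moves(start, goal)
  structure(list(
    start = start, goal = goal, min_moves = mm,
    requires_intermediate = requires_intermediate(start, goal),
    n_optimal_paths = count_optimal_paths(start, goal),
    correct_answer = if (mm == 2L) "yes" else "no"),
    class = "tol_problem")
}

#' @export
print.tol_problem <- function(x, ...) {
  cat(sprintf("S-TOL problem: %d move(s), answer '%s'\n",
              x$min_moves, x$correct_answer))
  cat(sprintf("  start %s  ->  goal %s\n", state_key(x$start), state_key(x$goal)))
  cat(sprintf("  intermediate move required: %s; optimal orderings: %d\n",
              x$requires_intermediate, x$n_optimal_paths))
  invisible(x)
}

#' Serialize a problem bank to JSON
#'
#' Board states are written as three arrays of ball labels, bottom to top.
#'
#' @param bank A list of `tol_problem` objects.
#' @param path Output file path.
#' @export
write_problem_bank <- function(bank, path) {
  enc <- lapply(bank, function(p) list(
    start = lapply(p$start$stacks, as.list),
    goal = lapply(p$goal$stacks, as.list),
    min_moves = p$min_moves,
    requires_intermediate = p$requires_intermediate,
    n_optimal_paths = p$n_optimal_paths,
    correct_answer = p$correct_answer))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a problem bank written by [write_problem_bank()]
#'
#' Problems are revalidated on read: stored classification fields must agree
#' with the solver's own re-computation.
#'
#' @param path JSON file path.
#' @return A list of `tol_problem` objects.
#' @export
read_problem_bank <- function(path) {
  dec <- jsonlite::read_json(path)
  lapply(dec, function(e) {
    stk <- function(s) vapply(s, as.character, "")
    start <- tol_state(stk(e$start[[1]]), stk(e$start[[2]]), stk(e$start[[3]]))
    goal <- tol_state(stk(e$goal[[1]]), stk(e$goal[[2]]), stk(e$goal[[3]]))
    p <- problem_spec(start, goal)
    if (p$min_moves != e$min_moves || p$correct_answer != e$correct_answer)
      stop("problem bank entry inconsistent with solver re-computation",
           call. = FALSE)
    p
  })
}
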