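# Independent oracles used across the suite. These deliberately avoid the
# package's own data structures and algorithms: states are plain lists of
# character vectors, move generation is re-derived from the task rules,
# shortest paths come from igraph, and the REML criterion is evaluated
# with dense matrices.

ORACLE_CAPS <- c(3L, 2L, 1L)

okey <- function(st) paste(vapply(st, paste, "", collapse = ","), collapse = "|")

# all placements of 3 distinct balls: every ball->peg assignment that fits
# the capacities, times every ordering of the balls within their pegs
oracle_states <- function(balls = c("red", "green", "blue")) {
  out <- list()
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) res[[length(res) + 1]] <- c(v[i], rest)
    res
  }
  assigns <- expand.grid(p1 = 1:3, p2 = 1:3, p3 = 1:3)
  for (r in seq_len(nrow(assigns))) {
    pegs_of <- as.integer(assigns[r, ])
    occ <- tabulate(pegs_of, 3)
    if (any(occ > ORACLE_CAPS)) next
    # orderings within pegs: permute the balls on each peg independently
    per_peg <- lapply(1:3, function(p) {
      on_peg <- balls[pegs_of == p]
      if (length(on_peg) == 0) list(character(0)) else perms(on_peg)
    })
    for (a in per_peg[[1]]) for (b in per_peg[[2]]) for (cc in per_peg[[3]])
      out[[length(out) + 1]] <- list(a, b, cc)
  }
  out[!duplicated(vapply(out, okey, ""))]
}

# rules re-derived: top ball of a non-empty peg to any non-full other peg
oracle_moves <- function(st) {
  mv <- list()
  for (i in 1:3) {
    if (length(st[[i]]) == 0) next
    for (j in 1:3) {
      if (j == i || length(st[[j]]) >= ORACLE_CAPS[j]) next
      mv[[length(mv) + 1]] <- c(i, j)
    }
  }
  mv
}

oracle_apply <- function(st, mv) {
  ball <- st[[mv[1]]][length(st[[mv[1]]])]
  st[[mv[1]]] <- st[[mv[1]]][-length(st[[mv[1]]])]
  st[[mv[2]]] <- c(st[[mv[2]]], ball)
  st
}

# adjacency and all-pairs distances via igraph (independent BFS)
oracle_graph <- function() {
  sts <- oracle_states()
  keys <- vapply(sts, okey, "")
  edges <- character(0)
  for (i in seq_along(sts)) {
    for (mv in oracle_moves(sts[[i]])) {
      k2 <- okey(oracle_apply(sts[[i]], mv))
      edges <- c(edges, keys[i], k2)
    }
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = TRUE)
  list(states = sts, keys = keys, graph = g,
       dist = igraph::distances(g, mode = "out"))
}

# iterative-deepening exhaustive search (spot-check oracle)
oracle_iddfs <- function(start, goal, max_depth = 9) {
  gk <- okey(goal)
  found <- function(st, depth) {
    if (okey(st) == gk) return(TRUE)
    if (depth == 0) return(FALSE)
    for (mv in oracle_moves(st)) if (found(oracle_apply(st, mv), depth - 1))
      return(TRUE)
    FALSE
  }
  for (d in 0:max_depth) if (found(start, d)) return(d)
  NA_integer_
}

# enumerate every optimal move sequence (list of moves) by bounded DFS
oracle_optimal_paths <- function(start, goal, len) {
  gk <- okey(goal)
  paths <- list()
  walk <- function(st, depth, acc) {
    if (depth == 0) {
      if (okey(st) == gk) paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (mv in oracle_moves(st))
      walk(oracle_apply(st, mv), depth - 1, c(acc, list(mv)))
  }
  walk(start, len, list())
  paths
}

# does a move sequence place some ball on a peg that is not its goal peg?
oracle_path_has_intermediate <- function(start, path, goal) {
  goal_peg <- integer(0)
  for (p in 1:3) for (b in goal[[p]]) goal_peg[[b]] <- p
  st <- start
  for (mv in path) {
    ball <- st[[mv[1]]][length(st[[mv[1]]])]
    if (goal_peg[[ball]] != mv[2]) return(TRUE)
    st <- oracle_apply(st, mv)
  }
  FALSE
}

# Benjamini-Hochberg from the definition: adjusted p_(i) = min over j >= i
# of min(1, m * p_(j) / j), mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# dense-matrix profiled REML criterion for the random-intercept model
oracle_reml_crit <- function(lambda, y, X, g) {
  g <- as.factor(g)
  N <- length(y); p <- ncol(X)
  Z <- stats::model.matrix(~ g - 1)
  Vs <- diag(N) + lambda * tcrossprod(Z)
  Vi <- solve(Vs)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (N - p)
  list(crit = (N - p) * log(s2) + determinant(Vs)$modulus +
         determinant(XtVX)$modulus,
       beta = as.numeric(beta), s2 = s2)
}

# signed-rank statistic recomputed independently, plus the exact two-sided
# p-value by enumerating all sign assignments
oracle_wilcoxon <- function(mm, zm) {
  d <- mm - zm
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  all_w <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(m - 1))) > 0
    sum(rk[signs])
  }, numeric(1))
  mu <- m * (m + 1) / 4
  p_exact <- mean(abs(all_w - mu) >= abs(W - mu) - 1e-12)
  list(W = W, p_exact = p_exact)
}

# frequency response magnitude of an FIR filter at frequency f (Hz)
oracle_fir_gain <- function(b, f, fs = 2) {
  abs(sum(b * exp(-1i * 2 * pi * f * (seq_along(b) - 1) / fs)))
}

# convenience: board states for tests
st3 <- function(p1 = character(), p2 = character(), p3 = character())
  tol_state(p1, p2, p3)
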