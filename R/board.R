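# Peg capacities of the S-TOL board, left to right.
.TOL_CAPACITIES <- c(3L, 2L, 1L)
.TOL_BALLS <- c("red", "green", "blue")

#' Construct a Tower of London board state
#'
#' A board holds three distinct colored balls on three pegs of capacities
#' 3, 2 and 1 (left to right), the configuration used by the S-TOL task.
#' Stacks are recorded bottom to top.
#'
#' @param peg1,peg2,peg3 Character vectors of ball labels, bottom to top.
#' @param balls The full set of ball labels the board must carry.
#' @return An object of class `tol_state`.
#' @examples
#' tol_state(c("red", "green", "blue"))
#' tol_state(c("red", "green"), character(), "blue")
#' @export
tol_state <- function(peg1 = character(), peg2 = character(),
                      peg3 = character(), balls = .TOL_BALLS) {
  stacks <- list(as.character(peg1), as.character(peg2), as.character(peg3))
  st <- structure(list(stacks = stacks, balls = sort(balls)),
                  class = "tol_state")
  validate_tol_state(st)
  st
}

#' @keywords internal
validate_tol_state <- function(state) {
  if (!inherits(state, "tol_state"))
    stop("not a 'tol_state' object", call. = FALSE)
  lens <- lengths(state$stacks)
  over <- which(lens > .TOL_CAPACITIES)
  if (length(over))
    stop(sprintf("invalid state: peg %d holds %d balls, capacity %d",
                 over[1], lens[over[1]], .TOL_CAPACITIES[over[1]]),
         call. = FALSE)
  held <- sort(unlist(state$stacks, use.names = FALSE))
  if (length(held) != length(state$balls) || !identical(held, state$balls))
    stop(sprintf("invalid state: balls on board (%s) are not the expected set (%s)",
                 paste(held, collapse = ","),
                 paste(state$balls, collapse = ",")), call. = FALSE)
  invisible(state)
}

# Canonical string key; states are equal iff keys are equal.
#' @keywords internal
state_key <- function(state) {
  paste(vapply(state$stacks, paste, "", collapse = ","), collapse = "|")
}

#' @keywords internal
state_from_key <- function(key, balls = .TOL_BALLS) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  length(parts) <- 3L
  stacks <- lapply(parts, function(p)
    if (is.na(p) || !nzchar(p)) character() else strsplit(p, ",", fixed = TRUE)[[1]])
  tol_state(stacks[[1]], stacks[[2]], stacks[[3]], balls = balls)
}

#' @export
print.tol_state <- function(x, ...) {
  cat("S-TOL board state (capacities 3/2/1)\n")
  for (i in 1:3) {
    s <- x$stacks[[i]]
    cat(sprintf("  peg %d: %s\n", i,
                if (length(s)) paste(s, collapse = " < ") else "-"))
  }
  invisible(x)
}

#' @export
`==.tol_state` <- function(e1, e2) state_key(e1) == state_key(e2)

#' Legal moves from a board state
#'
#' A move takes the topmost ball of a non-empty source peg to a destination
#' peg that is strictly below its capacity; only one ball moves at a time.
#'
#' @param state A `tol_state`.
#' @return A data frame with columns `from` and `to`, ordered by ascending
#'   `from` then `to`.
#' @examples
#' legal_moves(tol_state(c("red", "green", "blue")))
#' @export
legal_moves <- function(state) {
  validate_tol_state(state)
  lens <- lengths(state$stacks)
  from <- integer(); to <- integer()
  for (i in 1:3) {
    if (lens[i] == 0L) next
    for (j in 1:3) {
      if (j == i) next
      if (lens[j] < .TOL_CAPACITIES[j]) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  data.frame(from = from, to = to)
}

#' Apply a move to a board state
#'
#' @param state A `tol_state`.
#' @param move A length-2 integer vector `c(from, to)` or a one-row data
#'   frame with columns `from` and `to`.
#' @return The resulting `tol_state`; the input is not modified.
#' @examples
#' apply_move(tol_state(c("red", "green", "blue")), c(1, 3))
#' @export
apply_move <- function(state, move) {
  validate_tol_state(state)
  if (is.data.frame(move)) move <- c(move$from[1], move$to[1])
  move <- as.integer(move)
  if (length(move) != 2L || anyNA(move) || any(move < 1L | move > 3L) ||
      move[1] == move[2])
    stop("move must be two distinct peg indices in 1..3", call. = FALSE)
  from <- move[1]; to <- move[2]
  if (length(state$stacks[[from]]) == 0L)
    stop(sprintf("illegal move %d->%d: source peg %d is empty", from, to, from),
         call. = FALSE)
  if (length(state$stacks[[to]]) >= .TOL_CAPACITIES[to])
    stop(sprintf("illegal move %d->%d: destination peg %d is full", from, to, to),
         call. = FALSE)
  stacks <- state$stacks
  ball <- stacks[[from]][length(stacks[[from]])]
  stacks[[from]] <- stacks[[from]][-length(stacks[[from]])]
  stacks[[to]] <- c(stacks[[to]], ball)
  tol_state(stacks[[1]], stacks[[2]], stacks[[3]], balls = state$balls)
}

#' Enumerate all valid board states
#'
#' Generates every configuration of the three distinct balls on pegs of
#' capacity 3, 2 and 1. There are 36 such states: six feasible occupancy
#' patterns times the 3! orderings of the balls.
#'
#' @param balls Ball labels (three distinct strings).
#' @return A list of `tol_state` objects, each state exactly once, in a
#'   deterministic order.
#' @export
enumerate_states <- function(balls = .TOL_BALLS) {
  balls <- sort(balls)
  stopifnot(length(balls) == 3L, !anyDuplicated(balls))
  occ <- expand.grid(n1 = 0:3, n2 = 0:2, n3 = 0:1)
  occ <- occ[rowSums(occ) == 3L, , drop = FALSE]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (r in seq_len(nrow(occ))) {
    n <- as.integer(occ[r, ])
    for (p in perms) {
      seqb <- balls[p]
      out[[length(out) + 1L]] <- tol_state(
        seqb[seq_len(n[1])],
        if (n[2]) seqb[n[1] + seq_len(n[2])] else character(),
        if (n[3]) seqb[n[1] + n[2] + seq_len(n[3])] else character(),
        balls = balls)
    }
  }
  keys <- vapply(out, state_key, "")
  o <- order(keys)
  out <- out[o]
  out[!duplicated(keys[o])]
}
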