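# S-TOL task design: problem banks, the timed block schedule, behavioral
# scoring. Timing constants follow the task: 7-s study + 3-s response per
# trial, six trials per 60-s block, 30-s rests, twelve blocks alternating
# MM/ZM starting with MM.

.STOL_STUDY_S <- 7
.STOL_RESPONSE_S <- 3
.STOL_TRIALS_PER_BLOCK <- 6L
.STOL_BLOCKS_PER_COND <- 6L
.STOL_REST_S <- 30
.STOL_DT <- 0.5

# evaluate expr under a temporary seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# classified table of all 36 x 36 ordered state pairs (cached)
#' @keywords internal
.problem_table <- function(balls = .TOL_BALLS) {
  key <- paste("ptab", paste(sort(balls), collapse = ","))
  if (!is.null(.tol_cache[[key]])) return(.tol_cache[[key]])
  g <- .tol_graph(balls)
  n <- length(g$states)
  pairs <- expand.grid(start = seq_len(n), goal = seq_len(n))
  pairs$min_moves <- g$dist[cbind(pairs$start, pairs$goal)]
  pairs$n_optimal_paths <- NA_integer_
  pairs$requires_intermediate <- NA
  for (r in seq_len(nrow(pairs))) {
    s <- g$states[[pairs$start[r]]]; t <- g$states[[pairs$goal[r]]]
    if (pairs$min_moves[r] <= 4L) {
      pairs$n_optimal_paths[r] <- count_optimal_paths(s, t)
      pairs$requires_intermediate[r] <- requires_intermediate(s, t)
    }
  }
  .tol_cache[[key]] <- pairs
  pairs
}

#' Generate an S-TOL problem bank
#'
#' Samples problems from the 36-state space: two-move problems (answer
#' "yes"), three-move problems (answer "no"; both search-depth variants are
#' included when available) and zero-move problems (identical boards,
#' answer "no"). Problems are drawn without replacement until a pool is
#' exhausted, then recycled.
#'
#' @param seed Integer seed; the bank is deterministic given the seed.
#' @param n_two_move,n_three_move,n_zero_move Requested problem counts.
#' @param require_unambiguous If `TRUE` (the task's design), all
#'   multiple-move problems have exactly one optimal move ordering.
#' @param balance_depth If `TRUE`, three-move problems are split as evenly
#'   as possible between those requiring and not requiring an intermediate
#'   move.
#' @return A list of `tol_problem` objects, attributes `seed` and `counts`.
#' @export
generate_problem_bank <- function(seed = 1L, n_two_move = 18L,
                                  n_three_move = 18L, n_zero_move = 36L,
                                  require_unambiguous = TRUE,
                                  balance_depth = TRUE) {
  stopifnot(n_two_move >= 0, n_three_move >= 0, n_zero_move >= 0)
  tab <- .problem_table()
  g <- .tol_graph(.TOL_BALLS)
  pool <- function(rows, n) {
    if (nrow(rows) == 0L)
      stop("unsatisfiable constraints: no problems in the requested class",
           call. = FALSE)
    ix <- sample(nrow(rows))
    if (n > length(ix)) ix <- rep(ix, length.out = n) else ix <- ix[seq_len(n)]
    rows[ix, , drop = FALSE]
  }
  with_seed(seed, {
    two <- tab[tab$min_moves == 2L &
                 (!require_unambiguous | tab$n_optimal_paths == 1L), ]
    three <- tab[tab$min_moves == 3L &
                   (!require_unambiguous | tab$n_optimal_paths == 1L), ]
    zero <- tab[tab$min_moves == 0L, ]
    sel <- pool(two, n_two_move)
    if (balance_depth && n_three_move > 0L) {
      t_int <- three[three$requires_intermediate, ]
      t_dir <- three[!three$requires_intermediate, ]
      if (nrow(t_int) && nrow(t_dir)) {
        n_int <- ceiling(n_three_move / 2)
        sel3 <- rbind(pool(t_int, n_int), pool(t_dir, n_three_move - n_int))
        sel3 <- sel3[sample(nrow(sel3)), , drop = FALSE]
      } else sel3 <- pool(three, n_three_move)
    } else sel3 <- pool(three, n_three_move)
    sel <- rbind(sel, sel3, pool(zero, n_zero_move))
  })
  bank <- lapply(seq_len(nrow(sel)), function(r)
    problem_spec(g$states[[sel$start[r]]], g$states[[sel$goal[r]]]))
  structure(bank, seed = seed,
            counts = c(two = n_two_move, three = n_three_move,
                       zero = n_zero_move))
}

#' Build the timed S-TOL session schedule
#'
#' Twelve 60-s blocks of six 10-s trials, alternating multiple-move (MM)
#' and zero-move (ZM) blocks starting with MM, separated by 30-s rests.
#' MM blocks mix two- and three-move problems (default 3 + 3 per block).
#'
#' @param bank A problem bank from [generate_problem_bank()]. Must supply
#'   at least the trials' worth of each class unless `reuse = TRUE`.
#' @param seed Integer seed governing problem-to-trial assignment.
#' @param mm2_per_block Number of two-move trials per MM block (0..6).
#' @param reuse Recycle problems if the bank is short.
#' @return An object of class `stol_schedule` with components `blocks`,
#'   `trials` and `markers` (onset/duration/label data frames; times in
#'   seconds, exact multiples of the 0.5-s sampling interval).
#' @export
build_schedule <- function(bank, seed = 1L, mm2_per_block = 3L,
                           reuse = FALSE) {
  stopifnot(mm2_per_block >= 0, mm2_per_block <= .STOL_TRIALS_PER_BLOCK)
  mm <- vapply(bank, function(p) p$min_moves, integer(1))
  i2 <- which(mm == 2L); i3 <- which(mm == 3L); i0 <- which(mm == 0L)
  n2 <- .STOL_BLOCKS_PER_COND * mm2_per_block
  n3 <- .STOL_BLOCKS_PER_COND * (.STOL_TRIALS_PER_BLOCK - mm2_per_block)
  n0 <- .STOL_BLOCKS_PER_COND * .STOL_TRIALS_PER_BLOCK
  need <- c(two = n2, three = n3, zero = n0)
  have <- c(two = length(i2), three = length(i3), zero = length(i0))
  if (any(have < need) && !reuse)
    stop(sprintf(
      "insufficient bank: need %d/%d/%d two/three/zero-move problems, have %d/%d/%d (set reuse = TRUE to recycle)",
      n2, n3, n0, have[1], have[2], have[3]), call. = FALSE)
  draw <- function(ix, n) {
    ix <- sample(ix)
    if (n > length(ix)) rep(ix, length.out = n) else ix[seq_len(n)]
  }
  trial_dur <- .STOL_STUDY_S + .STOL_RESPONSE_S
  block_dur <- .STOL_TRIALS_PER_BLOCK * trial_dur
  n_blocks <- 2L * .STOL_BLOCKS_PER_COND
  with_seed(seed, {
    p2 <- draw(i2, n2); p3 <- draw(i3, n3); p0 <- draw(i0, n0)
    blocks <- data.frame(
      block = seq_len(n_blocks),
      condition = rep(c("MM", "ZM"), .STOL_BLOCKS_PER_COND),
      onset = (seq_len(n_blocks) - 1L) * (block_dur + .STOL_REST_S),
      duration = block_dur)
    trials <- NULL
    k2 <- k3 <- k0 <- 0L
    for (b in seq_len(n_blocks)) {
      if (blocks$condition[b] == "MM") {
        pid <- c(p2[k2 + seq_len(mm2_per_block)],
                 p3[k3 + seq_len(.STOL_TRIALS_PER_BLOCK - mm2_per_block)])
        k2 <- k2 + mm2_per_block
        k3 <- k3 + .STOL_TRIALS_PER_BLOCK - mm2_per_block
        pid <- sample(pid)
      } else {
        pid <- p0[k0 + seq_len(.STOL_TRIALS_PER_BLOCK)]
        k0 <- k0 + .STOL_TRIALS_PER_BLOCK
      }
      tt <- vapply(pid, function(i) switch(as.character(bank[[i]]$min_moves),
                                           "0" = "ZM", "2" = "MM2", "3" = "MM3"), "")
      trials <- rbind(trials, data.frame(
        block = b,
        trial = seq_len(.STOL_TRIALS_PER_BLOCK),
        onset = blocks$onset[b] + (seq_len(.STOL_TRIALS_PER_BLOCK) - 1L) * trial_dur,
        trial_type = tt,
        problem = pid,
        correct_answer = vapply(pid, function(i) bank[[i]]$correct_answer, "")))
    }
  })
  trials$trial_index <- seq_len(nrow(trials))
  markers <- data.frame(
    onset = blocks$onset, duration = blocks$duration,
    label = paste0("block_", blocks$condition))
  rests <- data.frame(onset = blocks$onset[-n_blocks] + block_dur,
                      duration = .STOL_REST_S, label = "rest")
  markers <- rbind(markers, rests)
  markers <- markers[order(markers$onset), ]
  rownames(markers) <- NULL
  structure(list(blocks = blocks, trials = trials, markers = markers,
                 bank = bank, seed = seed,
                 session_length = blocks$onset[n_blocks] + block_dur),
            class = "stol_schedule")
}

#' @export
print.stol_schedule <- function(x, ...) {
  cat(sprintf("S-TOL session schedule: %d blocks (%s), %d trials, %.0f s total\n",
              nrow(x$blocks), paste(rle(x$blocks$condition)$values[1:2], collapse = "/"),
              nrow(x$trials), x$session_length))
  cat(sprintf("  block length %.0f s, rests %.0f s, first block %s\n",
              x$blocks$duration[1], .STOL_REST_S, x$blocks$condition[1]))
  invisible(x)
}

#' Write event markers as a BIDS-events-style TSV
#'
#' Columns `onset`, `duration`, `label`; times in seconds with 3-decimal
#' precision.
#'
#' @param x An `stol_schedule` or a marker data frame.
#' @param path Output path.
#' @export
write_markers <- function(x, path) {
  m <- if (inherits(x, "stol_schedule")) x$markers else x
  stopifnot(all(c("onset", "duration", "label") %in% names(m)))
  out <- data.frame(onset = sprintf("%.3f", m$onset),
                    duration = sprintf("%.3f", m$duration),
                    label = m$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker TSV written by [write_markers()]
#' @param path File path.
#' @return Data frame with numeric `onset`, `duration` and `label`.
#' @export
read_markers <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$onset <- as.numeric(m$onset)
  m$duration <- as.numeric(m$duration)
  m
}

#' Score S-TOL behavioral records
#'
#' Accuracy per trial type (percent correct; omitted responses count as
#' incorrect) and response-time summaries over correct trials only.
#'
#' @param records Data frame with columns `trial_type`, `correct` (logical)
#'   and `rt_ms`; a `response` column with value `"none"` marks omissions.
#' @return Data frame, one row per trial type: `n`, `accuracy_pct`,
#'   `rt_mean_ms`, `rt_sd_ms`.
#' @export
score_behavior <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no behavioral records to score", call. = FALSE)
  stopifnot(all(c("trial_type", "correct", "rt_ms") %in% names(records)))
  correct <- records$correct
  if ("response" %in% names(records))
    correct <- correct & records$response != "none"
  types <- sort(unique(records$trial_type))
  out <- do.call(rbind, lapply(types, function(tt) {
    sel <- records$trial_type == tt
    ok <- sel & correct
    data.frame(trial_type = tt, n = sum(sel),
               accuracy_pct = 100 * sum(ok) / sum(sel),
               rt_mean_ms = if (any(ok)) mean(records$rt_ms[ok], na.rm = TRUE) else NA_real_,
               rt_sd_ms = if (sum(ok) > 1) stats::sd(records$rt_ms[ok], na.rm = TRUE) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Classify subjects into high/low accuracy groups
#'
#' Applies the 90% criterion to both trial classes: a subject is "high"
#' iff accuracy is at or above the threshold on multiple-move (MM2 + MM3
#' pooled) and on zero-move trials. The threshold is inclusive.
#'
#' @param records Behavioral records with a `subject` column.
#' @param threshold Percent-correct criterion (default 90).
#' @return Data frame: `subject`, `acc_mm`, `acc_zm`, `group`.
#' @export
classify_accuracy_group <- function(records, threshold = 90) {
  stopifnot("subject" %in% names(records))
  correct <- records$correct
  if ("response" %in% names(records))
    correct <- correct & records$response != "none"
  is_mm <- records$trial_type %in% c("MM2", "MM3", "MM")
  is_zm <- records$trial_type == "ZM"
  subs <- sort(unique(records$subject))
  out <- do.call(rbind, lapply(subs, function(s) {
    sel <- records$subject == s
    if (!any(sel & is_mm) || !any(sel & is_zm))
      stop(sprintf("subject %s lacks MM or ZM trials", s), call. = FALSE)
    amm <- 100 * sum(sel & is_mm & correct) / sum(sel & is_mm)
    azm <- 100 * sum(sel & is_zm & correct) / sum(sel & is_zm)
    data.frame(subject = s, acc_mm = amm, acc_zm = azm,
               group = if (amm >= threshold && azm >= threshold) "high" else "low")
  }))
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test on error counts
#'
#' Compares per-subject error counts between multiple-move and zero-move
#' trials with the signed-rank statistic and its tie-corrected normal
#' approximation. Zero differences are dropped (documented convention);
#' `z > 0` indicates more errors on MM than ZM. The effect size is
#' `r = z / sqrt(N)` where the `N` convention is configurable.
#'
#' @param mm_errors,zm_errors Paired numeric vectors (length >= 5).
#' @param r_n `"pairs"` (all pairs, default) or `"nonzero"` (pairs with a
#'   non-zero difference) for the effect-size denominator.
#' @return List with `W` (sum of positive ranks), `z`, `p` (two-sided),
#'   `r`, `n_pairs`, `n_nonzero`.
#' @export
wilcoxon_errors <- function(mm_errors, zm_errors, r_n = c("pairs", "nonzero")) {
  r_n <- match.arg(r_n)
  stopifnot(length(mm_errors) == length(zm_errors))
  if (length(mm_errors) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- mm_errors - zm_errors
  nz <- d != 0
  if (!any(nz))
    stop("degenerate case: all paired differences are zero", call. = FALSE)
  d <- d[nz]
  m <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(rk)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  N <- if (r_n == "pairs") length(mm_errors) else m
  list(W = W, z = z, p = p, r = z / sqrt(N),
       n_pairs = length(mm_errors), n_nonzero = m)
}

#' Write behavioral records as TSV
#' @param records Data frame of behavioral records.
#' @param path Output path.
#' @export
write_behavior <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read behavioral records written by [write_behavior()]
#' @param path File path.
#' @export
read_behavior <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
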