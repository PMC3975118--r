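# Problem banks, block schedule, behavioral scoring.

test_that("problem banks honor counts, answers and the ambiguity constraint", {
  bank <- generate_problem_bank(seed = 3)
  mm <- vapply(bank, function(p) p$min_moves, integer(1))
  expect_identical(as.integer(table(mm)[c("0", "2", "3")]), c(36L, 18L, 18L))
  # zero-move problems: identical boards, answer "no"
  for (p in bank[mm == 0L]) {
    expect_true(p$start == p$goal)
    expect_identical(p$correct_answer, "no")
  }
  # two-move problems answer "yes" and re-solve to 2
  for (p in bank[mm == 2L]) {
    expect_identical(p$correct_answer, "yes")
    expect_identical(min_moves(p$start, p$goal), 2L)
  }
  # unambiguous goal hierarchy on all MM problems
  expect_true(all(vapply(bank[mm > 0L], function(p) p$n_optimal_paths,
                         integer(1)) == 1L))
  # both search-depth variants among three-move problems
  ri <- vapply(bank[mm == 3L], function(p) p$requires_intermediate, logical(1))
  expect_true(any(ri) && any(!ri))
})

test_that("banks are deterministic under a seed and vary across seeds", {
  b1 <- generate_problem_bank(seed = 12)
  b2 <- generate_problem_bank(seed = 12)
  b3 <- generate_problem_bank(seed = 13)
  key <- function(b) vapply(b, function(p)
    paste(stolfnirs:::state_key(p$start), stolfnirs:::state_key(p$goal)), "")
  expect_identical(key(b1), key(b2))
  expect_false(identical(key(b1), key(b3)))
})

test_that("schedule satisfies the block-design invariants", {
  bank <- generate_problem_bank(seed = 4)
  sch <- build_schedule(bank, seed = 4)
  expect_identical(nrow(sch$blocks), 12L)
  expect_identical(sch$blocks$condition, rep(c("MM", "ZM"), 6))
  expect_true(all(sch$blocks$duration == 60))
  expect_identical(sch$session_length, 11 * 90 + 60)
  # 36 MM trials, 36 ZM trials; 6 per block
  expect_identical(sum(sch$trials$trial_type %in% c("MM2", "MM3")), 36L)
  expect_identical(sum(sch$trials$trial_type == "ZM"), 36L)
  expect_true(all(table(sch$trials$block) == 6L))
  # trial onsets tile each block in 10-s steps
  for (b in c(1, 7, 12)) {
    tt <- sch$trials[sch$trials$block == b, ]
    expect_equal(tt$onset, sch$blocks$onset[b] + 10 * (0:5))
  }
  # marker times are exact multiples of the 500-ms sampling interval
  expect_true(all(abs(sch$markers$onset * 2 -
                        round(sch$markers$onset * 2)) < 1e-12))
  # rests of 30 s separate consecutive blocks
  rests <- sch$markers[sch$markers$label == "rest", ]
  expect_identical(nrow(rests), 11L)
  expect_true(all(rests$duration == 30))
  # stored answers re-derive from the solver (bank self-consistency)
  for (r in seq_len(nrow(sch$trials))) {
    p <- bank[[sch$trials$problem[r]]]
    expect_identical(sch$trials$correct_answer[r],
                     if (min_moves(p$start, p$goal) == 2L) "yes" else "no")
  }
})

test_that("insufficient banks are rejected unless reuse is allowed", {
  small <- generate_problem_bank(seed = 1, n_two_move = 2, n_three_move = 2,
                                 n_zero_move = 2)
  expect_error(build_schedule(small, seed = 1), "insufficient bank")
  sch <- build_schedule(small, seed = 1, reuse = TRUE)
  expect_identical(nrow(sch$trials), 72L)
})

test_that("marker files round-trip exactly", {
  sch <- build_schedule(generate_problem_bank(seed = 2), seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_markers(sch, f)
  m <- read_markers(f)
  expect_equal(m$onset, sch$markers$onset)
  expect_equal(m$duration, sch$markers$duration)
  expect_identical(m$label, sch$markers$label)
})

test_that("behavior scoring: accuracy, omissions, RT over correct trials", {
  rec <- data.frame(
    trial_type = rep(c("MM2", "ZM"), each = 5),
    response = c(rep("yes", 4), "none", rep("no", 5)),
    rt_ms = c(900, 950, 850, 880, NA, 500, 520, 480, 510, 490),
    correct = c(rep(TRUE, 4), TRUE, rep(TRUE, 5)))
  s <- score_behavior(rec)
  expect_equal(s$accuracy_pct[s$trial_type == "MM2"], 80)  # omission counts wrong
  expect_equal(s$accuracy_pct[s$trial_type == "ZM"], 100)
  expect_equal(s$rt_mean_ms[s$trial_type == "MM2"], mean(c(900, 950, 850, 880)))
  # 9 of 10 correct -> 90%
  rec2 <- data.frame(trial_type = "ZM", response = "no",
                     rt_ms = 500, correct = c(rep(TRUE, 9), FALSE))
  expect_equal(score_behavior(rec2)$accuracy_pct, 90)
  expect_error(score_behavior(rec2[0, ]), "no behavioral records")
})

test_that("synthetic cohorts recover configured accuracy within binomial error", {
  cfg <- generator_config(n_subjects = 38, seed = 6)
  coh <- simulate_cohort(cfg, channels = integer(0))
  s <- score_behavior(coh$behavior)
  for (tt in c("MM2", "MM3", "ZM")) {
    # omissions (1%) count as errors, so expected accuracy is 0.99 * p
    p_cfg <- 0.99 * cfg$accuracy[[tt]]
    n <- s$n[s$trial_type == tt]
    se <- sqrt(p_cfg * (1 - p_cfg) / n)
    expect_lt(abs(s$accuracy_pct[s$trial_type == tt] / 100 - p_cfg), 4 * se)
  }
})

test_that("accuracy grouping applies the inclusive 90% criterion to both types", {
  mk <- function(subject, acc_mm, acc_zm) {
    data.frame(subject = subject,
               trial_type = rep(c("MM2", "ZM"), each = 20),
               response = "x",
               rt_ms = 500,
               correct = c(rep(TRUE, round(20 * acc_mm)),
                           rep(FALSE, 20 - round(20 * acc_mm)),
                           rep(TRUE, round(20 * acc_zm)),
                           rep(FALSE, 20 - round(20 * acc_zm))))
  }
  rec <- rbind(mk("a", 1, 1), mk("b", 0.80, 0.95), mk("c", 0.90, 0.90))
  rec$response <- "yes"  # no omissions
  g <- classify_accuracy_group(rec)
  expect_identical(g$group, c("high", "low", "high"))  # boundary is inclusive
})

test_that("wilcoxon signed-rank matches exact enumeration and behaves on null", {
  mm <- c(4, 2, 5, 1, 3, 6, 2, 0, 4, 1)
  zm <- c(1, 0, 2, 1, 1, 2, 3, 0, 1, 0)
  w <- wilcoxon_errors(mm, zm)
  o <- oracle_wilcoxon(mm, zm)
  expect_equal(w$W, o$W)
  expect_lt(abs(w$p - o$p_exact), 0.03)  # normal approx near exact p
  expect_gt(w$z, 0)
  # r conventions
  expect_equal(wilcoxon_errors(mm, zm, r_n = "pairs")$r, w$z / sqrt(10))
  expect_equal(wilcoxon_errors(mm, zm, r_n = "nonzero")$r,
               w$z / sqrt(w$n_nonzero))
  # degenerate all-zero differences
  expect_error(wilcoxon_errors(1:6, 1:6), "degenerate")
  expect_error(wilcoxon_errors(1:4, 2:5), "at least 5")
})

test_that("a 38-subject cohort with more MM than ZM errors gives z > 0, p < .05", {
  cfg <- generator_config(n_subjects = 38, seed = 8)
  coh <- simulate_cohort(cfg, channels = integer(0))
  err <- stolfnirs:::.per_subject_errors(coh$behavior)
  w <- wilcoxon_errors(err$mm, err$zm)
  expect_gt(w$z, 0)
  expect_lt(w$p, 0.05)
})
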