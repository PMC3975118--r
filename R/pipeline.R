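# End-to-end orchestration: simulate (or ingest) -> preprocess -> analyze
# -> report. The run configuration is a validated list (optionally read
# from YAML); outputs are TSV/JSON/PNG in a run directory.

.RUN_CONFIG_KEYS <- c("n_subjects", "preset", "seed", "icc", "white_sd",
                      "pink_sd", "artifact_rate", "artifact_amp",
                      "fdr_alpha", "roi", "group_split", "moderation",
                      "ar1", "output", "accuracy_threshold", "channels")

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected. Keys not supplied fall back to the
#' generator/analysis defaults.
#'
#' @param ... Named overrides among: `n_subjects`, `preset`, `seed`,
#'   `icc`, `white_sd`, `pink_sd`, `artifact_rate`, `artifact_amp`,
#'   `fdr_alpha`, `roi`, `group_split`, `moderation`, `ar1`, `output`,
#'   `accuracy_threshold`, `channels`.
#' @param file Optional YAML file of the same keys (overridden by `...`).
#' @return A named list of class `stol_run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list()
  if (!is.null(file)) cfg <- yaml::read_yaml(file)
  dots <- list(...)
  cfg[names(dots)] <- dots
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(n_subjects = 38L, preset = "table4", seed = 1L,
                   icc = 0.15, fdr_alpha = 0.05, roi = 1:4,
                   group_split = FALSE, moderation = TRUE, ar1 = FALSE,
                   output = "hb", accuracy_threshold = 90,
                   channels = 1:16)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "stol_run_config")
}

#' Preprocess a synthetic cohort into model-ready long data
#'
#' Per subject: convert raw intensities to hemoglobin if needed, screen
#' channels, low-pass filter the oxy-Hb series, reject motion windows, and
#' segment blocks with local baselines. Exclusions are logged on the
#' result.
#'
#' @param cohort An `stol_cohort`.
#' @param motion Apply sliding-window motion rejection (default TRUE).
#' @param screen Apply channel screening (raw input only).
#' @param ... Passed to [reject_motion_windows()].
#' @return An `stol_segmented` long data frame for all subjects, with an
#'   `exclusions` attribute (list of per-subject logs).
#' @export
preprocess_cohort <- function(cohort, motion = TRUE, screen = TRUE, ...) {
  stopifnot(inherits(cohort, "stol_cohort"))
  logs <- list()
  segs <- lapply(cohort$subjects, function(su) {
    if (!is.null(su$raw)) {
      keep <- su$channels
      if (screen) {
        q <- screen_channels(su$raw)
        keep <- intersect(keep, q$channel[q$included])
        logs[[su$subject]] <<- list(screened_out = setdiff(su$channels, keep))
      }
      hb <- intensities_to_hb(su$raw)
    } else {
      hb <- su$hb
      keep <- su$channels
    }
    mask <- NULL
    if (motion) {
      # detect artifacts on the unfiltered series: the 0.1-Hz low-pass
      # smears spikes below the jump detector's reach
      mask <- matrix(FALSE, nrow(hb$oxy), ncol(hb$oxy))
      for (j in seq_len(ncol(hb$oxy)))
        mask[, j] <- reject_motion_windows(hb$oxy[, j], ...)
      logs[[su$subject]]$masked_samples <<- colSums(mask)
    }
    hb$oxy <- lowpass_filter(hb$oxy)
    seg <- segment_blocks(hb, mask = mask,
                          channels = match(keep, su$channels))
    # segment_blocks records column indices; map back to true channel ids
    seg$channel <- su$channels[seg$channel]
    seg
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("stol_segmented", "data.frame")
  attr(out, "exclusions") <- logs
  out
}

#' Run the full S-TOL pipeline
#'
#' Problems -> schedule -> simulate -> preprocess -> channel-wise contrast
#' (with FDR), behavioral scoring, the 90%-criterion accuracy split
#' (optionally with separate channel tables per group), and the
#' deliberation moderation model. When `out_dir` is given, writes results
#' tables (TSV), a machine-readable JSON summary, the channel-grid heatmap
#' (PNG) and the resolved configuration; reruns with the same
#' configuration produce byte-identical JSON.
#'
#' @param config An `stol_run_config` (see [run_config()]).
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `stol_run`: `channelwise`, `behavior_summary`,
#'   `wilcoxon`, `accuracy_groups`, `moderation`, `icc`, optional
#'   `group_tables`, plus the cohort and segmented data.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "stol_run_config")) config <- do.call(run_config, config)
  gen_args <- list(n_subjects = config$n_subjects, preset = config$preset,
                   seed = config$seed, icc = config$icc, roi = config$roi)
  for (k in c("white_sd", "pink_sd", "artifact_rate", "artifact_amp"))
    if (!is.null(config[[k]])) gen_args[[k]] <- config[[k]]
  gen <- do.call(generator_config, gen_args)
  cohort <- simulate_cohort(gen, output = config$output,
                            channels = config$channels)
  seg <- preprocess_cohort(cohort)
  model_rows <- seg
  cw <- channelwise_analysis(model_rows, alpha = config$fdr_alpha,
                             ar1 = config$ar1, with_icc = TRUE)
  beh <- score_behavior(cohort$behavior)
  groups <- classify_accuracy_group(cohort$behavior,
                                    threshold = config$accuracy_threshold)
  err <- .per_subject_errors(cohort$behavior)
  wx <- tryCatch(wilcoxon_errors(err$mm, err$zm), error = function(e)
    list(W = NA, z = NA, p = NA, r = NA, error = conditionMessage(e)))
  res <- list(config = config, cohort = cohort, segmented = seg,
              channelwise = cw, behavior_summary = beh,
              accuracy_groups = groups, wilcoxon = wx)
  if (isTRUE(config$group_split)) {
    hi <- groups$subject[groups$group == "high"]
    res$group_tables <- list(
      high = if (length(unique(model_rows$subject[model_rows$subject %in% hi])) >= 2)
        channelwise_analysis(model_rows[model_rows$subject %in% hi, ],
                             alpha = config$fdr_alpha) else NULL,
      low = if (length(unique(model_rows$subject[!model_rows$subject %in% hi])) >= 2)
        channelwise_analysis(model_rows[!model_rows$subject %in% hi, ],
                             alpha = config$fdr_alpha) else NULL)
  }
  if (isTRUE(config$moderation)) {
    res$moderation <- tryCatch(
      fit_moderation(model_rows, cohort$traits, roi = config$roi),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stol_moderation_error"))
  }
  class(res) <- "stol_run"
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

#' @keywords internal
.per_subject_errors <- function(behavior) {
  correct <- behavior$correct & behavior$response != "none"
  is_mm <- behavior$trial_type %in% c("MM2", "MM3")
  subs <- sort(unique(behavior$subject))
  list(subjects = subs,
       mm = vapply(subs, function(s)
         sum(behavior$subject == s & is_mm & !correct), numeric(1)),
       zm = vapply(subs, function(s)
         sum(behavior$subject == s & !is_mm & !correct), numeric(1)))
}

#' @keywords internal
.write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(as.data.frame(res$channelwise), p("channelwise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$behavior_summary, p("behavior_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$accuracy_groups, p("accuracy_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cw <- as.data.frame(res$channelwise)
  summ <- list(
    seed = res$config$seed, preset = res$config$preset,
    n_subjects = res$config$n_subjects,
    channels = cw$channel,
    b = cw$b, t = cw$t, p_fdr = cw$p_fdr, label = cw$label,
    icc = cw$icc,
    behavior = res$behavior_summary,
    wilcoxon = res$wilcoxon[c("W", "z", "p", "r")],
    n_high_accuracy = sum(res$accuracy_groups$group == "high"))
  if (!is.null(res$moderation) && inherits(res$moderation, "stol_moderation")) {
    summ$moderation <- list(
      interaction_b = res$moderation$coefficients$b[4],
      interaction_t = res$moderation$coefficients$t[4],
      slope_low = res$moderation$slopes$slope[1],
      slope_low_p = res$moderation$slopes$p[1],
      slope_high = res$moderation$slopes$slope[2],
      slope_high_p = res$moderation$slopes$p[2])
    utils::write.table(res$moderation$slopes, p("moderation_slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(res$config), p("config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  grDevices::png(p("channel_grid.png"), width = 480, height = 480)
  plot(res$channelwise)
  grDevices::dev.off()
  invisible(out_dir)
}

#' @export
print.stol_run <- function(x, ...) {
  cat("S-TOL pipeline run\n==================\n")
  print(x$channelwise)
  cat("\nbehavior:\n")
  print(x$behavior_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$wilcoxon$z) && !is.na(x$wilcoxon$z))
    cat(sprintf("\nMM vs ZM errors (Wilcoxon): z = %.2f, p = %.2g, r = %.2f\n",
                x$wilcoxon$z, x$wilcoxon$p, x$wilcoxon$r))
  cat(sprintf("high-accuracy subjects (>= %g%% both types): %d of %d\n",
              x$config$accuracy_threshold,
              sum(x$accuracy_groups$group == "high"),
              nrow(x$accuracy_groups)))
  if (inherits(x$moderation, "stol_moderation")) {
    cat("\n"); print(x$moderation)
  }
  invisible(x)
}
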