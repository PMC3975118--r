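# Raw two-wavelength intensities -> oxy-hemoglobin, filtering, quality
# screening, motion-window rejection and block segmentation with local
# (first-10-s) baselines.

.STOL_FS <- 2            # Hz; 500-ms sampling
.STOL_N_CHANNELS <- 16L
.STOL_BASELINE_S <- 10   # local baseline window per block

#' Default extinction coefficients at 730 and 850 nm
#'
#' Molar extinction coefficients for oxy- and deoxy-hemoglobin in
#' 1/(mM cm), from standard published compilations of hemoglobin spectra.
#' Exposed so the conversion constants are fully configurable.
#'
#' @return A 2x2 matrix; rows = wavelengths (730, 850 nm), columns =
#'   chromophores (`oxy`, `deoxy`).
#' @export
extinction_coefficients <- function() {
  matrix(c(0.390, 1.1022,
           1.058, 0.69132),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("730", "850"), c("oxy", "deoxy")))
}

#' Construct a raw fNIRS recording
#'
#' @param subject Subject identifier.
#' @param i730,i850 Numeric matrices, time x channel, of raw light
#'   intensities at 730 and 850 nm.
#' @param markers Marker data frame (`onset`, `duration`, `label`).
#' @param fs Sampling rate in Hz (0.5-s interval by default).
#' @return An object of class `stol_raw`.
#' @export
stol_raw <- function(subject, i730, i850, markers = NULL, fs = .STOL_FS) {
  i730 <- as.matrix(i730); i850 <- as.matrix(i850)
  if (!identical(dim(i730), dim(i850)))
    stop("intensity matrices differ in shape", call. = FALSE)
  if (!is.null(markers)) {
    span <- nrow(i730) / fs
    if (any(markers$onset + markers$duration > span + 1e-9))
      stop("markers extend beyond the recording span", call. = FALSE)
  }
  structure(list(subject = subject, i730 = i730, i850 = i850,
                 markers = markers, fs = fs,
                 time = (seq_len(nrow(i730)) - 1) / fs),
            class = "stol_raw")
}

#' @export
print.stol_raw <- function(x, ...) {
  cat(sprintf("raw fNIRS recording: subject %s, %d channels, %d samples (%.1f s at %g Hz)\n",
              x$subject, ncol(x$i730), nrow(x$i730), nrow(x$i730) / x$fs, x$fs))
  invisible(x)
}

#' Convert raw intensities to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law: optical density change
#' `dOD(lambda, t) = -log10(I(t) / mean(I_ref))` per wavelength, then the
#' 2x2 extinction system is inverted and scaled by the effective pathlength
#' (source-detector distance times differential pathlength factor) to give
#' oxy- and deoxy-hemoglobin changes in micromolar units relative to the
#' reference segment. Because the mapping is linear in dOD, the choice of
#' reference segment only shifts each channel by a constant, which cancels
#' under the per-block local-baseline referencing applied downstream.
#'
#' @param raw An `stol_raw` recording with strictly positive intensities in
#'   the reference window.
#' @param reference `"recording"` (default: whole-recording mean) or a
#'   two-element numeric window `c(start_s, end_s)`, half-open.
#' @param coefficients Extinction matrix as from
#'   [extinction_coefficients()].
#' @param distance_cm Source-detector separation (cm).
#' @param dpf Differential pathlength factor (dimensionless).
#' @return An object of class `stol_hb` with matrices `oxy`, `deoxy`,
#'   `total` (micromolar), inheriting time base and markers.
#' @export
intensities_to_hb <- function(raw, reference = "recording",
                              coefficients = extinction_coefficients(),
                              distance_cm = 2.5, dpf = 6) {
  stopifnot(inherits(raw, "stol_raw"))
  if (abs(det(coefficients)) < 1e-8)
    stop("configuration error: extinction matrix is singular", call. = FALSE)
  n <- nrow(raw$i730)
  if (identical(reference, "recording")) {
    ref_idx <- seq_len(n)
  } else {
    stopifnot(is.numeric(reference), length(reference) == 2L)
    ref_idx <- which(raw$time >= reference[1] & raw$time < reference[2])
    if (!length(ref_idx)) stop("empty reference window", call. = FALSE)
  }
  for (w in c("i730", "i850")) {
    bad <- which(raw[[w]][ref_idx, , drop = FALSE] <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive intensity at %s, channel %d, sample %d",
                   sub("i", "", w), bad[1, 2], ref_idx[bad[1, 1]]),
           call. = FALSE)
  }
  ref730 <- colMeans(raw$i730[ref_idx, , drop = FALSE])
  ref850 <- colMeans(raw$i850[ref_idx, , drop = FALSE])
  od730 <- -log10(sweep(raw$i730, 2, ref730, "/"))
  od850 <- -log10(sweep(raw$i850, 2, ref850, "/"))
  inv <- solve(coefficients) / (distance_cm * dpf)  # -> mM
  oxy <- 1000 * (inv["oxy", "730"] * od730 + inv["oxy", "850"] * od850)
  deoxy <- 1000 * (inv["deoxy", "730"] * od730 + inv["deoxy", "850"] * od850)
  structure(list(subject = raw$subject, oxy = oxy, deoxy = deoxy,
                 total = oxy + deoxy, markers = raw$markers, fs = raw$fs,
                 time = raw$time),
            class = "stol_hb")
}

#' @export
print.stol_hb <- function(x, ...) {
  cat(sprintf("hemoglobin series: subject %s, %d channels, %d samples (%.1f s)\n",
              x$subject, ncol(x$oxy), nrow(x$oxy), nrow(x$oxy) / x$fs))
  invisible(x)
}

#' Forward model: hemoglobin changes to raw intensities
#'
#' Inverse of [intensities_to_hb()]: given oxy/deoxy concentration changes
#' (micromolar) it produces the two-wavelength intensities a detector with
#' baseline intensity `i0` would record. Used by the synthetic generator
#' and as a round-trip oracle.
#'
#' @param oxy,deoxy Numeric matrices (time x channel), micromolar.
#' @inheritParams intensities_to_hb
#' @param i0 Baseline intensity per wavelength (length 2: 730, 850 nm).
#' @return List with matrices `i730` and `i850`.
#' @export
hb_to_intensities <- function(oxy, deoxy,
                              coefficients = extinction_coefficients(),
                              distance_cm = 2.5, dpf = 6,
                              i0 = c(1000, 1000)) {
  oxy <- as.matrix(oxy) / 1000; deoxy <- as.matrix(deoxy) / 1000  # mM
  L <- distance_cm * dpf
  od730 <- L * (coefficients["730", "oxy"] * oxy + coefficients["730", "deoxy"] * deoxy)
  od850 <- L * (coefficients["850", "oxy"] * oxy + coefficients["850", "deoxy"] * deoxy)
  list(i730 = i0[1] * 10^(-od730), i850 = i0[2] * 10^(-od850))
}

#' Low-pass FIR filter coefficients
#'
#' Linear-phase FIR low-pass (Hamming window design), order 20, cutoff
#' 0.1 Hz at 2-Hz sampling by default, matching the physiological-noise
#' filter used for continuous-wave fNIRS. Coefficients are normalized to
#' exact unit DC gain.
#'
#' @param order Filter order (number of taps minus one).
#' @param cutoff Cutoff frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of `order + 1` coefficients.
#' @export
lowpass_coefficients <- function(order = 20, cutoff = 0.1, fs = .STOL_FS) {
  b <- signal::fir1(order, cutoff / (fs / 2), "low")
  as.numeric(b) / sum(b)
}

# single forward FIR pass (convolution), NA-free via caller's padding
#' @keywords internal
.fir_pass <- function(x, b) {
  as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
}

#' Zero-phase low-pass filtering of fNIRS series
#'
#' Applies the linear-phase FIR of [lowpass_coefficients()] forward and
#' backward (zero net phase, so block timing is not shifted; effective
#' magnitude response is the squared design response). Edges are handled by
#' odd reflection padding of three filter lengths, and the output has the
#' input's length. Constant series pass unchanged (unit DC gain).
#'
#' @param x Numeric vector or time-by-channel matrix.
#' @param order,cutoff,fs Filter design parameters; see
#'   [lowpass_coefficients()].
#' @return Filtered object of the same shape as `x`.
#' @export
lowpass_filter <- function(x, order = 20, cutoff = 0.1, fs = .STOL_FS) {
  b <- lowpass_coefficients(order, cutoff, fs)
  vec <- !is.matrix(x)
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  if (n <= length(b))
    stop(sprintf("series too short to filter: %d samples, filter length %d",
                 n, length(b)), call. = FALSE)
  np <- min(3L * length(b), n - 1L)
  top <- 2 * matrix(xm[1, ], np, ncol(xm), byrow = TRUE) -
    xm[1L + rev(seq_len(np)), , drop = FALSE]
  bot <- 2 * matrix(xm[n, ], np, ncol(xm), byrow = TRUE) -
    xm[n - rev(seq_len(np)), , drop = FALSE]
  xp <- rbind(top, xm, bot)
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- stats::filter(y[nrow(y):1, , drop = FALSE], b,
                     method = "convolution", sides = 1)
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[np + seq_len(n), , drop = FALSE]
  out <- matrix(as.numeric(out), n, ncol(xm), dimnames = dimnames(xm))
  if (vec) as.numeric(out) else out
}

#' Screen channels for poor signal quality
#'
#' A channel is excluded if its median raw intensity at either wavelength
#' falls below a floor (very low signal) or above a ceiling (saturation),
#' or if listed for manual exclusion.
#'
#' @param raw An `stol_raw` recording.
#' @param low_signal_floor,saturation_ceiling Thresholds in the intensity
#'   units of the recording.
#' @param manual Integer vector of channels to exclude by hand.
#' @return An object of class `stol_channel_quality`: data frame with
#'   `channel`, `included`, `reason` (`low_signal`, `saturation`, `manual`
#'   or `NA`).
#' @export
screen_channels <- function(raw, low_signal_floor = 10,
                            saturation_ceiling = 4000,
                            manual = integer(0)) {
  stopifnot(inherits(raw, "stol_raw"))
  nc <- ncol(raw$i730)
  med730 <- apply(raw$i730, 2, stats::median)
  med850 <- apply(raw$i850, 2, stats::median)
  reason <- rep(NA_character_, nc)
  reason[med730 > saturation_ceiling | med850 > saturation_ceiling] <- "saturation"
  reason[med730 < low_signal_floor | med850 < low_signal_floor] <- "low_signal"
  reason[seq_len(nc) %in% manual] <- "manual"
  structure(data.frame(channel = seq_len(nc),
                       included = is.na(reason),
                       reason = reason),
            class = c("stol_channel_quality", "data.frame"),
            subject = raw$subject)
}

#' @export
print.stol_channel_quality <- function(x, ...) {
  n_ex <- sum(!x$included)
  cat(sprintf("channel screening: %d/%d excluded", n_ex, nrow(x)))
  if (n_ex) cat(" (", paste(sprintf("%d:%s", x$channel[!x$included],
                                    x$reason[!x$included]), collapse = ", "),
                ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Sliding-window motion artifact rejection
#'
#' Scores sliding windows by their within-window standard deviation (slow
#' shifts, baseline jumps) and largest sample-to-sample jump (spikes),
#' converts both to robust z-scores (median/MAD across windows) and masks
#' every sample belonging to a window exceeding either threshold. Masked
#' samples are meant to be dropped from model input.
#'
#' @param x Numeric vector (one channel's series).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 10).
#' @param step_s Hop between window starts (default half a window).
#' @param spike_z Robust-z threshold on the within-window max jump.
#' @param shift_z Robust-z threshold on the within-window SD.
#' @return Logical vector, `TRUE` where the sample is rejected.
#' @export
reject_motion_windows <- function(x, fs = .STOL_FS, window_s = 10,
                                  step_s = window_s / 2,
                                  spike_z = 5, shift_z = 5) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  if (w > n) stop("window longer than series", call. = FALSE)
  starts <- seq(1L, n - w + 1L, by = max(1L, as.integer(round(step_s * fs))))
  win <- matrix(x[outer(0:(w - 1L), starts, "+")], nrow = w)
  mu <- colMeans(win)
  sds <- sqrt(colSums((win - matrix(mu, w, length(starts), byrow = TRUE))^2) /
                (w - 1))
  jumps <- apply(abs(win[-1L, , drop = FALSE] - win[-w, , drop = FALSE]),
                 2, max)
  rz <- function(v) {
    med <- stats::median(v); s <- stats::mad(v)
    if (s == 0) s <- .Machine$double.eps
    (v - med) / s
  }
  bad <- rz(sds) > shift_z | rz(jumps) > spike_z
  mask <- logical(n)
  for (k in which(bad)) mask[starts[k] + 0:(w - 1L)] <- TRUE
  mask
}

#' Segment hemoglobin series into baseline-referenced block rows
#'
#' Extracts the twelve 60-s activation blocks, subtracts each block's local
#' baseline (mean of its first 10 s, i.e. 20 samples at 500-ms sampling)
#' per channel, attaches the effect code (ZM = -1, MM = +1) and returns
#' long-format rows. Rest periods are excluded; masked samples are dropped.
#'
#' @param hb An `stol_hb` object.
#' @param markers Marker data frame; defaults to `hb$markers`. Block rows
#'   must be labelled `block_MM` / `block_ZM` and alternate starting MM.
#' @param measure Which series to segment (default `"oxy"`).
#' @param mask Optional logical matrix (time x channel) of rejected
#'   samples, as from [reject_motion_windows()] per channel.
#' @param baseline_s Local baseline length in seconds.
#' @param channels Channels to keep (default all).
#' @return Long-format data frame of class `stol_segmented`: `subject`,
#'   `channel`, `block`, `condition`, `code`, `time` (within block), `y`
#'   (baseline-referenced), `baseline` (flag for baseline-window rows).
#'   Block/channel segments whose entire baseline window was rejected are
#'   dropped and listed in the `dropped_blocks` attribute.
#' @export
segment_blocks <- function(hb, markers = hb$markers, measure = "oxy",
                           mask = NULL, baseline_s = .STOL_BASELINE_S,
                           channels = NULL) {
  stopifnot(inherits(hb, "stol_hb"))
  if (is.null(markers)) stop("no markers supplied", call. = FALSE)
  blk <- markers[grepl("^block_", markers$label), , drop = FALSE]
  if (nrow(blk) == 0L) stop("markers contain no block rows", call. = FALSE)
  cond <- sub("block_", "", blk$label)
  if (cond[1] != "MM" || any(cond[-1] == cond[-length(cond)]))
    stop("blocks must alternate MM/ZM starting with MM", call. = FALSE)
  n <- nrow(hb[[measure]])
  fs <- hb$fs
  nb <- as.integer(round(baseline_s * fs))
  if (is.null(channels)) channels <- seq_len(ncol(hb[[measure]]))
  if (!is.null(mask)) stopifnot(nrow(mask) == n)
  # gather per-block index ranges, then build the long table columnwise
  acc_ch <- acc_blk <- acc_t <- acc_y <- acc_base <- acc_code <- list()
  acc_cond <- list()
  k <- 0L
  dropped <- NULL
  for (b in seq_len(nrow(blk))) {
    i0 <- as.integer(round(blk$onset[b] * fs)) + 1L
    len <- as.integer(round(blk$duration[b] * fs))
    if (len < nb)
      stop(sprintf("block %d shorter than the baseline window", b), call. = FALSE)
    if (i0 + len - 1L > n)
      stop(sprintf("block %d extends beyond the series (marker/series mismatch)", b),
           call. = FALSE)
    idx <- i0 + 0:(len - 1L)
    ym <- hb[[measure]][idx, channels, drop = FALSE]
    keepm <- if (is.null(mask)) matrix(TRUE, len, length(channels)) else
      !mask[idx, channels, drop = FALSE]
    basem <- keepm[seq_len(nb), , drop = FALSE]
    for (jj in seq_along(channels)) {
      if (!any(basem[, jj])) {
        dropped <- rbind(dropped,
                         data.frame(block = b, channel = channels[jj]))
        next
      }
      kp <- keepm[, jj]
      yr <- ym[kp, jj] - mean(ym[seq_len(nb), jj][basem[, jj]])
      k <- k + 1L
      acc_ch[[k]] <- rep(channels[jj], sum(kp))
      acc_blk[[k]] <- rep(b, sum(kp))
      acc_cond[[k]] <- rep(cond[b], sum(kp))
      acc_code[[k]] <- rep(if (cond[b] == "MM") 1 else -1, sum(kp))
      acc_t[[k]] <- (idx[kp] - i0) / fs
      acc_y[[k]] <- yr
      acc_base[[k]] <- (idx[kp] - i0) < nb
    }
  }
  out <- data.frame(
    subject = hb$subject,
    channel = unlist(acc_ch), block = unlist(acc_blk),
    condition = unlist(acc_cond), code = unlist(acc_code),
    time = unlist(acc_t), y = unlist(acc_y), baseline = unlist(acc_base))
  class(out) <- c("stol_segmented", "data.frame")
  attr(out, "dropped_blocks") <- dropped
  out
}

#' Write a raw recording as a wide TSV
#'
#' Columns `time`, `ch01_730`, `ch01_850`, ..., one row per sample.
#' @param raw An `stol_raw` object.
#' @param path Output path.
#' @export
write_raw <- function(raw, path) {
  stopifnot(inherits(raw, "stol_raw"))
  nc <- ncol(raw$i730)
  out <- data.frame(time = raw$time)
  for (ch in seq_len(nc)) {
    out[[sprintf("ch%02d_730", ch)]] <- raw$i730[, ch]
    out[[sprintf("ch%02d_850", ch)]] <- raw$i850[, ch]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide raw-recording TSV written by [write_raw()]
#' @param path File path.
#' @param subject Subject id to attach.
#' @param markers Optional marker data frame.
#' @param fs Sampling rate, Hz.
#' @return An `stol_raw` object.
#' @export
read_raw <- function(path, subject = NA_character_, markers = NULL,
                     fs = .STOL_FS) {
  d <- utils::read.delim(path)
  cols730 <- grep("_730$", names(d), value = TRUE)
  cols850 <- grep("_850$", names(d), value = TRUE)
  stol_raw(subject, as.matrix(d[cols730]), as.matrix(d[cols850]),
           markers = markers, fs = fs)
}

#' Write segmented long-format data as TSV
#' @param seg An `stol_segmented` data frame.
#' @param path Output path.
#' @export
write_segmented <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segmented long-format TSV written by [write_segmented()]
#' @param path File path.
#' @export
read_segmented <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("stol_segmented", "data.frame")
  out
}
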