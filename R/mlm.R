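# Channel-wise multilevel contrast of MM vs ZM oxy-Hb, intraclass
# correlation, FDR correction and the deliberation moderation model.

#' @keywords internal
.check_long <- function(data, channel = NULL) {
  need <- c("subject", "y", "code")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("long data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(channel)) {
    if (!"channel" %in% names(data))
      stop("no 'channel' column to subset on", call. = FALSE)
    data <- data[data$channel == channel, , drop = FALSE]
    if (!nrow(data))
      stop(sprintf("no rows for channel %s", channel), call. = FALSE)
  }
  data
}

#' Fit the random-intercept condition contrast for one channel
#'
#' Estimates `y = g0 + g1 * code + u_subject + e` by restricted maximum
#' likelihood, where `code` is the effect code (ZM = -1, MM = +1), so that
#' a two-unit change in the code -- hence `2 * b` -- is the unstandardized
#' MM-minus-ZM mean difference. Degrees of freedom for the condition
#' effect follow the between-within partition (`N - n - 1`); the p-value is
#' two-sided from the t reference distribution.
#'
#' @param data Long-format data with columns `subject`, `y`, `code` (and
#'   `channel` if `channel` is given). Unbalanced rows per subject are
#'   supported; every fitted channel needs both condition levels and at
#'   least two subjects.
#' @param channel Optional channel to subset on.
#' @param ar1 If `TRUE`, adds a within-subject AR(1) residual correlation
#'   (continuous-time order within subject), delegated to [nlme::lme()];
#'   degrees of freedom and p-values still follow the between-within rule.
#' @return An object of class `stol_mlm`: coefficient table (`b`, `SE`,
#'   `df`, `t`, `p`), variance components `sigma_u2` and `sigma_e2`, row
#'   and subject counts. Non-convergence of the AR(1) fit is returned as a
#'   flagged result (`converged = FALSE` with a diagnostic), never
#'   silently.
#' @export
fit_random_intercept <- function(data, channel = NULL, ar1 = FALSE) {
  d <- .check_long(data, channel)
  if (length(unique(d$code)) < 2L)
    stop("channel has a single condition level", call. = FALSE)
  if (length(unique(d$subject)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  X <- cbind("(Intercept)" = 1, code = d$code)
  if (!ar1) {
    f <- .reml_ri(d$y, X, d$subject)
    out <- list(coefficients = data.frame(
      term = colnames(X), b = f$beta, SE = f$se, df = f$df, t = f$t, p = f$p),
      vcov = f$vcov, sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2,
      lambda = f$lambda, neg2reml = f$neg2reml, N = f$N, n = f$n,
      channel = channel, ar1 = FALSE, converged = TRUE,
      boundary = f$boundary, diagnostics = NULL)
  } else {
    d$subject <- factor(d$subject)
    fit <- tryCatch(
      nlme::lme(y ~ code, random = ~ 1 | subject, data = d,
                correlation = nlme::corAR1(form = ~ 1 | subject),
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(structure(list(coefficients = NULL, converged = FALSE,
                            diagnostics = conditionMessage(fit),
                            channel = channel, ar1 = TRUE),
                       class = "stol_mlm"))
    }
    tt <- summary(fit)$tTable
    N <- nrow(d); n <- nlevels(d$subject)
    df <- c(n - 1L, N - n - 1L)
    tval <- tt[, "Value"] / tt[, "Std.Error"]
    vc <- nlme::VarCorr(fit)
    out <- list(coefficients = data.frame(
      term = rownames(tt), b = tt[, "Value"], SE = tt[, "Std.Error"],
      df = df, t = tval, p = 2 * stats::pt(-abs(tval), df)),
      vcov = fit$varFix,
      sigma_u2 = as.numeric(vc["(Intercept)", "Variance"]),
      sigma_e2 = fit$sigma^2,
      phi = stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE),
      N = N, n = n, channel = channel, ar1 = TRUE, converged = TRUE,
      diagnostics = NULL)
  }
  structure(out, class = "stol_mlm")
}

#' @export
print.stol_mlm <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("random-intercept fit: NOT CONVERGED\n  ", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("random-intercept contrast%s%s (N = %d rows, n = %d subjects)\n",
              if (!is.null(x$channel)) sprintf(", channel %s", x$channel) else "",
              if (isTRUE(x$ar1)) ", AR(1) residuals" else "", x$N, x$n))
  ct <- x$coefficients
  ct$p <- format.pval(ct$p, digits = 3)
  print(ct, row.names = FALSE, digits = 4)
  cat(sprintf("  sigma_u^2 = %.5g, sigma_e^2 = %.5g (ICC %.3f)\n",
              x$sigma_u2, x$sigma_e2, x$sigma_u2 / (x$sigma_u2 + x$sigma_e2)))
  invisible(x)
}

#' @export
coef.stol_mlm <- function(object, ...) {
  stats::setNames(object$coefficients$b, object$coefficients$term)
}

#' @export
summary.stol_mlm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Intraclass correlation for one channel
#'
#' Between-subject share of total variance from the intercept-only
#' random-intercept model: `sigma_u^2 / (sigma_u^2 + sigma_e^2)`.
#'
#' @inheritParams fit_random_intercept
#' @return A value in `[0, 1)`.
#' @export
icc <- function(data, channel = NULL) {
  d <- .check_long(data, channel)
  f <- .reml_ri(d$y, cbind("(Intercept)" = rep(1, nrow(d))), d$subject)
  f$sigma_u2 / (f$sigma_u2 + f$sigma_e2)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved and adjusted values are never below the raw ones.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Deliberation moderation of the ROI condition effect
#'
#' Fits the cross-level interaction model on rows pooled over the region
#' of interest (left DLPFC, channels 1-4 by default):
#' `y = g00 + g01 * D + g10 * code + g11 * D * code + u_subject + e`,
#' with the subject-level trait `D` centered at the sample mean of the
#' analyzed subjects. Subjects without a trait score are dropped listwise.
#' Simple slopes of the condition effect are probed at D = mean +/- 1 SD
#' with between-within degrees of freedom (`N - n - 2` for level-1 terms,
#' `n - 2` for the trait main effect).
#'
#' @param data Long-format data (`subject`, `channel`, `code`, `y`).
#' @param traits Data frame with columns `subject` and `deliberation_t`.
#' @param roi Channels pooled into the region of interest.
#' @param probe_sd Probe offset in trait SD units (default 1).
#' @return An object of class `stol_moderation`: `coefficients` (the four
#'   gammas with SE/df/t/p), `slopes` (condition effect at low/high D),
#'   centering constants, counts.
#' @export
fit_moderation <- function(data, traits, roi = 1:4, probe_sd = 1) {
  d <- .check_long(data)
  if (!"channel" %in% names(d)) stop("data lacks 'channel'", call. = FALSE)
  d <- d[d$channel %in% roi, , drop = FALSE]
  if (!nrow(d)) stop("no rows in the ROI channels", call. = FALSE)
  stopifnot(all(c("subject", "deliberation_t") %in% names(traits)))
  tr <- traits[!is.na(traits$deliberation_t), c("subject", "deliberation_t")]
  d <- merge(d, tr, by = "subject")
  subs <- unique(d$subject)
  if (length(subs) < 3L)
    stop("fewer than 3 subjects with a deliberation score", call. = FALSE)
  dsub <- tr$deliberation_t[match(subs, tr$subject)]
  d_mean <- mean(dsub); d_sd <- stats::sd(dsub)
  Dc <- d$deliberation_t - d_mean
  X <- cbind("(Intercept)" = 1, D = Dc, code = d$code, "code:D" = d$code * Dc)
  f <- .reml_ri(d$y, X, d$subject)
  co <- data.frame(term = colnames(X), b = f$beta, SE = f$se, df = f$df,
                   t = f$t, p = f$p)
  probe <- c(low = -probe_sd * d_sd, high = probe_sd * d_sd)
  slopes <- do.call(rbind, lapply(names(probe), function(lv) {
    dv <- probe[[lv]]
    b <- f$beta[3] + f$beta[4] * dv
    v <- f$vcov[3, 3] + dv^2 * f$vcov[4, 4] + 2 * dv * f$vcov[3, 4]
    se <- sqrt(v)
    df1 <- f$N - f$n - 2L
    tv <- b / se
    data.frame(level = lv, d_offset = dv, slope = b, SE = se, df = df1,
               t = tv, p = 2 * stats::pt(-abs(tv), df1))
  }))
  structure(list(coefficients = co, slopes = slopes, vcov = f$vcov,
                 sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2,
                 d_mean = d_mean, d_sd = d_sd, roi = roi,
                 N = f$N, n = f$n),
            class = "stol_moderation")
}

#' @export
print.stol_moderation <- function(x, ...) {
  cat(sprintf("deliberation moderation, ROI channels %s (N = %d rows, n = %d subjects)\n",
              paste(x$roi, collapse = ","), x$N, x$n))
  co <- x$coefficients; co$p <- format.pval(co$p, digits = 3)
  print(co, row.names = FALSE, digits = 4)
  cat(sprintf("simple slopes of condition at deliberation mean %+.1f SD:\n",
              x$slopes$d_offset[2] / x$d_sd))
  sl <- x$slopes; sl$p <- format.pval(sl$p, digits = 3)
  print(sl, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Channel-wise multilevel contrast with FDR correction
#'
#' Fits [fit_random_intercept()] on every channel, adjusts the condition
#' p-values across channels by Benjamini-Hochberg, and labels each channel
#' `activated` (b > 0, adjusted p below `alpha`), `deactivated` (b < 0) or
#' `null`. Per-channel fitting errors become flagged rows, not failures.
#'
#' @inheritParams fit_random_intercept
#' @param alpha FDR-adjusted significance threshold (default 0.05).
#' @param with_icc Also compute each channel's intraclass correlation
#'   (intercept-only model).
#' @return An object of class `stol_channelwise`: a data frame with one
#'   row per channel (`channel`, `b`, `SE`, `df`, `t`, `p`, `p_fdr`,
#'   `label`, `N`, `n`, variance components, optional `icc`, `note`).
#' @export
channelwise_analysis <- function(data, alpha = 0.05, ar1 = FALSE,
                                 with_icc = FALSE) {
  d <- .check_long(data)
  if (!"channel" %in% names(d)) stop("data lacks 'channel'", call. = FALSE)
  chans <- sort(unique(d$channel))
  if (length(chans) < 2L) stop("need at least 2 channels", call. = FALSE)
  rows <- lapply(chans, function(ch) {
    f <- tryCatch(fit_random_intercept(d, channel = ch, ar1 = ar1),
                  error = function(e) e)
    if (inherits(f, "error") || !isTRUE(f$converged)) {
      msg <- if (inherits(f, "error")) conditionMessage(f) else f$diagnostics
      return(data.frame(channel = ch, b = NA_real_, SE = NA_real_,
                        df = NA_real_, t = NA_real_, p = NA_real_,
                        N = NA_integer_, n = NA_integer_,
                        sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                        icc = NA_real_, note = msg))
    }
    i <- which(f$coefficients$term == "code")
    data.frame(channel = ch, b = f$coefficients$b[i],
               SE = f$coefficients$SE[i], df = f$coefficients$df[i],
               t = f$coefficients$t[i], p = f$coefficients$p[i],
               N = f$N, n = f$n,
               sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2,
               icc = if (with_icc) icc(d, channel = ch) else NA_real_,
               note = NA_character_)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- fdr_adjust(tab$p)
  tab$label <- ifelse(is.na(tab$p_fdr), NA_character_,
                      ifelse(tab$p_fdr < alpha,
                             ifelse(tab$b > 0, "activated", "deactivated"),
                             "null"))
  if (!with_icc) tab$icc <- NULL
  tab <- tab[, c(setdiff(names(tab), c("p_fdr", "label", "note")),
                 "p_fdr", "label", "note")]
  structure(tab, class = c("stol_channelwise", "data.frame"), alpha = alpha)
}

#' @export
print.stol_channelwise <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("channel-wise MM vs ZM contrast (FDR-adjusted alpha = %g)\n", alpha))
  tab <- as.data.frame(x)
  star <- ifelse(is.na(tab$p_fdr), "",
                 ifelse(tab$p_fdr < 0.001, "***",
                        ifelse(tab$p_fdr < alpha, "*", "")))
  show <- data.frame(channel = tab$channel,
                     b = sprintf("%.4f", tab$b),
                     SE = sprintf("%.4f", tab$SE),
                     df = tab$df,
                     t = sprintf("%.2f%s", tab$t, star),
                     label = tab$label)
  print(show, row.names = FALSE)
  if (any(!is.na(tab$note)))
    cat("flagged channels:", paste(tab$channel[!is.na(tab$note)], collapse = ", "), "\n")
  invisible(x)
}

#' Schematic channel-grid heatmap of the contrast
#'
#' Draws the 16 channels as a 4x4 grid (channel 1 top-left, row-major)
#' colored by the contrast t statistic; FDR-significant channels are
#' outlined. A schematic stand-in for template-based topography.
#'
#' @param x An `stol_channelwise` object.
#' @param ... Unused.
#' @export
plot.stol_channelwise <- function(x, ...) {
  tab <- as.data.frame(x)
  n <- nrow(tab)
  ncol_grid <- 4L
  nrow_grid <- ceiling(n / ncol_grid)
  tmat <- matrix(NA_real_, nrow_grid, ncol_grid)
  tmat[cbind((tab$channel - 1L) %/% ncol_grid + 1L,
             (tab$channel - 1L) %% ncol_grid + 1L)] <- tab$t
  lim <- max(abs(tmat), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(65)
  graphics::image(t(tmat[nrow_grid:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  main = "MM vs ZM contrast (t)")
  cx <- (seq_len(ncol_grid) - 1) / (ncol_grid - 1)
  cy <- rev((seq_len(nrow_grid) - 1) / (nrow_grid - 1))
  for (i in seq_len(n)) {
    r <- (tab$channel[i] - 1L) %/% ncol_grid + 1L
    cc <- (tab$channel[i] - 1L) %% ncol_grid + 1L
    sig <- !is.na(tab$p_fdr[i]) && tab$p_fdr[i] < attr(x, "alpha")
    graphics::text(cx[cc], cy[r],
                   labels = sprintf("%d%s", tab$channel[i], if (sig) "*" else ""),
                   font = if (sig) 2 else 1)
  }
  invisible(x)
}

#' Interaction plot for the moderation fit
#'
#' Model-implied oxy-Hb at the four condition-by-deliberation cells
#' (ZM/MM crossed with low/high trait, at mean -/+ 1 SD), the crossing
#' pattern the cross-level interaction tests.
#'
#' @param x An `stol_moderation` object.
#' @param ... Unused.
#' @export
plot.stol_moderation <- function(x, ...) {
  b <- x$coefficients$b
  dvals <- c(low = -x$d_sd, high = x$d_sd)
  pred <- outer(c(ZM = -1, MM = 1), dvals,
                function(cc, dv) b[1] + b[2] * dv + (b[3] + b[4] * dv) * cc)
  graphics::matplot(c(-1, 1), pred, type = "b", pch = 19, lty = 1:2,
                    col = c("#2166AC", "#B2182B"), xaxt = "n",
                    xlab = "condition", ylab = "predicted oxy-Hb (uM)",
                    main = "condition x deliberation")
  graphics::axis(1, at = c(-1, 1), labels = c("ZM", "MM"))
  graphics::legend("topleft", bty = "n", lty = 1:2, pch = 19,
                   col = c("#2166AC", "#B2182B"),
                   legend = c("deliberation -1 SD", "deliberation +1 SD"))
  invisible(x)
}
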