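# Random-intercept linear mixed model, restricted maximum likelihood.
#
# Model: y_ij = x_ij' beta + u_j + e_ij, u_j ~ N(0, s2u), e_ij ~ N(0, s2e).
# The REML criterion is profiled down to the single variance ratio
# lambda = s2u / s2e. With V* = I + lambda * J within each subject block,
# Woodbury gives V*^-1 = I - w J with w = lambda / (1 + lambda * n_j), so
# everything reduces to group-level sufficient statistics (counts, column
# sums of X, sums of y) and one 1-D optimization. This makes each fit
# O(rows) once, then O(groups) per criterion evaluation, which is what lets
# the calibration and recovery suites run thousands of fits.

#' @keywords internal
.reml_ri <- function(y, X, g) {
  g <- as.factor(g)
  N <- length(y)
  p <- ncol(X)
  nj <- as.numeric(table(g))
  G <- length(nj)
  if (G < 2L) stop("need at least 2 subjects", call. = FALSE)
  A <- crossprod(X)
  a <- rowsum(X, g)                # G x p group column sums
  tj <- as.numeric(rowsum(y, g))   # group sums of y
  s <- as.numeric(crossprod(X, y))
  yy <- sum(y * y)

  crit <- function(loglam) {
    lam <- exp(loglam)
    w <- lam / (1 + lam * nj)
    M <- A - crossprod(a, w * a)
    v <- s - as.numeric(crossprod(a, w * tj))
    q <- yy - sum(w * tj^2)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), v))
    rss <- max(q - sum(beta * v), 0)
    s2 <- max(rss / (N - p), 1e-300)
    obj <- (N - p) * log(s2) + sum(log1p(lam * nj)) +
      2 * sum(log(diag(ch)))
    list(obj = obj, beta = beta, s2 = s2, M = M, lam = lam)
  }

  opt <- stats::optimize(function(u) crit(u)$obj,
                         interval = c(-30, 15), tol = 1e-10)
  lo <- crit(-30)
  best <- if (lo$obj < opt$objective) -30 else opt$minimum
  fit <- crit(best)
  vc <- fit$s2 * chol2inv(chol(fit$M))
  se <- sqrt(diag(vc))
  # between-within degrees of freedom: a coefficient whose column varies
  # within subjects is level-1 (df = N - n - k1); constants within subject,
  # including the intercept, are level-2 (df = n - 1 - k2).
  wvar <- vapply(seq_len(p), function(j) {
    m <- rowsum(X[, j], g) / nj
    sum((X[, j] - m[g])^2)
  }, numeric(1))
  level1 <- wvar > 1e-10 * pmax(1, colSums(X^2))
  k1 <- sum(level1)
  k2 <- sum(!level1) - 1L
  df <- ifelse(level1, N - G - k1, G - 1L - k2)
  tval <- fit$beta / se
  list(beta = as.numeric(fit$beta), se = se, vcov = vc,
       t = as.numeric(tval), df = df,
       p = 2 * stats::pt(-abs(tval), df),
       sigma_e2 = fit$s2, sigma_u2 = fit$lam * fit$s2, lambda = fit$lam,
       neg2reml = fit$obj, N = N, n = G, level1 = level1,
       boundary = best <= -30 + 1e-8 || best >= 15 - 1e-8)
}
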