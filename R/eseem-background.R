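#' Background-correct a 3-pulse ESEEM trace
#'
#' Deconvolutes the echo decay from the nuclear modulation. The deuterium
#' modulation only ever *reduces* the stimulated echo, so the oscillation-free
#' background is the upper envelope of the trace. The envelope is located by
#' taking the per-period maxima of the trace (one modulation period estimated
#' from the spectrum), a decay model is fitted to those points, and a second
#' pass re-fits after masking envelope points whose residuals are
#' inconsistent with the bulk (iterative masking of oscillatory residuals).
#' The normalized nuclear modulation function is then
#' `m(T) = V(T) / B(T) - 1`, which is dimensionless, non-positive in
#' expectation, and decays to zero at long T.
#'
#' @param trace an [echo_trace()].
#' @param model background model: `"stretched_exp"` (default) fits
#'   `a exp(-(T/t0)^beta)`; `"poly3"` fits a cubic polynomial to the log
#'   envelope.
#' @param nu_hint frequency used to set the envelope window length, MHz.
#'   Defaults to the trace's `nu` metadata, falling back to a spectral peak
#'   estimate.
#' @return An object of class `modulation_function`: list with elements `T`,
#'   `value`, `tau`, `background` (model descriptor, coefficients and fitted
#'   values), `nu_est` and `label`.
#' @export
correct_background <- function(trace, model = c("stretched_exp", "poly3"),
                               nu_hint = NULL) {
  stopifnot(inherits(trace, "echo_trace"))
  model <- match.arg(model)
  T_ns <- trace$T
  y <- trace$amplitude
  n <- length(y)
  if (any(y <= 0))
    stop("echo amplitudes must be positive for background deconvolution",
         call. = FALSE)

  if (is.null(nu_hint)) nu_hint <- trace$nu
  if (is.null(nu_hint) || is.na(nu_hint)) nu_hint <- .estimate_nu(T_ns, y)
  step <- T_ns[2] - T_ns[1]
  period_pts <- max(8L, round(1000 / (nu_hint * step)))

  ## per-period maxima approximate the oscillation-free envelope
  idx_env <- .window_argmax(y, period_pts)
  fit1 <- .fit_background(T_ns[idx_env], y[idx_env], model)
  if (is.null(fit1))
    stop("background fit failed to converge (pass 1); residual range ",
         paste(signif(range(y - mean(y)), 3), collapse = " .. "),
         call. = FALSE)

  ## pass 2: mask envelope points with outlying residuals and refit
  r <- y[idx_env] / .predict_background(fit1, T_ns[idx_env]) - 1
  s <- stats::mad(r)
  keep <- if (s > 0) abs(r - stats::median(r)) <= 3 * s else rep(TRUE, length(r))
  if (sum(keep) >= 8) {
    fit2 <- .fit_background(T_ns[idx_env][keep], y[idx_env][keep], model)
    if (!is.null(fit2)) fit1 <- fit2
  }

  bg <- .predict_background(fit1, T_ns)
  if (any(bg <= 0))
    stop("fitted background is non-positive; residual summary: ",
         paste(signif(quantile(y - bg), 3), collapse = ", "), call. = FALSE)
  value <- y / bg - 1
  structure(list(T = T_ns, value = value, tau = trace$tau,
                 background = list(model = model, coef = fit1$coef,
                                   fitted = bg),
                 nu_est = nu_hint, label = trace$label),
            class = "modulation_function")
}

#' @export
print.modulation_function <- function(x, ...) {
  cat(sprintf("<modulation_function> %s: %d points, background = %s\n",
              ifelse(is.na(x$label), "(unlabelled)", x$label),
              length(x$T), x$background$model))
  invisible(x)
}

## indices of the maximum within consecutive windows of `width` points
.window_argmax <- function(y, width) {
  n <- length(y)
  starts <- seq(1L, n, by = width)
  vapply(starts, function(s) {
    e <- min(s + width - 1L, n)
    as.integer(s - 1L + which.max(y[s:e]))
  }, integer(1))
}

## crude spectral estimate of the dominant modulation frequency (MHz)
.estimate_nu <- function(T_ns, y, band = c(0.5, 15)) {
  step <- T_ns[2] - T_ns[1]
  detr <- stats::residuals(lm(log(pmax(y, .Machine$double.eps)) ~ poly(T_ns, 3)))
  n <- length(detr)
  nfft <- 2^ceiling(log2(4 * n))
  mag <- Mod(fft(c(detr * .hamming_window(n), rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1) / (nfft * step) * 1e3  # MHz
  half <- freq <= 1e3 / (2 * step)
  sel <- half & freq >= band[1] & freq <= band[2]
  if (!any(sel)) return(2.25)
  freq[sel][which.max(mag[sel])]
}

.hamming_window <- function(n) as.numeric(signal::hamming(n))

.fit_background <- function(T_ns, y, model) {
  if (model == "poly3") {
    fit <- lm(log(y) ~ poly(T_ns, 3, raw = TRUE))
    return(list(model = "poly3", coef = coef(fit)))
  }
  a0 <- max(y)
  starts <- expand.grid(t0 = c(0.5, 1, 2) * max(T_ns), beta = c(0.7, 1, 1.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(T_ns / t0)^beta),
                        start = list(a = a0, t0 = starts$t0[i],
                                     beta = starts$beta[i]),
                        lower = c(a = 0, t0 = 1, beta = 0.1),
                        upper = c(a = Inf, t0 = Inf, beta = 3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(model = "stretched_exp", coef = coef(fit), rss = rss)
  }
  best
}

.predict_background <- function(fit, T_ns) {
  cf <- fit$coef
  if (fit$model == "poly3") {
    exp(cf[1] + cf[2] * T_ns + cf[3] * T_ns^2 + cf[4] * T_ns^3)
  } else {
    cf[["a"]] * exp(-(T_ns / cf[["t0"]])^cf[["beta"]])
  }
}
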