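#' Quantify one trace by the fit or Fourier route
#'
#' Convenience wrapper: background-correct a trace and return the solvent
#' accessibility observable of the chosen analysis route, either the fitted
#' modulation depth or the integrated deuterium spectral intensity.
#'
#' @param trace an [echo_trace()].
#' @param method `"fit"` (damped harmonic oscillation) or `"ft"`
#'   (magnitude-spectrum intensity).
#' @param background background model passed to [correct_background()].
#' @param ... further arguments for [fit_modulation()] or
#'   [spectrum_intensity()].
#' @return A one-row data frame: `label`, `method`, `value`, `sd`.
#' @export
trace_accessibility <- function(trace, method = c("fit", "ft"),
                                background = "stretched_exp", ...) {
  method <- match.arg(method)
  modfn <- correct_background(trace, model = background)
  if (method == "fit") {
    fit <- fit_modulation(modfn, ...)
    value <- fit$depth_k
    sdv <- if (is.finite(fit$relative_sd)) fit$relative_sd * value else NA_real_
  } else {
    ## both routes quantify the same deconvoluted modulation function; the
    ## joint background refinement of the fit stage is reused here so that
    ## the Fourier route is not biased by the first-pass envelope estimate
    fit <- tryCatch(fit_modulation(modfn), error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$background)) {
      modfn$value <- (modfn$value + 1) *
        modfn$background$fitted / fit$background - 1
      modfn$background$fitted <- fit$background
    }
    res <- spectrum_intensity(modfn, ...)
    value <- res$intensity
    ## noise floor of the magnitude spectrum away from the deuterium line,
    ## scaled to the integration window width
    spec <- res$spectrum
    far <- spec$freq > 6 & spec$freq < max(spec$freq) * 0.9
    df <- spec$freq[2] - spec$freq[1]
    nbin <- max(1, round(1 / df))  # default window is 2 * 0.5 MHz wide
    sdv <- stats::mad(spec$magnitude[far]) * sqrt(nbin) * df
  }
  data.frame(label = ifelse(is.na(trace$label), "trace", trace$label),
             method = method, value = value, sd = sdv,
             stringsAsFactors = FALSE)
}

#' Process a set of traces into raw accessibility observables
#'
#' @param traces a list of [echo_trace()] objects (e.g. from
#'   [simulate_accessibility_panel()] or [load_trace()]).
#' @inheritParams trace_accessibility
#' @return A data frame with one row per trace (`label`, `method`, `value`,
#'   `sd`).
#' @export
panel_accessibility <- function(traces, method = c("fit", "ft"), ...) {
  method <- match.arg(method)
  do.call(rbind, lapply(traces, trace_accessibility, method = method, ...))
}

#' Normalize a panel of accessibility observables to a 0-100% scale
#'
#' The residue with the highest accessibility (or an explicitly named
#' reference residue) is set to 100%, and every other entry is expressed
#' relative to it. Uncertainties are propagated from the per-residue standard
#' deviations and floored at 5 percentage points, the conventional bound that
#' exceeds fitting and relaxation-difference errors.
#'
#' @param raw data frame with columns `label`, `value` (non-negative) and
#'   optionally `sd` and `method`.
#' @param reference `"max"` (default) or the label of the reference residue.
#' @param uncertainty_floor minimum reported uncertainty, percentage points.
#' @return An `accessibility_panel`: data frame (`label`, `method`, `value`,
#'   `accessibility_pct`, `uncertainty_pct`) with attributes
#'   `reference_label` and `uncertainty_floor`.
#' @export
normalize_panel <- function(raw, reference = "max", uncertainty_floor = 5) {
  if (!is.data.frame(raw) || !all(c("label", "value") %in% names(raw)))
    stop("`raw` must be a data frame with columns label and value", call. = FALSE)
  if (nrow(raw) < 2) stop("a panel needs at least 2 entries", call. = FALSE)
  if (any(raw$value < 0)) stop("accessibility observables must be >= 0",
                               call. = FALSE)
  if (is.null(raw$sd)) raw$sd <- 0
  if (is.null(raw$method)) raw$method <- NA_character_
  if (identical(reference, "max")) {
    iref <- which.max(raw$value)
  } else {
    iref <- match(reference, raw$label)
    if (is.na(iref)) stop("reference label not in panel", call. = FALSE)
  }
  vref <- raw$value[iref]
  if (vref <= 0) stop("reference accessibility value is zero", call. = FALSE)
  pct <- 100 * raw$value / vref
  sd_ref <- ifelse(is.na(raw$sd[iref]), 0, raw$sd[iref])
  sdv <- ifelse(is.na(raw$sd), 0, raw$sd)
  u <- 100 / vref * sqrt(sdv^2 + (raw$value / vref)^2 * sd_ref^2)
  u[iref] <- 100 * sd_ref / vref
  u <- pmax(u, uncertainty_floor)
  out <- data.frame(label = raw$label, method = raw$method, value = raw$value,
                    accessibility_pct = pct, uncertainty_pct = u,
                    stringsAsFactors = FALSE)
  structure(out, class = c("accessibility_panel", "data.frame"),
            reference_label = raw$label[iref],
            uncertainty_floor = uncertainty_floor)
}

#' Compare per-residue accessibility between two states
#'
#' Each panel is normalized on its own 0-100% scale; the comparison is on the
#' percentages. A residue is called `deprotected` (more solvent exposed in
#' the second state) or `protected` when the percentage change exceeds the
#' combined uncertainty of the two panels (each floored at 5 points), and
#' `no_change` otherwise.
#'
#' @param panel_a reference-state [normalize_panel()] result (e.g. WT).
#' @param panel_b comparison-state panel (e.g. a pocket-modified mutant).
#' @return Data frame: `label`, `a_pct`, `b_pct`, `delta_pct`, `fold_change`,
#'   `combined_uncertainty_pct`, `class`.
#' @export
compare_states <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "accessibility_panel"),
            inherits(panel_b, "accessibility_panel"))
  shared <- intersect(panel_a$label, panel_b$label)
  if (length(shared) == 0)
    stop("panels share no residue labels", call. = FALSE)
  a <- panel_a[match(shared, panel_a$label), ]
  b <- panel_b[match(shared, panel_b$label), ]
  delta <- b$accessibility_pct - a$accessibility_pct
  comb <- sqrt(a$uncertainty_pct^2 + b$uncertainty_pct^2)
  cls <- ifelse(abs(delta) <= comb, "no_change",
                ifelse(delta > 0, "deprotected", "protected"))
  fold <- ifelse(a$accessibility_pct > 0,
                 b$accessibility_pct / a$accessibility_pct, NA_real_)
  data.frame(label = shared, a_pct = a$accessibility_pct,
             b_pct = b$accessibility_pct, delta_pct = delta,
             fold_change = fold, combined_uncertainty_pct = comb,
             class = cls, stringsAsFactors = FALSE)
}

#' Full panel analysis: traces to normalized accessibilities
#'
#' @inheritParams panel_accessibility
#' @inheritParams normalize_panel
#' @return An `accessibility_panel`.
#' @export
analyze_panel <- function(traces, method = c("fit", "ft"), reference = "max",
                          ...) {
  normalize_panel(panel_accessibility(traces, method = method, ...),
                  reference = reference)
}
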