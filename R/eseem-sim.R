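#' Acquisition and sample parameters for a synthetic 3-pulse ESEEM trace
#'
#' Bundles everything needed to simulate the deuterium echo modulation of a
#' spin-labelled site: the stimulated-echo pulse delays, the total deuterium
#' modulation depth `depth_k`, the effective deuterium Larmor frequency, a
#' modulation damping time, and a stretched-exponential echo-decay background.
#'
#' The defaults describe a typical X-band acquisition at 80 K: the delay `T`
#' is incremented from 400 ns in 12 ns steps, and `tau` sits on a proton
#' blind spot (m/nu_H with nu_H about 14.6 MHz) so that proton modulation is
#' suppressed while the deuterium term, proportional to
#' `1 - cos(2 pi nu_D tau)`, is close to its maximum.
#'
#' @param tau inter-pulse delay tau, ns.
#' @param t_start first value of the variable delay T, ns.
#' @param t_step increment of T, ns. Must be positive.
#' @param n_points number of points in the T grid.
#' @param depth_k total deuterium modulation depth, dimensionless in `[0, 1]`.
#' @param nu_D effective deuterium Larmor frequency, MHz. Must be positive.
#' @param damping_time exponential damping time of the nuclear modulation, ns.
#'   `Inf` disables damping.
#' @param bg_amplitude echo amplitude at T = 0, arbitrary units.
#' @param bg_time stretched-exponential background decay constant, ns.
#' @param bg_stretch stretch exponent of the background decay.
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   `bg_amplitude`. Must be non-negative.
#' @param seed integer seed for the noise generator, or `NULL`.
#'
#' @return An object of class `eseem_sim_params`.
#' @seealso [simulate_eseem_trace()], [simulate_accessibility_panel()]
#' @export
eseem_sim_params <- function(tau = 205, t_start = 400, t_step = 12,
                             n_points = 2048, depth_k = 0.3, nu_D = 2.25,
                             damping_time = 8000, bg_amplitude = 1,
                             bg_time = 20000, bg_stretch = 0.9,
                             noise_sigma = 0, seed = NULL) {
  if (!is.numeric(depth_k) || depth_k < 0 || depth_k > 1)
    stop("`depth_k` must lie in [0, 1]", call. = FALSE)
  if (t_step <= 0) stop("`t_step` must be positive", call. = FALSE)
  if (n_points < 8) stop("`n_points` must be at least 8", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (nu_D <= 0) stop("`nu_D` must be positive", call. = FALSE)
  if (tau <= 0 || t_start <= 0)
    stop("`tau` and `t_start` must be positive", call. = FALSE)
  if (damping_time <= 0) stop("`damping_time` must be positive", call. = FALSE)
  if (bg_time <= 0 || bg_amplitude <= 0 || bg_stretch <= 0)
    stop("background parameters must be positive", call. = FALSE)
  structure(list(tau = tau, t_start = t_start, t_step = t_step,
                 n_points = as.integer(n_points), depth_k = depth_k,
                 nu_D = nu_D, damping_time = damping_time,
                 bg_amplitude = bg_amplitude, bg_time = bg_time,
                 bg_stretch = bg_stretch, noise_sigma = noise_sigma,
                 seed = seed),
            class = "eseem_sim_params")
}

#' Construct a 3-pulse ESEEM echo trace
#'
#' @param T_ns strictly increasing, uniformly spaced grid of the variable
#'   delay T, ns.
#' @param amplitude echo amplitude at each T, arbitrary units.
#' @param tau inter-pulse delay tau, ns.
#' @param nu nominal deuterium frequency stored as metadata, MHz (optional).
#' @param field spectrometer field, mT (optional).
#' @param label residue/state identifier (optional).
#' @param meta named list of additional metadata.
#'
#' @return An object of class `echo_trace`.
#' @export
echo_trace <- function(T_ns, amplitude, tau, nu = NA_real_, field = NA_real_,
                       label = NA_character_, meta = list()) {
  if (length(T_ns) != length(amplitude))
    stop("`T_ns` and `amplitude` lengths differ", call. = FALSE)
  if (length(T_ns) < 2 || any(diff(T_ns) <= 0))
    stop("T grid must be strictly increasing", call. = FALSE)
  steps <- diff(T_ns)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop("T grid must be uniform", call. = FALSE)
  if (!all(is.finite(amplitude)))
    stop("amplitudes must be finite", call. = FALSE)
  structure(list(T = as.numeric(T_ns), amplitude = as.numeric(amplitude),
                 tau = tau, nu = nu, field = field, label = label,
                 meta = meta),
            class = "echo_trace")
}

#' @export
print.echo_trace <- function(x, ...) {
  cat(sprintf("<echo_trace> %s: %d points, T = %g..%g ns (step %g), tau = %g ns\n",
              ifelse(is.na(x$label), "(unlabelled)", x$label),
              length(x$T), min(x$T), max(x$T), x$T[2] - x$T[1], x$tau))
  invisible(x)
}

## Deuterium modulation factor of the stimulated echo for a single effective
## Larmor line: 1 - (k/4) (1 - cos w tau) (1 - cos w (T+tau)) damp(T).
.eseem_modulation_factor <- function(T_ns, tau, depth_k, nu, damping_time) {
  w <- .MHZ_NS * nu
  damp <- if (is.finite(damping_time)) exp(-T_ns / damping_time) else 1
  1 - (depth_k / 4) * (1 - cos(w * tau)) * (1 - cos(w * (T_ns + tau))) * damp
}

## Stretched-exponential echo decay background.
.eseem_background <- function(T_ns, amplitude, decay, stretch) {
  amplitude * exp(-(T_ns / decay)^stretch)
}

#' Simulate a 3-pulse ESEEM time-domain trace
#'
#' Generates the echo amplitude `V(T) = B(T) * M(T) + noise`, where `B` is a
#' stretched-exponential echo decay and `M` the deuterium nuclear modulation
#' factor
#' `M(T) = 1 - (k/4) (1 - cos 2 pi nu tau) (1 - cos 2 pi nu (T+tau)) e^(-T/td)`.
#' A single effective deuterium line is used: nuclear quadrupole structure
#' and combination harmonics are deliberately absorbed into the empirical
#' damping, matching the damped-harmonic model used downstream.
#'
#' @param params an [eseem_sim_params()] object.
#' @return An [echo_trace()] whose `meta` records all ground-truth parameters.
#' @examples
#' tr <- simulate_eseem_trace(eseem_sim_params(depth_k = 0.4, noise_sigma = 0))
#' @export
simulate_eseem_trace <- function(params) {
  stopifnot(inherits(params, "eseem_sim_params"))
  p <- params
  T_ns <- p$t_start + (seq_len(p$n_points) - 1) * p$t_step
  bg <- .eseem_background(T_ns, p$bg_amplitude, p$bg_time, p$bg_stretch)
  v <- bg * .eseem_modulation_factor(T_ns, p$tau, p$depth_k, p$nu_D,
                                     p$damping_time)
  if (p$noise_sigma > 0) {
    if (!is.null(p$seed)) set.seed(as.integer(p$seed %% .Machine$integer.max))
    v <- v + rnorm(length(v), 0, p$noise_sigma * p$bg_amplitude)
  }
  echo_trace(T_ns, v, tau = p$tau, nu = p$nu_D,
             meta = list(params = unclass(p), truth_depth_k = p$depth_k,
                         seed = p$seed))
}

#' Simulate a panel of ESEEM traces with shared acquisition settings
#'
#' One trace per labelled residue, all on the identical T grid, with
#' independent noise realisations whose seeds are derived from the shared
#' seed (`shared$seed + offset`; the offset defaults to the position in the
#' panel, so two entries given the same explicit offset reproduce identical
#' noise).
#'
#' @param depths a named numeric vector of modulation depths, or a data frame
#'   with columns `label`, `depth_k` and optionally `seed_offset`.
#' @param shared an [eseem_sim_params()] object holding the common
#'   acquisition settings (its `depth_k` is ignored).
#' @return A named list of [echo_trace()] objects.
#' @export
simulate_accessibility_panel <- function(depths, shared = eseem_sim_params()) {
  stopifnot(inherits(shared, "eseem_sim_params"))
  if (is.numeric(depths) && !is.null(names(depths)))
    depths <- data.frame(label = names(depths), depth_k = unname(depths),
                         stringsAsFactors = FALSE)
  if (!is.data.frame(depths) || !all(c("label", "depth_k") %in% names(depths)))
    stop("`depths` must be a named vector or a data frame with label/depth_k",
         call. = FALSE)
  if (nrow(depths) == 0) stop("`depths` is empty", call. = FALSE)
  if (anyDuplicated(depths$label))
    stop("duplicate residue labels in panel", call. = FALSE)
  if (is.null(depths$seed_offset)) depths$seed_offset <- seq_len(nrow(depths))
  base_seed <- if (is.null(shared$seed)) 0L else shared$seed
  traces <- lapply(seq_len(nrow(depths)), function(i) {
    p <- shared
    p$depth_k <- depths$depth_k[i]
    p$seed <- if (p$noise_sigma > 0) base_seed + depths$seed_offset[i] else NULL
    tr <- simulate_eseem_trace(p)
    tr$label <- depths$label[i]
    tr
  })
  names(traces) <- depths$label
  traces
}
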