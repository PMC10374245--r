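#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates a canonical hemodynamic response kernel on a time grid: the
#' difference of two gamma densities (a positive lobe peaking a few seconds
#' after stimulus onset and a late undershoot), normalized to unit peak
#' amplitude. Event-locked HbO responses rise over roughly 5--6 s and return
#' to baseline within 10--12 s, which this kernel reproduces with its
#' conventional defaults.
#'
#' @param t_grid Numeric vector of non-negative time points in seconds,
#'   uniformly spaced (typically `seq(0, 32, by = 1/fs)`).
#' @param peak_delay_s Delay of the response peak lobe, seconds (default 6).
#' @param undershoot_delay_s Delay of the undershoot lobe, seconds
#'   (default 16).
#' @param dispersion Dispersion (gamma scale) of both lobes, seconds
#'   (default 1).
#' @param undershoot_ratio Relative amplitude of the undershoot (default 1/6).
#'   `0` gives a single non-negative gamma kernel.
#'
#' @return Numeric vector of kernel amplitudes, unit peak.
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.25))
#' plot(seq(0, 32, by = 0.25), h, type = "l")
#' @export
canonical_hrf <- function(t_grid, peak_delay_s = 6, undershoot_delay_s = 16,
                          dispersion = 1, undershoot_ratio = 1 / 6) {
  if (!is.numeric(t_grid) || any(t_grid < 0)) {
    stop("`t_grid` must be a numeric vector of non-negative times")
  }
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 || dispersion <= 0) {
    stop("`peak_delay_s`, `undershoot_delay_s` and `dispersion` must be positive")
  }
  if (undershoot_ratio < 0) stop("`undershoot_ratio` must be >= 0")
  # gamma densities parameterized so each lobe's mode sits at its stated delay
  h <- stats::dgamma(t_grid, shape = peak_delay_s / dispersion + 1,
                     scale = dispersion) -
    undershoot_ratio * stats::dgamma(t_grid, shape = undershoot_delay_s / dispersion + 1,
                                     scale = dispersion)
  peak <- max(abs(h))
  if (peak == 0) stop("degenerate HRF: kernel is identically zero on this grid")
  h / max(h)
}

#' Resolve HRF parameters from a simulation configuration
#' @param hrf list with fields `peak_delay_s`, `undershoot_delay_s`,
#'   `dispersion`, `undershoot_ratio`
#' @param t_grid time grid in seconds
#' @return amplitude series (unit peak)
#' @keywords internal
#' @noRd
hrf_from_params <- function(t_grid, hrf) {
  canonical_hrf(t_grid,
                peak_delay_s = hrf$peak_delay_s,
                undershoot_delay_s = hrf$undershoot_delay_s,
                dispersion = hrf$dispersion,
                undershoot_ratio = hrf$undershoot_ratio)
}
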