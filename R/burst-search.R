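#' All-photon sliding-window burst search
#'
#' A photon is burst-eligible iff at least `min_per_window` photons (all
#' gates pooled) fall in the time window of length `window_s` centred on it;
#' the window is closed at both edges. Maximal runs of consecutive eligible
#' photons form candidate bursts (runs also end at inter-photon gaps longer
#' than the window, since such photons can share no window); candidates are
#' kept when they hold at least
#' `min_photons` photons and their duration (first to last photon) lies
#' within `duration_range`. Defaults: 500 us window, 5 photons per window,
#' 50 photons per burst, 0-20 ms duration cutoff.
#'
#' @param ps a [photon_stream()] (photons must be time-sorted, which the
#'   class guarantees).
#' @param window_s sliding window length in seconds.
#' @param min_per_window minimum photons inside the centred window.
#' @param min_photons minimum photons per burst.
#' @param duration_range inclusive burst duration cutoff in seconds.
#' @return A data.frame with one row per burst: `i_start`, `i_end` (photon
#'   indices), `n_photons`, `t_start_s`, `t_end_s`, `duration_s`.
#' @export
find_bursts <- function(ps, window_s = 500e-6, min_per_window = 5,
                        min_photons = 50, duration_range = c(0, 20e-3)) {
  stopifnot(inherits(ps, "photon_stream"))
  empty <- data.frame(i_start = integer(0), i_end = integer(0),
                      n_photons = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), duration_s = numeric(0))
  n <- length(ps)
  if (n == 0) return(empty)
  t <- ps$macrotime
  if (is.unsorted(t)) stop("photon stream is not time-sorted")
  W <- window_s / 2 * ps$sync_rate_hz
  # closed window [t - W, t + W] on integer sync counts
  hi <- findInterval(floor(t + W) + 0.5, t)
  lo <- findInterval(ceiling(t - W) - 0.5, t)
  eligible <- (hi - lo) >= min_per_window
  ## runs of consecutive eligible photons; two photons farther apart than the
  ## full window can share no window, so such gaps also terminate a run
  Wfull <- window_s * ps$sync_rate_hz
  change <- if (n > 1) c(TRUE, (eligible[-1] != eligible[-n]) | (diff(t) > Wfull))
            else TRUE
  starts <- which(change)
  ends <- c(starts[-1] - 1L, n)
  keep <- eligible[starts]
  i1 <- starts[keep]; i2 <- ends[keep]
  np <- i2 - i1 + 1L
  dur <- (t[i2] - t[i1]) / ps$sync_rate_hz
  ok <- np >= min_photons & dur >= duration_range[1] & dur <= duration_range[2]
  if (!any(ok)) return(empty)
  data.frame(i_start = i1[ok], i_end = i2[ok], n_photons = np[ok],
             t_start_s = t[i1[ok]] / ps$sync_rate_hz,
             t_end_s = t[i2[ok]] / ps$sync_rate_hz,
             duration_s = dur[ok])
}

#' Per-burst photon data
#'
#' Extracts, for each burst, the arrival times and gate classes of its
#' photons -- the substrate for the 2CDE kernels, BVA and fFCS patterns.
#'
#' @param ps a [photon_stream()] with gates assigned.
#' @param bursts a burst table from [find_bursts()].
#' @return A list with one element per burst: `t_dex` (donor-excitation
#'   photon times, s), `acc` (logical, TRUE for BR-gate photons among
#'   `t_dex`), `t_aex` (acceptor-excitation photon times, s), `nano_idx`
#'   (photon indices into `ps` for the donor-excitation photons).
#' @export
burst_photon_data <- function(ps, bursts) {
  ts <- macrotime_s(ps)
  lapply(seq_len(nrow(bursts)), function(b) {
    idx <- bursts$i_start[b]:bursts$i_end[b]
    g <- ps$gate[idx]
    dex <- g >= 1L & g <= 4L
    aex <- g == 5L | g == 6L
    list(t_dex = ts[idx[dex]],
         acc = g[dex] >= 3L,
         t_aex = ts[idx[aex]],
         idx_dex = idx[dex])
  })
}
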