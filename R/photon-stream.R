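#' @keywords internal
"_PACKAGE"

DETECTORS <- c("Bpar", "Bperp", "Rpar", "Rperp")
GATES <- c("BBpar", "BBperp", "BRpar", "BRperp", "RRpar", "RRperp", "discarded")

#' Construct a time-tagged photon stream
#'
#' A photon stream holds one record per detected photon: the macrotime (the
#' laser sync cycle in which the photon arrived), the microtime (the TCSPC
#' delay within the sync period) and the detector that fired. Internally both
#' times are stored as exact integers -- sync counts and TCSPC bins -- so that
#' file round trips are bit-faithful; seconds are derived from the metadata.
#'
#' @param macrotime numeric vector of sync counts (nondecreasing,
#'   integer-valued; stored as doubles because counts routinely exceed 2^31).
#' @param nanotime integer vector of TCSPC bins, `0 <= nanotime < n_tcspc_bins`.
#' @param detector character or factor with levels `Bpar`, `Bperp`, `Rpar`,
#'   `Rperp` (blue/red spectral band, parallel/perpendicular polarization).
#' @param sync_rate_hz laser sync (excitation alternation) rate in Hz.
#'   Default 26.67 MHz.
#' @param n_tcspc_bins number of TCSPC bins spanning one sync period.
#' @param duration_s acquisition duration in seconds; defaults to the last
#'   macrotime converted to seconds.
#' @param windows PIE gate windows, see [gate_windows()]. When supplied, gates
#'   are assigned immediately.
#' @return An object of class `photon_stream`.
#' @seealso [assign_pie_gates()], [read_photons()], [write_photons()]
#' @export
photon_stream <- function(macrotime, nanotime, detector,
                          sync_rate_hz = 26.67e6,
                          n_tcspc_bins = 4096L,
                          duration_s = NULL,
                          windows = NULL) {
  n <- length(macrotime)
  stopifnot(length(nanotime) == n, length(detector) == n)
  if (n > 0 && any(diff(macrotime) < 0))
    stop("macrotimes must be nondecreasing")
  if (any(macrotime < 0) || any(macrotime != floor(macrotime)))
    stop("macrotime must hold nonnegative integer sync counts")
  if (any(nanotime < 0) || any(nanotime >= n_tcspc_bins))
    stop("nanotime outside [0, n_tcspc_bins)")
  det <- as.integer(factor(as.character(detector), levels = DETECTORS))
  if (any(is.na(det)))
    stop("unknown detector label; expected one of ", paste(DETECTORS, collapse = ", "))
  if (is.null(duration_s))
    duration_s <- if (n) (macrotime[n] + 1) / sync_rate_hz else 0
  ps <- structure(
    list(macrotime = as.numeric(macrotime),
         nanotime = as.integer(nanotime),
         detector = det,
         gate = rep.int(7L, n),
         sync_rate_hz = sync_rate_hz,
         n_tcspc_bins = as.integer(n_tcspc_bins),
         duration_s = duration_s,
         windows = NULL),
    class = "photon_stream")
  if (!is.null(windows)) ps <- assign_pie_gates(ps, windows)
  ps
}

#' @export
length.photon_stream <- function(x) length(x$macrotime)

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> %d photons, %.3f s, sync %.4g MHz, %d TCSPC bins\n",
              length(x), x$duration_s, x$sync_rate_hz / 1e6, x$n_tcspc_bins))
  if (length(x)) {
    tab <- table(factor(GATES[x$gate], levels = GATES))
    cat("  gates:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`[.photon_stream` <- function(x, i) {
  out <- x
  out$macrotime <- x$macrotime[i]
  out$nanotime <- x$nanotime[i]
  out$detector <- x$detector[i]
  out$gate <- x$gate[i]
  out
}

#' Macrotime in seconds
#' @param ps a [photon_stream()]
#' @return numeric vector of arrival times in seconds.
#' @export
macrotime_s <- function(ps) ps$macrotime / ps$sync_rate_hz

#' Microtime in seconds
#' @param ps a [photon_stream()]
#' @return numeric vector of TCSPC delays in seconds.
#' @export
microtime_s <- function(ps) ps$nanotime * microtime_resolution(ps)

#' TCSPC bin width in seconds
#' @param ps a [photon_stream()]
#' @export
microtime_resolution <- function(ps) 1 / (ps$sync_rate_hz * ps$n_tcspc_bins)

#' Gate labels of a photon stream
#' @param ps a [photon_stream()]
#' @return character vector with one of `BBpar`, `BBperp`, `BRpar`, `BRperp`,
#'   `RRpar`, `RRperp`, `discarded` per photon.
#' @export
gate_labels <- function(ps) GATES[ps$gate]

#' Define PIE excitation gate windows
#'
#' PIE alternates a blue (donor-exciting) and a red (acceptor-exciting) laser
#' pulse within one sync period; the two pulses are separated by a fixed delay
#' (18 ns at a 26.67 MHz sync rate), so a photon's microtime identifies which
#' laser excited the molecule. The defaults put the donor-excitation window at
#' [0, 18) ns and the acceptor-excitation window at [18, 37.5) ns.
#'
#' @param donor,acceptor two-element numeric vectors, window start/end in
#'   seconds within the sync period.
#' @return An object of class `gate_windows`.
#' @export
gate_windows <- function(donor = c(0, 18e-9), acceptor = c(18e-9, 37.5e-9)) {
  stopifnot(length(donor) == 2, length(acceptor) == 2,
            donor[1] < donor[2], acceptor[1] < acceptor[2])
  if (max(donor[1], acceptor[1]) < min(donor[2], acceptor[2]) &&
      !(donor[2] <= acceptor[1] || acceptor[2] <= donor[1]))
    stop("gate windows must not overlap")
  structure(list(donor = donor, acceptor = acceptor), class = "gate_windows")
}

#' Assign PIE gates to photons
#'
#' Labels every photon by (detector band, excitation window): blue-detector
#' photons in the donor window are donor emission (`BB`), red-detector photons
#' in the donor window are FRET-sensitized or crosstalk acceptor emission
#' (`BR`), red-detector photons in the acceptor window are direct acceptor
#' emission (`RR`). Blue-detector photons in the acceptor window fall in a
#' physically dark channel and are discarded, as are photons outside both
#' windows. The labeling is total: every photon gets exactly one gate.
#'
#' @param ps a [photon_stream()]
#' @param windows a [gate_windows()]
#' @return The stream with its `gate` field (and stored windows) updated.
#' @export
assign_pie_gates <- function(ps, windows = gate_windows()) {
  stopifnot(inherits(ps, "photon_stream"), inherits(windows, "gate_windows"))
  mt <- microtime_s(ps)
  in_d <- mt >= windows$donor[1] & mt < windows$donor[2]
  in_a <- mt >= windows$acceptor[1] & mt < windows$acceptor[2]
  blue <- ps$detector <= 2L
  par <- ps$detector %in% c(1L, 3L)
  gate <- rep.int(7L, length(ps))
  gate[blue & in_d] <- ifelse(par[blue & in_d], 1L, 2L)
  red <- !blue
  gate[red & in_d] <- ifelse(par[red & in_d], 3L, 4L)
  gate[red & in_a] <- ifelse(par[red & in_a], 5L, 6L)
  ps$gate <- gate
  ps$windows <- windows
  ps
}

#' Count photons per PIE gate
#' @param ps a [photon_stream()]
#' @param idx optional photon index subset.
#' @return named integer vector over the seven gate labels.
#' @export
gate_counts <- function(ps, idx = NULL) {
  g <- if (is.null(idx)) ps$gate else ps$gate[idx]
  out <- tabulate(g, nbins = 7L)
  names(out) <- GATES
  out
}
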