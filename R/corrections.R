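#' Instrument correction factors
#'
#' Bundles the correction factors shared by all downstream burst math:
#' donor emission crosstalk into the red channels (`ct`), acceptor direct
#' excitation by the blue laser (`de`), the relative donor/acceptor detection
#' efficiency (`gamma`), the excitation/detection normalization of the
#' red-excitation channel (`beta`), the polarization G factors of the blue and
#' red detector pairs, and the per-gate background rates.
#'
#' The defaults are typical values for an MFD-PIE setup with a 483/635 nm
#' laser pair: ct = 0.0059, de = 0.024, gamma = 0.69, beta = 1.9,
#' G_B = 0.99, G_R = 1.13.
#'
#' @param ct donor crosstalk fraction (unitless, >= 0).
#' @param de acceptor direct-excitation fraction (unitless, >= 0).
#' @param gamma relative detection efficiency of acceptor vs donor (> 0).
#' @param beta red-excitation normalization factor (> 0).
#' @param G_B,G_R polarization G factors for the blue and red detector pairs.
#' @param background named numeric vector of per-gate background rates in Hz
#'   over the six live gates.
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(ct = 0.0059, de = 0.024, gamma = 0.69, beta = 1.9,
                           G_B = 0.99, G_R = 1.13,
                           background = c(BBpar = 0, BBperp = 0, BRpar = 0,
                                          BRperp = 0, RRpar = 0, RRperp = 0)) {
  stopifnot(ct >= 0, de >= 0, gamma > 0, beta > 0, G_B > 0, G_R > 0)
  bg <- c(BBpar = 0, BBperp = 0, BRpar = 0, BRperp = 0, RRpar = 0, RRperp = 0)
  bg[names(background)] <- background
  structure(list(ct = ct, de = de, gamma = gamma, beta = beta,
                 G_B = G_B, G_R = G_R, background = bg),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf("<correction_set> ct=%.4g de=%.4g gamma=%.3g beta=%.3g G_B=%.3g G_R=%.3g\n",
              x$ct, x$de, x$gamma, x$beta, x$G_B, x$G_R))
  cat("  background [Hz]:", paste(sprintf("%s=%.3g", names(x$background), x$background),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Identity corrections (no crosstalk, unit detection factors)
#' @param background optional per-gate background rates in Hz.
#' @return a [correction_set()] with ct = de = 0, gamma = beta = G = 1.
#' @export
identity_corrections <- function(background = NULL) {
  if (is.null(background))
    correction_set(ct = 0, de = 0, gamma = 1, beta = 1, G_B = 1, G_R = 1)
  else
    correction_set(ct = 0, de = 0, gamma = 1, beta = 1, G_B = 1, G_R = 1,
                   background = background)
}
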