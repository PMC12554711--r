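#' The 16-lead 10-20 montage
#'
#' Channel labels of the 16-electrode subset of the international 10-20
#' system used throughout the package, in canonical order.
#'
#' @return Character vector of 16 channel labels.
#' @export
#' @examples
#' montage_channels()
montage_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

#' Canonical EEG frequency bands
#'
#' The five conventional bands, half-open on the upper edge (a shared edge
#' belongs to the upper band) except gamma, which is closed at the 45 Hz
#' global low-pass edge.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 45)
  )
}

band_names <- function() eeg_bands()$band

#' Schematic scalp layout for the 16-lead montage
#'
#' Two-dimensional schematic head coordinates (unit disc, nose up) for the
#' 16 montage channels. The layout is a conventional flattened 10-20
#' schematic, not an anatomical projection; left/right homologues are
#' mirrored in x.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' montage_layout()
montage_layout <- function() {
  # outer ring at r = 0.9, inner electrodes on a square-ish grid
  deg <- function(a) a * pi / 180
  ring <- function(a) c(0.9 * cos(deg(a)), 0.9 * sin(deg(a)))
  coords <- rbind(
    Fp1 = ring(108), Fp2 = ring(72),
    F7  = ring(144), F8  = ring(36),
    T3  = ring(180), T4  = ring(0),
    T5  = ring(216), T6  = ring(324),
    O1  = ring(252), O2  = ring(288),
    F3  = c(-0.38, 0.45), F4 = c(0.38, 0.45),
    C3  = c(-0.45, 0.00), C4 = c(0.45, 0.00),
    P3  = c(-0.38, -0.45), P4 = c(0.38, -0.45)
  )
  out <- tibble::tibble(
    channel = rownames(coords),
    x = round(unname(coords[, 1]), 10),
    y = round(unname(coords[, 2]), 10)
  )
  out[match(montage_channels(), out$channel), ]
}
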