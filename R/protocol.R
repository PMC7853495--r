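#' Adjacent (neighbouring-pair) stimulation and measurement protocol
#'
#' Builds the standard adjacent drive pattern on `electrode_count` electrodes:
#' current of `amplitude` is injected between each neighbouring electrode pair
#' `(k, k+1 mod n)` in turn, and for every injection the voltage is measured
#' across every neighbouring pair that does not involve a driving electrode,
#' in counter-clockwise order.  On 16 electrodes this yields 16 injections
#' with 13 measurements each, 208 rows in total.
#'
#' @param electrode_count Number of electrodes (>= 4).
#' @param amplitude Injected current amplitude (arbitrary units).
#' @return A tibble of class `eit_protocol` with one row per measurement:
#'   columns `injection`, `src`, `sink` (1-based electrode indices),
#'   `meas_pos`, `meas_neg` and `amplitude`.  The measured value convention is
#'   `U[meas_pos] - U[meas_neg]`.
#' @examples
#' p <- make_adjacent_protocol(16)
#' nrow(p)  # 208
#' @export
make_adjacent_protocol <- function(electrode_count = 16L, amplitude = 1) {
  stopifnot(electrode_count >= 4, amplitude > 0)
  E <- as.integer(electrode_count)
  rows <- list()
  for (k in seq_len(E)) {          # injection k: src = k, sink = k %% E + 1
    src <- k; sink <- k %% E + 1L
    pos <- seq_len(E)
    neg <- pos %% E + 1L
    keep <- pos != src & pos != sink & neg != src & neg != sink
    rows[[k]] <- tibble::tibble(
      injection = k, src = src, sink = sink,
      meas_pos = pos[keep], meas_neg = neg[keep], amplitude = amplitude)
  }
  out <- do.call(rbind, rows)
  attr(out, "electrode_count") <- E
  class(out) <- c("eit_protocol", class(out))
  out
}
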