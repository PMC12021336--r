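# CAIPI image-slice and transition-band phase modulation, the residual-error
# coefficient of the demodulated transition-band signal, and the nulling
# condition. Excitation index m is 1-based throughout.

#' CAIPI phase of an image slice
#'
#' Per-excitation controlled-aliasing phase of slice `alpha` in a group of
#' `Ns` simultaneously excited slices: `exp(-2i pi (alpha - 1) m / Ns)`.
#'
#' @param alpha Slice index within the group, 1..Ns.
#' @param m Excitation index (1-based); may be a vector.
#' @param Ns Multiband factor.
#' @return Unit-modulus complex value(s).
#' @examples
#' caipi_phase(2, 1, 3)   # exp(-2i pi / 3)
#' @export
caipi_phase <- function(alpha, m, Ns) {
  stopifnot(Ns >= 1, all(m >= 1))
  if (any(alpha < 1 | alpha > Ns)) stop("alpha must lie in 1..Ns")
  exp(-2i * pi * (alpha - 1) * m / Ns)
}

#' Transition-band spoiling phase
#'
#' Per-excitation phase of the transition-band RF waveform that makes the
#' demodulated band signal sum to zero over any multiple of `2 Ns`
#' excitations: `exp(-i pi m)` for odd `Ns` and
#' `exp(-i pi (m + floor((m - 1) / Ns)))` for even `Ns`.
#'
#' @param m Excitation index (1-based); may be a vector.
#' @param Ns Multiband factor.
#' @return Unit-modulus complex value(s).
#' @examples
#' Re(tb_phase(1:6, 3))   # -1 +1 -1 +1 -1 +1
#' @export
tb_phase <- function(m, Ns) {
  stopifnot(Ns >= 1, all(m >= 1))
  if (Ns %% 2 == 1) exp(-1i * pi * m)
  else exp(-1i * pi * (m + floor((m - 1) / Ns)))
}

#' Residual transition-band weight of a reconstructed slice
#'
#' The constant-band-signal coefficient of the residual error in slice `b`
#' after demodulating `M` excitations:
#' `sum_m conj(phi(b, m)) * varphi(m)`, with the band phase `varphi` equal to
#' 1 when spoiling is off. Without band spoiling and `M` a multiple of
#' `2 Ns` this equals `M` for `b = 1` and 0 otherwise (the band aliases only
#' into the first slice of the group); with the spoiling phase on it vanishes
#' for every slice.
#'
#' @param b Reconstructed slice index, 1..Ns.
#' @param Ns Multiband factor.
#' @param M Number of excitations.
#' @param tb_mode `"eq_spoil"` (band spoiling phase on) or `"off"`.
#' @return Complex weight.
#' @export
residual_weight <- function(b, Ns, M, tb_mode = c("eq_spoil", "off")) {
  tb_mode <- match.arg(tb_mode)
  stopifnot(M >= 1)
  m <- seq_len(M)
  phi <- if (tb_mode == "off") rep(1 + 0i, M) else tb_phase(m, Ns)
  sum(Conj(caipi_phase(b, m, Ns)) * phi)
}

#' Minimum number of excitations for complete band nulling
#'
#' Smallest `M` such that the residual weight vanishes for every slice under
#' the band spoiling phase; equals twice the multiband factor (six
#' excitations per group for Ns = 3).
#'
#' @param Ns Multiband factor.
#' @param search_max Upper bound of the brute-force search (default `4 * Ns`).
#' @return Integer M.
#' @export
min_nulling_length <- function(Ns, search_max = 4 * Ns) {
  stopifnot(Ns >= 1)
  for (M in seq_len(search_max)) {
    w <- vapply(seq_len(Ns), function(b)
      abs(residual_weight(b, Ns, M, "eq_spoil")), numeric(1))
    if (all(w < 1e-9)) return(M)
  }
  stop("no nulling length found up to search_max")
}

#' Build a full phase schedule
#'
#' Unit-modulus image-slice phases `phi(alpha, m)` and transition-band phases
#' `varphi(m)` for `M` excitations.
#'
#' @param Ns Multiband factor.
#' @param M Number of excitations.
#' @param tb_mode `"eq_spoil"` (default), `"off"` (all-ones band phase).
#' @return A `tbp_phase_schedule`: list with `Ns`, `M`, `img` (Ns x M complex
#'   matrix), `tb` (length-M complex), `tb_mode`.
#' @export
phase_schedule <- function(Ns, M, tb_mode = c("eq_spoil", "off")) {
  tb_mode <- match.arg(tb_mode)
  stopifnot(Ns >= 1, M >= 1)
  m <- seq_len(M)
  img <- t(vapply(seq_len(Ns), function(a) caipi_phase(a, m, Ns), complex(M)))
  tb <- if (tb_mode == "off") rep(1 + 0i, M) else tb_phase(m, Ns)
  structure(list(Ns = Ns, M = M, img = img, tb = tb, tb_mode = tb_mode),
            class = "tbp_phase_schedule")
}

#' @export
print.tbp_phase_schedule <- function(x, ...) {
  cat(sprintf("<tbp_phase_schedule> Ns=%d, M=%d, tb_mode=%s\n",
              x$Ns, x$M, x$tb_mode))
  invisible(x)
}

#' Phase schedule as a tidy table
#'
#' One row per excitation with slice and band phases in degrees, matching the
#' tabular layout used to describe the modulation scheme.
#'
#' @param x A `tbp_phase_schedule`.
#' @param ... Unused.
#' @return Tibble with `m`, `slice_1..slice_Ns` and `tb` phase columns
#'   (degrees, half-open interval from -180 exclusive to 180 inclusive).
#' @export
tidy.tbp_phase_schedule <- function(x, ...) {
  deg <- function(z) {
    d <- Arg(z) * 180 / pi
    d[d <= -180 + 1e-9] <- 180
    round(d, 6)
  }
  out <- tibble::tibble(m = seq_len(x$M))
  for (a in seq_len(x$Ns)) out[[paste0("slice_", a)]] <- deg(x$img[a, ])
  out$tb <- deg(x$tb)
  out
}

#' Export a phase schedule to CSV
#'
#' @param x A `tbp_phase_schedule`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(x, path) {
  utils::write.csv(tidy.tbp_phase_schedule(x), path, row.names = FALSE)
  invisible(path)
}
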