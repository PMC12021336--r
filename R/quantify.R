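# Signal-to-T1 and T1-to-gadolinium quantification: proton-density
# normalization, dictionary pattern matching and relaxivity conversion.

#' Normalize a signal series by its proton-density reference
#'
#' Element-wise magnitude ratio per band between a series acquired at the
#' imaging flip angle and the matching proton-density (low-flip) series.
#'
#' @param series,pd_series `tbp_signal_series` tibbles over the same bands.
#' @return A `tbp_signal_series` with `signal` replaced by the ratio.
#' @export
pd_normalize <- function(series, pd_series) {
  if (!setequal(unique(series$band), unique(pd_series$band)))
    stop("series and pd_series must cover the same bands")
  pd <- pd_series |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(k = dplyr::row_number(), pd_signal = abs(.data$signal)) |>
    dplyr::ungroup() |>
    dplyr::select("band", "k", "pd_signal")
  out <- series |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(pd, by = c("band", "k"))
  if (any(out$pd_signal == 0))
    stop("zero proton-density signal: cannot normalize")
  out <- out |>
    dplyr::mutate(signal = abs(.data$signal) / .data$pd_signal) |>
    dplyr::select(-"k", -"pd_signal")
  attrs <- attributes(series)
  structure(out, class = class(series), params = attrs$params,
            motion = attrs$motion, normalized = TRUE)
}

#' Dictionary T1 matching
#'
#' Estimates per-slice T1 by comparing a signal series against a simulated
#' dictionary. `method = "correlation"` maximizes the normalized
#' inner-product (cosine) correlation between the measured evolution and the
#' atom templates, the pattern-recognition matching used for signal
#' evolutions; it is invariant to overall scaling of the input.
#' `method = "amplitude"` matches the steady-state proton-density-normalized
#' signal level to the dictionary amplitude curve, the per-frame conversion
#' used in perfusion quantification (the input must then be PD-normalized).
#' Ties break toward the smaller T1.
#'
#' @param series A `tbp_signal_series` (PD-normalized for `"amplitude"`), or
#'   a numeric vector/single-column input for one slice.
#' @param dict A [build_dictionary()] result.
#' @param method `"correlation"` or `"amplitude"`.
#' @param window_fraction Steady-state tail fraction for amplitude matching.
#' @param slice Band name when `series` is a bare numeric vector.
#' @return Tibble with `band` and `t1_est_ms`.
#' @export
match_t1 <- function(series, dict, method = c("correlation", "amplitude"),
                     window_fraction = dict$window_fraction,
                     slice = dict$slice_bands[1]) {
  method <- match.arg(method)
  if (length(dict$T1_grid_ms) == 0) stop("empty dictionary")
  if (is.numeric(series)) {
    series <- tibble::tibble(band = slice, kind = "slice",
                             signal = as.numeric(series))
  }
  slices <- intersect(unique(series$band), dict$slice_bands)
  if (length(slices) == 0) stop("series contains no dictionary slice bands")
  est <- vapply(slices, function(b) {
    y <- series$signal[series$band == b]
    j <- match(b, dict$slice_bands)
    if (method == "correlation") {
      atoms <- dict$atoms[, , j]
      ny <- length(y)
      if (ny != nrow(atoms))
        stop("series length does not match dictionary template length")
      score <- as.numeric(crossprod(atoms, y)) /
        (sqrt(colSums(atoms^2)) * sqrt(sum(y^2)))
      dict$T1_grid_ms[which.max(score)]
    } else {
      n <- length(y)
      win <- seq(floor(n * (1 - window_fraction)) + 1, n)
      a <- mean(y[win])
      dict$T1_grid_ms[which.min(abs(dict$amp[, j] - a))]
    }
  }, numeric(1))
  tibble::tibble(band = slices, t1_est_ms = unname(est))
}

#' Relaxivity parameters
#'
#' Baseline T1 and contrast-agent relaxivity for the linear fast-exchange
#' relaxation model `1/T1 = 1/T1_0 + r [Gd]`. Both are acquisition inputs:
#' defaults are a 1600 ms pre-contrast blood T1 at 3 T and a gadoteridol
#' relaxivity of 3.7 / mM / s.
#'
#' @param T1_0_ms Baseline (pre-contrast) T1, ms.
#' @param r_mM_s Relaxivity, 1/(mM s).
#' @return A `tbp_relaxation_params` list.
#' @export
relaxation_params <- function(T1_0_ms = 1600, r_mM_s = 3.7) {
  stopifnot(T1_0_ms > 0, r_mM_s > 0)
  structure(list(T1_0_ms = T1_0_ms, r_mM_s = r_mM_s),
            class = "tbp_relaxation_params")
}

#' Convert T1 to gadolinium concentration (and back)
#'
#' `[Gd] = (1/T1 - 1/T1_0) / r` with T1 in seconds; the inverse round-trips
#' exactly. A T1 longer than baseline yields a negative concentration, which
#' is flagged with a warning but returned.
#'
#' @param T1_ms T1 value(s), ms.
#' @param relax A [relaxation_params()].
#' @param conc_mM Concentration(s), mM.
#' @return Concentration in mM (`gd_from_t1`) or T1 in ms (`t1_from_gd`).
#' @export
gd_from_t1 <- function(T1_ms, relax = relaxation_params()) {
  stopifnot(all(T1_ms > 0))
  conc <- (1000 / T1_ms - 1000 / relax$T1_0_ms) / relax$r_mM_s
  if (any(conc < 0))
    warning("T1 above baseline: negative concentration returned")
  conc
}

#' @rdname gd_from_t1
#' @export
t1_from_gd <- function(conc_mM, relax = relaxation_params()) {
  1000 / (1000 / relax$T1_0_ms + relax$r_mM_s * conc_mM)
}

#' Concentration curve container
#'
#' @param t_s Strictly increasing, uniformly spaced times, s.
#' @param conc_mM Concentrations, mM.
#' @return A `tbp_conc_curve` tibble with columns `t_s`, `conc_mM`.
#' @export
conc_curve <- function(t_s, conc_mM) {
  stopifnot(length(t_s) == length(conc_mM), all(diff(t_s) > 0),
            all(is.finite(conc_mM)))
  structure(tibble::tibble(t_s = t_s, conc_mM = conc_mM),
            class = c("tbp_conc_curve", class(tibble::tibble())))
}

assert_uniform <- function(curve) {
  dt <- diff(curve$t_s)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("curve must be on a uniform time grid")
  dt[1]
}

#' Write / read a concentration curve as CSV
#'
#' @param curve A `tbp_conc_curve`.
#' @param path CSV path.
#' @return `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  conc_curve(df$t_s, df$conc_mM)
}

#' Map concentrations to steady-state signal through the dictionary
#'
#' Forward signal model for synthetic perfusion data: each concentration is
#' converted to T1 through the relaxation model and then to the
#' proton-density-normalized steady-state signal by interpolating the
#' dictionary amplitude curve. `conc_from_signal` inverts the chain by
#' amplitude matching on the dictionary grid followed by the relaxation
#' model.
#'
#' @param conc_mM Concentrations, mM.
#' @param dict A [build_dictionary()] result.
#' @param relax A [relaxation_params()].
#' @param slice Dictionary slice used for the amplitude curve.
#' @return Normalized signal values (`signal_from_conc`) or concentrations
#'   in mM (`conc_from_signal`).
#' @export
signal_from_conc <- function(conc_mM, dict, relax = relaxation_params(),
                             slice = dict$slice_bands[1]) {
  j <- match(slice, dict$slice_bands)
  T1 <- t1_from_gd(conc_mM, relax)
  approx(dict$T1_grid_ms, dict$amp[, j], T1, rule = 2)$y
}

#' @rdname signal_from_conc
#' @param signal Normalized signal values.
#' @export
conc_from_signal <- function(signal, dict, relax = relaxation_params(),
                             slice = dict$slice_bands[1]) {
  j <- match(slice, dict$slice_bands)
  amp <- dict$amp[, j]
  t1 <- dict$T1_grid_ms[vapply(signal, function(a)
    which.min(abs(amp - a)), integer(1))]
  gd_from_t1(t1, relax)
}
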