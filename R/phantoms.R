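# Synthetic fixtures: gamma-variate arterial input function, the flow-tube
# experiment bundle and a short-axis DCE phantom with ground-truth
# pharmacokinetics. All generators are deterministic given a seed.

#' Gamma-variate arterial input function
#'
#' First-pass bolus `A (t/tp)^a exp(a (1 - t/tp))` (peak value at `tp`) plus
#' an optional recirculation bump (a delayed, broadened gamma-variate),
#' normalized so the global maximum equals `peak_conc`. Default parameters
#' place the peak near 4.1 mM and the recirculation plateau near 1 mM, which
#' correspond to blood T1 of about 63 ms at peak and 234 ms post-injection
#' under the default relaxivity model (see [relaxation_params()]).
#'
#' @param t_s Time grid, s (uniform).
#' @param peak_time_s Time of the first-pass peak, s.
#' @param peak_conc_mM Peak concentration, mM.
#' @param shape Gamma shape parameter (dimensionless).
#' @param recirc_fraction Amplitude of the recirculation bump relative to the
#'   first pass (0 disables it).
#' @param recirc_delay_s Delay of the recirculation bump after the first-pass
#'   peak, s.
#' @return A [conc_curve()].
#' @export
gamma_variate_aif <- function(t_s = seq(0, 90, by = 1), peak_time_s = 12,
                              peak_conc_mM = 4.1, shape = 3,
                              recirc_fraction = 0.25,
                              recirc_delay_s = 18) {
  stopifnot(peak_conc_mM > 0, peak_time_s > 0, shape > 0,
            recirc_fraction >= 0)
  gv <- function(t, tp, a) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- (t[pos] / tp)^a * exp(a * (1 - t[pos] / tp))
    out
  }
  c1 <- gv(t_s, peak_time_s, shape)
  c2 <- recirc_fraction * gv(t_s - recirc_delay_s, peak_time_s * 1.6,
                             shape / 2)
  total <- c1 + c2
  conc_curve(t_s, total / max(total) * peak_conc_mM)
}

#' Flow-tube experiment bundle
#'
#' Configuration bundle for the flow-phantom study: a tube of T1-doped water
#' perpendicular to the slice stack, every combination of flow velocity and
#' transition-band option (`none`, one slice thickness, the full-bandwidth
#' band), ready to run through the replacement-inflow simulator or the
#' isochromat advection model.
#'
#' @param T1_ms Liquid T1, ms.
#' @param velocities_cm_s Flow velocities, cm/s.
#' @param geometry Base [slice_geometry()] (band thickness is overridden per
#'   option).
#' @param tb_thicknesses_mm Band options, mm (0 = none).
#' @return A tibble with one row per (velocity, band option): columns
#'   `T1_ms`, `velocity_cm_s`, `tb_thickness_mm`, plus list-columns
#'   `geometry` and `motion`.
#' @export
flow_tube_phantom <- function(T1_ms, velocities_cm_s,
                              geometry = slice_geometry(),
                              tb_thicknesses_mm = c(0, 7, 17.4)) {
  stopifnot(all(velocities_cm_s >= 0), T1_ms > 0)
  grid <- tidyr::expand_grid(velocity_cm_s = velocities_cm_s,
                             tb_thickness_mm = tb_thicknesses_mm)
  grid |>
    dplyr::mutate(
      T1_ms = T1_ms,
      geometry = purrr::map(.data$tb_thickness_mm, function(tb)
        slice_geometry(geometry$n_slices, geometry$slice_thickness_mm,
                       geometry$multiband_factor, tb)),
      motion = purrr::map(.data$velocity_cm_s, function(v)
        motion_model("replacement_inflow", velocity_cm_s = v))) |>
    dplyr::relocate("T1_ms")
}

disc_mask <- function(n, cx, cy, r) {
  x <- matrix(seq_len(n) - (n + 1) / 2, n, n)
  y <- t(x)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Short-axis DCE phantom with ground-truth pharmacokinetics
#'
#' A small short-axis frame: circular left-ventricular blood pool carrying
#' the arterial input function, an annular myocardium with normal-tissue
#' pharmacokinetics and an optional hypoperfused (defect) wedge. Tissue
#' curves are generated by the forward two-compartment model; optional
#' complex Gaussian noise is added on the signal scale via
#' [add_signal_noise()] after conversion.
#'
#' @param n Matrix size (default 24).
#' @param aif Blood [conc_curve()] (default [gamma_variate_aif()]).
#' @param normal [pk_params()] of normal myocardium.
#' @param defect Optional [pk_params()] of the defect region (NULL for
#'   none).
#' @param defect_angle_deg Angular extent c(from, to) of the defect wedge,
#'   degrees counterclockwise from +x (default the inferior wall, 240-300).
#' @return A `tbp_dce_phantom`: list with `conc` (x, y, time array), `t_s`,
#'   `masks` (`blood`, `myocardium`, `normal`, `defect`), `truth` tibble and
#'   `aif`.
#' @export
dce_sax_phantom <- function(n = 24, aif = gamma_variate_aif(),
                            normal = pk_params(1.0, 2.0, 0.05, 1),
                            defect = NULL,
                            defect_angle_deg = c(240, 300)) {
  blood <- disc_mask(n, 0, 0, n * 0.18)
  outer <- disc_mask(n, 0, 0, n * 0.42)
  inner <- disc_mask(n, 0, 0, n * 0.26)
  myo <- outer & !inner
  x <- matrix(seq_len(n) - (n + 1) / 2, n, n)
  y <- t(x)
  ang <- (atan2(y, x) * 180 / pi) %% 360
  defect_mask <- myo & ang >= defect_angle_deg[1] & ang < defect_angle_deg[2]
  if (is.null(defect)) defect_mask[] <- FALSE
  normal_mask <- myo & !defect_mask
  nt <- nrow(aif)
  conc <- array(0, c(n, n, nt))
  ct_norm <- forward_2cm(aif, normal)$conc_mM
  put <- function(mask, vals) {
    for (k in seq_len(nt)) {
      sl <- conc[, , k]
      sl[mask] <- vals[k]
      conc[, , k] <<- sl
    }
  }
  put(blood, aif$conc_mM)
  put(normal_mask, ct_norm)
  truth <- tibble::tibble(region = "normal", ktrans = normal$ktrans,
                          kep = normal$kep, vb = normal$vb,
                          dt_delay_s = normal$dt_delay_s)
  if (!is.null(defect)) {
    put(defect_mask, forward_2cm(aif, defect)$conc_mM)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      region = "defect", ktrans = defect$ktrans, kep = defect$kep,
      vb = defect$vb, dt_delay_s = defect$dt_delay_s))
  }
  structure(
    list(conc = conc, t_s = aif$t_s,
         masks = list(blood = blood, myocardium = myo,
                      normal = normal_mask, defect = defect_mask),
         truth = truth, aif = aif),
    class = "tbp_dce_phantom")
}

#' @export
print.tbp_dce_phantom <- function(x, ...) {
  cat(sprintf(
    "<tbp_dce_phantom> %d x %d x %d frames, %d myocardial pixels (%d defect)\n",
    dim(x$conc)[1], dim(x$conc)[2], dim(x$conc)[3],
    sum(x$masks$myocardium), sum(x$masks$defect)))
  invisible(x)
}

#' Add complex Gaussian noise to magnitude signals
#'
#' Adds independent Gaussian noise to the real and imaginary channels (the
#' input is taken as the real channel) and returns the magnitude, the noise
#' model of magnitude MR data. The level is an absolute standard deviation
#' on the signal scale (e.g. a fraction of the proton-density signal).
#'
#' @param signal Numeric vector/array of signal values.
#' @param sd Noise standard deviation per channel.
#' @param seed Integer seed (local to this call).
#' @return Magnitude signals with the same shape.
#' @export
add_signal_noise <- function(signal, sd, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
  if (is.null(dim(signal))) out else array(out, dim = dim(signal))
}
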