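# Longitudinal Bloch simulation of the ungated steady-state multiband
# sequence: slice profiles, the isochromat stepping kernel, T1 dictionaries
# and dictionary matching under motion.

#' Closed-form spoiled steady-state signal
#'
#' Longitudinal steady state of repeated excitations with perfect spoiling:
#' `sin(flip) * (1 - E1) / (1 - E1 cos(flip))`, `E1 = exp(-TR_eff / T1)`.
#' Serves as the analytic oracle for the stepping simulator (which must agree
#' for a static isochromat) and as the rectangular-profile dictionary of the
#' pool-model flow experiments.
#'
#' @param T1_ms Longitudinal relaxation time, ms.
#' @param TR_eff_ms Effective repetition time between a band's own
#'   excitations, ms (`n_groups * TR` for interleaved groups).
#' @param flip_deg Flip angle, degrees.
#' @return Signal as a fraction of M0.
#' @export
ernst_steady_state <- function(T1_ms, TR_eff_ms, flip_deg) {
  stopifnot(all(T1_ms > 0), TR_eff_ms > 0, all(flip_deg > 0))
  E1 <- exp(-TR_eff_ms / T1_ms)
  th <- flip_deg * pi / 180
  sin(th) * (1 - E1) / (1 - E1 * cos(th))
}

#' Default RF pulse pair of the reference protocol
#'
#' Late-asymmetric image-slice pulse and early-asymmetric transition-band
#' pulse sharing a 900 us duration; the band pulse bandwidth is scaled by the
#' geometry's band-to-slice thickness ratio (fixed slice-select gradient).
#' `peak_fraction` defaults are calibrated to the protocol's printed refocus
#' fractions (26.6% image, 86.7% band), i.e. a 540 us peak-B1 separation.
#'
#' @param geometry A [slice_geometry()].
#' @param duration_us Shared pulse duration, us.
#' @param tbw_img Image-pulse time-bandwidth product (default 4).
#' @param peak_fraction_img,peak_fraction_tb B1 peak positions.
#' @param apodization Window passed to [design_filtered_sinc()].
#' @return List with `img` and (if bands present) `tb` waveforms, plus the
#'   shared `gradient_mt_m`.
#' @export
protocol_pulses <- function(geometry = slice_geometry(), duration_us = 900,
                            tbw_img = 4, peak_fraction_img = 0.734,
                            peak_fraction_tb = 0.133,
                            apodization = "hamming") {
  bw_img <- tbw_img / (duration_us * 1e-6)
  img <- design_filtered_sinc(duration_us, bw_img, peak_fraction_img,
                              apodization)
  out <- list(img = img,
              gradient_mt_m = slice_gradient(bw_img,
                                             geometry$slice_thickness_mm))
  if (geometry$tb_thickness_mm > 0) {
    out$tb <- design_filtered_sinc(duration_us, bw_img * geometry$tb_bw_ratio,
                                   peak_fraction_tb, apodization)
  }
  out
}

#' Per-band flip-angle profiles for the simulator
#'
#' Evaluates each excited band's flip profile on a common fine z grid. With
#' `type = "small_tip"` the profiles are the small-tip Fourier profiles of
#' the protocol pulses (image pulse for slices, transition pulse for bands),
#' thresholded to compact support; `type = "ideal"` uses rectangular
#' profiles of the nominal thickness.
#'
#' @param params A [sequence_params()].
#' @param type `"small_tip"` (default) or `"ideal"`.
#' @param dz_mm Profile grid step, mm.
#' @param pulses Optional [protocol_pulses()] result to reuse.
#' @param support_threshold Relative amplitude below which the profile is
#'   zeroed (compact support for the stepping kernel).
#' @param guard_mm For `"ideal"` profiles, shrink each rectangular support
#'   by this much per side (0 keeps abutting bands contiguous).
#' @return A `tbp_band_profiles`: list with `z_mm` grid, `mat` (grid x band,
#'   relative amplitude with 1 at band center), `bands` ([band_table()]) and
#'   the nominal thicknesses.
#' @export
band_profiles <- function(params, type = c("small_tip", "ideal"),
                          dz_mm = 0.1, pulses = NULL,
                          support_threshold = 1e-2, guard_mm = 0) {
  type <- match.arg(type)
  geom <- params$geometry
  bands <- band_table(geom)
  halfspan <- 1.6 * max(bands$thickness_mm)
  # integer-index grid keeps cell positions reproducible across geometries
  i0 <- floor((min(bands$center_mm) - halfspan) / dz_mm)
  i1 <- ceiling((max(bands$center_mm) + halfspan) / dz_mm)
  z <- (i0:i1) * dz_mm
  mat <- matrix(0, length(z), nrow(bands))
  if (type == "ideal") {
    # guard_mm > 0 shrinks each support so abutting bands stay strictly
    # disjoint after the kernel's linear interpolation; the default keeps
    # supports contiguous (no unexcited cracks between bands)
    for (b in seq_len(nrow(bands))) {
      half <- max(bands$thickness_mm[b] / 2 - guard_mm, dz_mm)
      mat[, b] <- as.numeric(abs(z - bands$center_mm[b]) <= half + 1e-9)
    }
  } else {
    if (is.null(pulses)) pulses <- protocol_pulses(geom)
    shape_of <- function(w, thickness) {
      off <- seq(-halfspan, halfspan, by = dz_mm)
      pr <- small_tip_profile(w, pulses$gradient_mt_m, 1, off)
      s <- pr$flip_deg / max(pr$flip_deg)
      s[s < support_threshold] <- 0
      list(off = off, s = s)
    }
    shp_img <- shape_of(pulses$img, geom$slice_thickness_mm)
    shp_tb <- if (!is.null(pulses$tb)) shape_of(pulses$tb, geom$tb_thickness_mm)
    for (b in seq_len(nrow(bands))) {
      shp <- if (bands$kind[b] == "slice") shp_img else shp_tb
      mat[, b] <- approx(shp$off + bands$center_mm[b], shp$s, z,
                         yleft = 0, yright = 0)$y
    }
  }
  structure(list(z_mm = z, mat = mat, bands = bands, type = type,
                 dz_mm = dz_mm),
            class = "tbp_band_profiles")
}

sim_displacement <- function(motion, params) {
  t_ms <- (seq_len(params$n_excitations) - 1) * params$TR_ms
  motion_displacement(motion, t_ms)
}

#' Simulate per-band signals of the multiband sequence
#'
#' Steps the longitudinal magnetization of an isochromat ensemble through the
#' interleaved-group excitation pattern (group 1, group 2, ... separated by
#' TR; each transition band fires with its assigned group). At each
#' excitation every isochromat inside a firing band is saturated by
#' `cos(flip_eff(z))`, the band signal accumulates `Mz sin(flip_eff(z))`
#' (integral over z), then all isochromats relax toward M0 over TR under
#' perfect spoiling. Positions follow the motion model.
#'
#' @param params A [sequence_params()].
#' @param ensemble An [isochromat_ensemble()].
#' @param motion A [motion_model()] (not `replacement_inflow`; that kind is
#'   simulated by [simulate_pool_signals()]).
#' @param profiles A [band_profiles()] (default small-tip profiles).
#' @param flip_deg Flip angle override (e.g. the PD flip), degrees.
#' @return A `tbp_signal_series` tibble: one row per (band, its excitation)
#'   with `m` (global excitation index), `t_ms`, `band`, `kind`, `group`,
#'   `signal`. The final Mz and the raw matrix are kept as attributes.
#' @export
simulate_signals <- function(params, ensemble, motion = motion_model(),
                             profiles = NULL, flip_deg = params$flip_deg) {
  stopifnot(inherits(params, "tbp_sequence_params"),
            inherits(ensemble, "tbp_isochromat_ensemble"))
  if (motion$kind == "replacement_inflow")
    stop("use simulate_pool_signals() for the replacement inflow model")
  if (is.null(profiles)) profiles <- band_profiles(params)
  bands <- profiles$bands
  disp <- sim_displacement(motion, params)
  check_coverage(ensemble, profiles, disp)
  res <- cpp_bloch_sim(
    ensemble$z_mm, exp(-params$TR_ms / ensemble$T1_ms), ensemble$Mz,
    params$n_excitations, params$n_groups, as.integer(bands$group),
    rep(flip_deg * pi / 180, nrow(bands)),
    profiles$z_mm[1], profiles$z_mm[2] - profiles$z_mm[1], profiles$mat, disp)
  dz <- ensemble$z_mm[2] - ensemble$z_mm[1]
  sig <- res$signal * dz
  m <- seq_len(params$n_excitations)
  grp <- ((m - 1) %% params$n_groups) + 1
  out <- purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    sel <- grp == bands$group[b]
    tibble::tibble(m = m[sel], t_ms = (m[sel] - 1) * params$TR_ms,
                   band = bands$band[b], kind = bands$kind[b],
                   group = bands$group[b], signal = sig[sel, b])
  })
  structure(dplyr::arrange(out, .data$m, .data$band),
            class = c("tbp_signal_series", class(out)),
            params = params, motion = motion, flip_deg = flip_deg,
            mz_final = res$mz)
}

check_coverage <- function(ensemble, profiles, disp) {
  excited <- range(profiles$z_mm[rowSums(profiles$mat) > 0])
  lo <- excited[1] - max(disp)
  hi <- excited[2] - min(disp)
  if (min(ensemble$z_mm) > lo || max(ensemble$z_mm) < hi)
    stop("ensemble does not cover the excited region over the motion excursion")
  invisible(TRUE)
}

#' Wide matrix view of a signal series
#'
#' @param series A `tbp_signal_series`.
#' @return Matrix: one column per band, one row per that band's excitation.
#' @export
series_matrix <- function(series) {
  wide <- series |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = "k", names_from = "band",
                       values_from = "signal")
  as.matrix(wide[, -1, drop = FALSE])
}

#' @export
autoplot.tbp_signal_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t_ms / 1e3, y = .data$signal,
                               color = .data$band)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)", color = NULL)
}

#' Build a T1 dictionary by Bloch simulation
#'
#' One per-slice signal template per T1 grid value, simulated with the static
#' stepping kernel, the protocol's slice profiles and the interleaved group
#' timing, plus a matching proton-density template (PD flip) whose
#' steady-state value normalizes the atoms. The default grid spans 1-1500 ms
#' in 1 ms steps.
#'
#' @param T1_grid_ms Strictly increasing T1 grid, ms.
#' @param params A [sequence_params()].
#' @param profiles A [band_profiles()] (defaults to small-tip profiles).
#' @param spacing_mm Isochromat spacing, mm.
#' @param window_fraction Tail fraction of each template averaged to form the
#'   steady-state amplitude (default last half).
#' @return A `tbp_t1_dictionary`: list with `T1_grid_ms`, `atoms` (array
#'   excitation x T1 x slice), `ss`, `pd_ss` and `amp = ss / pd_ss`
#'   (T1 x slice matrices), `params`, `window_fraction`.
#' @export
build_dictionary <- function(T1_grid_ms = seq(1, 1500, by = 1),
                             params = sequence_params(), profiles = NULL,
                             spacing_mm = 0.25, window_fraction = 0.5) {
  stopifnot(length(T1_grid_ms) >= 1, all(diff(T1_grid_ms) > 0),
            all(T1_grid_ms > 0))
  if (is.null(profiles)) profiles <- band_profiles(params)
  geom <- params$geometry
  ens <- isochromat_ensemble(geom, T1_ms = 1000, spacing_mm = spacing_mm)
  bands <- profiles$bands
  nb <- nrow(bands)
  # static per-isochromat flip factors
  flip <- params$flip_deg * pi / 180
  pdflip <- params$pd_flip_deg * pi / 180
  p_at <- vapply(seq_len(nb), function(b)
    approx(profiles$z_mm, profiles$mat[, b], ens$z_mm,
           yleft = 0, yright = 0)$y, numeric(length(ens$z_mm)))
  keep <- which(bands$kind == "slice") - 1L
  dz <- ens$z_mm[2] - ens$z_mm[1]
  run <- function(fl) {
    a <- fl * p_at
    cpp_bloch_dict(T1_grid_ms, params$TR_ms, params$n_excitations,
                   params$n_groups, as.integer(bands$group),
                   sin(a) * (p_at > 0), cos(a), as.integer(keep)) * dz
  }
  atoms <- run(flip)
  pd_atoms <- run(pdflip)
  n_per <- dim(atoms)[1]
  win <- seq(floor(n_per * (1 - window_fraction)) + 1, n_per)
  tail_mean <- function(arr) apply(arr[win, , , drop = FALSE], c(2, 3), mean)
  ss <- tail_mean(atoms)
  pd_ss <- tail_mean(pd_atoms)
  structure(
    list(T1_grid_ms = T1_grid_ms, atoms = atoms, ss = ss, pd_ss = pd_ss,
         amp = ss / pd_ss, slice_bands = bands$band[keep + 1L],
         params = params, window_fraction = window_fraction),
    class = "tbp_t1_dictionary"
  )
}

#' @export
print.tbp_t1_dictionary <- function(x, ...) {
  cat(sprintf(
    "<tbp_t1_dictionary> %d atoms (T1 %g-%g ms), %d excitations/slice, %d slices\n",
    length(x$T1_grid_ms), min(x$T1_grid_ms), max(x$T1_grid_ms),
    dim(x$atoms)[1], dim(x$atoms)[3]))
  invisible(x)
}

#' Save / load a dictionary
#'
#' Serialized with R's native format (a hierarchical container holding the
#' atom array and the embedded sequence parameters).
#'
#' @param dict A `tbp_t1_dictionary`.
#' @param path File path.
#' @return `write_dictionary` returns `path` invisibly.
#' @export
write_dictionary <- function(dict, path) {
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) readRDS(path)
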