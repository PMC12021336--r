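# Parameter containers for the Bloch simulator: sequence timing, isochromat
# ensembles and through-plane motion models.

#' Sequence parameters of the ungated steady-state multiband protocol
#'
#' Defaults follow the reference protocol: TR 2.1 ms per excitation, 12
#' degree flip, multiband factor 3 in two interleaved groups (effective
#' per-slice repetition time `n_groups * TR`), 2 degree proton-density
#' reference flip, transition bands on.
#'
#' @param TR_ms Repetition time per excitation, ms.
#' @param flip_deg Excitation flip angle, degrees (0, 90).
#' @param pd_flip_deg Proton-density reference flip angle, degrees.
#' @param n_excitations Total excitations to simulate (all groups).
#' @param use_tb Excite transition bands?
#' @param geometry A [slice_geometry()]; its band thickness is zeroed when
#'   `use_tb = FALSE`.
#' @return A `tbp_sequence_params` list.
#' @export
sequence_params <- function(TR_ms = 2.1, flip_deg = 12, pd_flip_deg = 2,
                            n_excitations = 1428, use_tb = TRUE,
                            geometry = slice_geometry()) {
  stopifnot(TR_ms > 0, flip_deg > 0, flip_deg < 90, pd_flip_deg < flip_deg,
            n_excitations >= 1)
  if (!use_tb && geometry$tb_thickness_mm > 0)
    geometry <- slice_geometry(geometry$n_slices, geometry$slice_thickness_mm,
                               geometry$multiband_factor, 0)
  structure(
    list(TR_ms = TR_ms, flip_deg = flip_deg, pd_flip_deg = pd_flip_deg,
         n_excitations = n_excitations, use_tb = use_tb,
         Ns = geometry$multiband_factor, n_groups = geometry$n_groups,
         geometry = geometry),
    class = "tbp_sequence_params"
  )
}

#' @export
print.tbp_sequence_params <- function(x, ...) {
  cat(sprintf(
    "<tbp_sequence_params> TR %.2f ms, flip %g deg (PD %g deg), Ns=%d x %d groups, %d excitations, tb %s\n",
    x$TR_ms, x$flip_deg, x$pd_flip_deg, x$Ns, x$n_groups, x$n_excitations,
    if (x$use_tb) "on" else "off"))
  invisible(x)
}

#' Through-plane motion models
#'
#' * `static`: no motion.
#' * `sinusoidal`: rigid displacement `z(t) = A sin(2 pi HR/60 t + phase)`,
#'   emulating through-plane cardiac motion.
#' * `isochromat_flow`: uniform plug flow at `velocity` (positive moves tissue
#'   from the slice-`n` side toward slice 1); spins advect and fresh, fully
#'   relaxed spins enter upstream.
#' * `replacement_inflow`: the well-mixed pool model in which, each advection
#'   step, a fraction `v * dt / thickness` of a band's longitudinal
#'   magnetization is replaced by magnetization from the upstream band (fully
#'   recovered at the upstream edge).
#'
#' @param kind One of `"static"`, `"sinusoidal"`, `"isochromat_flow"`,
#'   `"replacement_inflow"`.
#' @param velocity_cm_s Flow speed for the flow kinds, cm/s.
#' @param heart_rate_bpm Sinusoidal rate, beats per minute.
#' @param amplitude_mm Sinusoidal peak displacement, mm.
#' @param phase_rad Sinusoidal phase at the first excitation (default 0).
#' @param replacement_step `"per_group"` (default: one advection per group
#'   cycle, duration `n_groups * TR`) or `"per_tr"`.
#' @return A `tbp_motion_model` list.
#' @export
motion_model <- function(kind = c("static", "sinusoidal", "isochromat_flow",
                                  "replacement_inflow"),
                         velocity_cm_s = 0, heart_rate_bpm = 120,
                         amplitude_mm = 0, phase_rad = 0,
                         replacement_step = c("per_group", "per_tr")) {
  kind <- match.arg(kind)
  replacement_step <- match.arg(replacement_step)
  stopifnot(velocity_cm_s >= 0, amplitude_mm >= 0)
  if (kind == "sinusoidal") stopifnot(heart_rate_bpm > 0)
  structure(
    list(kind = kind, velocity_cm_s = velocity_cm_s,
         heart_rate_bpm = heart_rate_bpm, amplitude_mm = amplitude_mm,
         phase_rad = phase_rad, replacement_step = replacement_step),
    class = "tbp_motion_model"
  )
}

#' Per-excitation rigid displacement of a motion model
#'
#' @param motion A `tbp_motion_model` (`static`, `sinusoidal` or
#'   `isochromat_flow`).
#' @param t_ms Excitation times, ms.
#' @return Displacement in mm at each time.
#' @export
motion_displacement <- function(motion, t_ms) {
  switch(motion$kind,
    static = rep(0, length(t_ms)),
    sinusoidal = motion$amplitude_mm *
      sin(2 * pi * motion$heart_rate_bpm / 60 * t_ms / 1e3 + motion$phase_rad),
    isochromat_flow = motion$velocity_cm_s * 10 * t_ms / 1e3,
    stop("replacement_inflow has no isochromat displacement; use simulate_pool_signals()")
  )
}

#' Isochromat ensemble spanning a geometry and its motion excursion
#'
#' Uniformly spaced isochromats covering the excited region plus the motion
#' excursion plus a margin, all at equilibrium (`Mz = 1`).
#'
#' @param geometry A [slice_geometry()].
#' @param T1_ms Longitudinal relaxation time, ms (scalar or per-isochromat).
#' @param motion A `tbp_motion_model`; flow/oscillation extends the covered
#'   range (`excursion_mm` can override it).
#' @param duration_ms Simulation duration used to size the flow fetch, ms.
#' @param spacing_mm Isochromat spacing, mm (default 0.25).
#' @param margin_mm Extra margin on both ends, mm (default 10).
#' @param excursion_mm Explicit excursion override, mm.
#' @param profiles Optional [band_profiles()]; when given, the covered range
#'   is based on the actual profile support (which extends beyond the
#'   nominal band edges through the transition regions) instead of the
#'   nominal geometry.
#' @return A `tbp_isochromat_ensemble`: list with `z_mm`, `Mz`, `T1_ms`.
#' @export
isochromat_ensemble <- function(geometry, T1_ms, motion = motion_model(),
                                duration_ms = 0, spacing_mm = 0.25,
                                margin_mm = 10, excursion_mm = NULL,
                                profiles = NULL) {
  stopifnot(all(T1_ms > 0), spacing_mm > 0)
  if (!is.null(profiles)) {
    supp <- profiles$z_mm[rowSums(profiles$mat) > 0]
    lo <- min(supp)
    hi <- max(supp)
  } else {
    bt <- band_table(geometry)
    lo <- min(bt$center_mm - bt$thickness_mm / 2)
    hi <- max(bt$center_mm + bt$thickness_mm / 2)
  }
  if (is.null(excursion_mm)) {
    excursion_mm <- switch(motion$kind,
      static = 0,
      sinusoidal = motion$amplitude_mm,
      isochromat_flow = motion$velocity_cm_s * 10 * duration_ms / 1e3,
      replacement_inflow = 0)
  }
  # flow moves tissue toward +z (slice 1); fetch extends the upstream (-z) end
  lo2 <- lo - excursion_mm - margin_mm
  hi2 <- hi + (if (motion$kind == "sinusoidal") excursion_mm else 0) + margin_mm
  z <- seq(lo2, hi2, by = spacing_mm)
  n <- length(z)
  structure(
    list(z_mm = z, Mz = rep(1, n), T1_ms = rep(T1_ms, length.out = n)),
    class = "tbp_isochromat_ensemble"
  )
}

#' @export
print.tbp_isochromat_ensemble <- function(x, ...) {
  cat(sprintf("<tbp_isochromat_ensemble> %d isochromats, z in [%.1f, %.1f] mm\n",
              length(x$z_mm), min(x$z_mm), max(x$z_mm)))
  invisible(x)
}
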