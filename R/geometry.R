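# Slice-stack geometry: Ns slices per group, n_groups interleaved groups and
# one transition band abutting each end of the imaged region.

#' Slice and transition-band geometry
#'
#' Builds the excited-region geometry: `n_slices` contiguous image slices
#' (slice 1 at the most positive z, matching a flow direction "from slice
#' `n_slices` to slice 1" for positive velocity) split into `n_groups`
#' interleaved simultaneous-multislice groups of `multiband_factor` slices,
#' plus one transition band abutting each outer slice. Group membership
#' interleaves slices (group 1 = slices 1, 3, 5 for two groups), the top band
#' is excited with group 1 and the bottom band with group 2, so every band is
#' excited at the same rate as any image slice.
#'
#' @param n_slices Number of image slices (default 6).
#' @param slice_thickness_mm Slice thickness, mm (default 7).
#' @param multiband_factor Slices per simultaneous excitation, Ns (default 3).
#' @param tb_thickness_mm Transition-band thickness, mm (default 17.4; use 0
#'   for no bands).
#' @return A `tbp_slice_geometry`: list with slice/band centers, thicknesses,
#'   group assignments and the band-to-slice bandwidth ratio.
#' @examples
#' slice_geometry()
#' @export
slice_geometry <- function(n_slices = 6, slice_thickness_mm = 7,
                           multiband_factor = 3, tb_thickness_mm = 17.4) {
  stopifnot(n_slices >= 1, slice_thickness_mm > 0, multiband_factor >= 1,
            tb_thickness_mm >= 0)
  if (n_slices %% multiband_factor != 0)
    stop("n_slices must be a multiple of multiband_factor")
  n_groups <- n_slices / multiband_factor
  centers <- ((n_slices + 1) / 2 - seq_len(n_slices)) * slice_thickness_mm
  groups <- ((seq_len(n_slices) - 1) %% n_groups) + 1
  use_tb <- tb_thickness_mm > 0
  tb_centers <- if (use_tb) {
    c(top = centers[1] + (slice_thickness_mm + tb_thickness_mm) / 2,
      bottom = centers[n_slices] - (slice_thickness_mm + tb_thickness_mm) / 2)
  } else numeric(0)
  tb_groups <- if (use_tb) c(top = 1, bottom = n_groups) else integer(0)
  structure(
    list(
      n_slices = n_slices, slice_thickness_mm = slice_thickness_mm,
      multiband_factor = multiband_factor, n_groups = n_groups,
      slice_centers_mm = centers, slice_groups = groups,
      tb_thickness_mm = tb_thickness_mm, tb_centers_mm = tb_centers,
      tb_groups = tb_groups,
      tb_bw_ratio = if (use_tb) tb_thickness_mm / slice_thickness_mm else 0
    ),
    class = "tbp_slice_geometry"
  )
}

#' @export
print.tbp_slice_geometry <- function(x, ...) {
  cat(sprintf(
    "<tbp_slice_geometry> %d x %.1f mm slices (Ns=%d, %d groups), bands %.1f mm\n",
    x$n_slices, x$slice_thickness_mm, x$multiband_factor, x$n_groups,
    x$tb_thickness_mm
  ))
  invisible(x)
}

#' Band table of a geometry
#'
#' All excited bands (image slices then transition bands) as a tibble with
#' center, thickness, group and a band label. This is the band ordering used
#' by the Bloch simulator.
#'
#' @param geometry A `tbp_slice_geometry`.
#' @return Tibble with columns `band`, `kind`, `center_mm`, `thickness_mm`,
#'   `group`.
#' @export
band_table <- function(geometry) {
  stopifnot(inherits(geometry, "tbp_slice_geometry"))
  sl <- tibble::tibble(
    band = paste0("slice_", seq_len(geometry$n_slices)),
    kind = "slice",
    center_mm = geometry$slice_centers_mm,
    thickness_mm = geometry$slice_thickness_mm,
    group = geometry$slice_groups
  )
  if (geometry$tb_thickness_mm > 0) {
    tb <- tibble::tibble(
      band = paste0("tb_", names(geometry$tb_centers_mm)),
      kind = "tb",
      center_mm = unname(geometry$tb_centers_mm),
      thickness_mm = geometry$tb_thickness_mm,
      group = unname(geometry$tb_groups)
    )
    sl <- dplyr::bind_rows(sl, tb)
  }
  sl
}
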