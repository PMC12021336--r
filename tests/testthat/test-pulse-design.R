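test_that("filtered sinc peak sits at the requested fraction and sets the refocus area", {
  # a wide-band pulse accommodates the full asymmetry range
  for (p in seq(0.1, 0.9, by = 0.05)) {
    w <- design_filtered_sinc(900, 12000, p)
    expect_lte(abs(w$peak_time_us - p * 900), w$dwell_us)
    t_at_max <- w$t_us[which.max(Mod(w$samples))]
    expect_lte(abs(t_at_max - w$peak_time_us), w$dwell_us)
    expect_equal(refocus_fraction(w), 1 - p, tolerance = 1e-9)
  }
  expect_equal(refocus_fraction(design_filtered_sinc(900, 4444.4, 0.5)), 0.5)
})

test_that("protocol pulse pair reproduces the printed refocus fractions and peak separation", {
  pl <- ref_pulses()
  expect_equal(refocus_fraction(pl$img), 0.266, tolerance = 1e-6)
  expect_equal(refocus_fraction(pl$tb), 0.867, tolerance = 1e-6)
  expect_equal(pl$img$asymmetry, "late")
  expect_equal(pl$tb$asymmetry, "early")
  sep <- pl$img$peak_time_us - pl$tb$peak_time_us
  expect_lt(abs(sep - 540), 2)
})

test_that("extreme peak fractions that truncate the main lobe are rejected", {
  expect_error(design_filtered_sinc(900, 4444.4, 0.2), "too extreme")
  expect_error(design_filtered_sinc(900, 1000, 0.5), "main lobe")
})

test_that("spectral FWHM is within 10% of the requested bandwidth", {
  pl <- ref_pulses()
  expect_lt(abs(spectral_fwhm(pl$img) - pl$img$bandwidth_hz) /
              pl$img$bandwidth_hz, 0.1)
  expect_lt(abs(spectral_fwhm(pl$tb) - pl$tb$bandwidth_hz) /
              pl$tb$bandwidth_hz, 0.1)
})

test_that("band thickness scales with bandwidth ratio at fixed gradient", {
  expect_equal(band_thickness(7, 1), 7)
  expect_equal(round(band_thickness(7, 2.49), 1), 17.4)
  expect_equal(round(17.4 / 7, 2), 2.49)
})

test_that("waveform text serialization round-trips", {
  w <- design_filtered_sinc(900, 4444.4, 0.734)
  path <- withr::local_tempfile(fileext = ".txt")
  write_waveform(w, path)
  w2 <- read_waveform(path)
  expect_equal(w2$samples, w$samples, tolerance = 1e-12)
  expect_equal(w2$peak_time_us, w$peak_time_us)
  expect_equal(w2$asymmetry, "late")
})

test_that("composite multiband pulse is linear with coherent energy scaling", {
  w <- design_filtered_sinc(900, 4444.4, 0.734)
  single <- compose_multiband(list(w), 0, 14.9)
  expect_equal(single$samples, w$samples, tolerance = 1e-12)
  tripled <- compose_multiband(list(w, w, w), c(0, 0, 0), 14.9)
  expect_equal(tripled$energy, 9 * rf_energy(w), tolerance = 1e-9)
  # linearity: scaling inputs scales the composite
  w2 <- w
  w2$samples <- 2 * w$samples
  comp1 <- compose_multiband(list(w, w), c(-7, 7), 14.9)
  comp2 <- compose_multiband(list(w2, w2), c(-7, 7), 14.9)
  expect_equal(comp2$samples, 2 * comp1$samples, tolerance = 1e-12)
})

test_that("composite spectrum shows a pass-band at each programmed slice offset", {
  pl <- ref_pulses()
  g <- pl$gradient_mt_m
  offsets <- c(-7, 0, 7, 29.7)
  comp <- compose_multiband(list(pl$img, pl$img, pl$img, pl$tb), offsets, g)
  sp <- rf_spectrum(comp)
  f_expect <- offsets * 1e-3 * gamma_hz_per_mt() * g
  for (f0 in f_expect) {
    near <- abs(sp$f_hz - f0) < 1500
    far <- abs(sp$f_hz - f0) > 8000 & abs(sp$f_hz) < 25000 &
      !Reduce(`|`, lapply(f_expect, function(fe) abs(sp$f_hz - fe) < 8000))
    expect_gt(max(Mod(sp$H[near])), 3 * max(Mod(sp$H[far])))
  }
})

test_that("mismatched sampling grids are rejected in composition", {
  w1 <- design_filtered_sinc(900, 4444.4, 0.734)
  w2 <- design_filtered_sinc(1000, 4444.4, 0.734)
  expect_error(compose_multiband(list(w1, w2), c(0, 7), 14.9), "sampling")
})

test_that("small-tip profile mirrors pulse symmetry and bandwidth ratio", {
  z <- seq(-25, 25, by = 0.1)
  sym <- design_filtered_sinc(900, 4444.4, 0.5)
  pr <- small_tip_profile(sym, 14.9, 10, z)
  expect_equal(pr$flip_deg, rev(pr$flip_deg), tolerance = 1e-6)
  expect_equal(max(pr$flip_deg), 10, tolerance = 1e-2)
  pl <- ref_pulses()
  fwhm <- function(w) {
    p <- small_tip_profile(w, pl$gradient_mt_m, 10, z)
    diff(range(z[p$flip_deg >= max(p$flip_deg) / 2]))
  }
  ratio <- fwhm(pl$tb) / fwhm(pl$img)
  expect_lt(abs(ratio - 2.49) / 2.49, 0.05)
})

test_that("rectangular envelope yields a sinc-shaped small-tip profile", {
  rect <- structure(
    list(samples = as.complex(rep(1, 901)), t_us = 0:900, duration_us = 900,
         peak_time_us = 450, bandwidth_hz = 1111, dwell_us = 1,
         asymmetry = "symmetric"),
    class = "tbp_rf_waveform")
  z <- seq(-30, 30, by = 0.25)
  pr <- small_tip_profile(rect, 14.9, 10, z)
  f <- z * 1e-3 * gamma_hz_per_mt() * 14.9
  expected <- abs(sin(pi * f * 900e-6) / (pi * f * 900e-6))
  expected[f == 0] <- 1
  expect_lt(max(abs(pr$flip_deg / 10 - expected)), 0.01)
})

test_that("gradient dephasing attenuation follows the closed form and quadrature", {
  z <- seq(-8.7, 8.7, by = 0.001)
  rect_band <- tibble::tibble(z_mm = z, flip_deg = rep(1, length(z)))
  g <- 14.9
  expect_equal(dephasing_attenuation(rect_band, 0, g), 1)
  # closed form |sin(Phi/2)/(Phi/2)| for a rectangular band
  for (frac in c(0.1, 0.3, 0.6)) {
    area <- frac * g * 900e-6
    phi <- 2 * pi * gamma_hz_per_mt() * area * 17.4e-3
    expect_lt(abs(dephasing_attenuation(rect_band, frac, g) -
                    abs(sin(phi / 2) / (phi / 2))), 5e-4)
  }
  # non-increasing up to the first null
  first_null_frac <- 1 / (gamma_hz_per_mt() * g * 900e-6 * 17.4e-3)
  fr <- seq(0, first_null_frac, length.out = 15)
  att <- vapply(fr, function(f) dephasing_attenuation(rect_band, f, g),
                numeric(1))
  expect_true(all(diff(att) < 1e-9))
  # realistic band profile vs fine-grid quadrature oracle
  pl <- ref_pulses()
  zp <- seq(-15, 15, by = 0.05)
  prof <- small_tip_profile(pl$tb, pl$gradient_mt_m, 12, zp)
  frac <- 540 / 900
  area <- frac * pl$gradient_mt_m * 900e-6
  phase <- 2 * pi * gamma_hz_per_mt() * area * zp * 1e-3
  oracle <- abs(sum(prof$flip_deg * exp(1i * phase))) / sum(prof$flip_deg)
  expect_equal(dephasing_attenuation(prof, frac, pl$gradient_mt_m),
               oracle, tolerance = 1e-10)
  expect_lt(oracle, 0.05)  # the unrefocused moment strongly dephases the band
})
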