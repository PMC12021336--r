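test_that("closed-form steady state has the right limits", {
  expect_equal(ernst_steady_state(234, 4.2, 1e-9), 0, tolerance = 1e-10)
  expect_lt(ernst_steady_state(1e9, 4.2, 12), 1e-6)  # saturation limit
  # longer T1 means more saturation, hence less signal
  t1s <- c(50, 100, 400, 1200)
  expect_true(all(diff(ernst_steady_state(t1s, 4.2, 12)) < 0))
})

test_that("static simulation converges to the closed-form steady state", {
  T1 <- 234
  n_exc <- 2 * ceiling(5 * T1 / 4.2)
  params <- sequence_params(n_excitations = n_exc)
  prof <- band_profiles(params, "ideal")
  ens <- isochromat_ensemble(params$geometry, T1)
  s <- simulate_signals(params, ens, motion_model(), prof)
  dz <- ens$z_mm[2] - ens$z_mm[1]
  ernst <- ernst_steady_state(T1, 2 * params$TR_ms, params$flip_deg)
  for (b in c(paste0("slice_", 1:6), "tb_top", "tb_bottom")) {
    j <- match(b, prof$bands$band)
    w <- approx(prof$z_mm, prof$mat[, j], ens$z_mm, yleft = 0, yright = 0)$y
    pred <- ernst * sum(w) * dz     # closed form weighted over the profile
    last <- tail(s$signal[s$band == b], 1)
    expect_lt(abs(last - pred) / pred, 1e-3)
  }
})

test_that("with disjoint supports, slice signals are identical with and without bands", {
  p_tb <- sequence_params(n_excitations = 200, use_tb = TRUE)
  p_no <- sequence_params(n_excitations = 200, use_tb = FALSE)
  ens <- isochromat_ensemble(p_tb$geometry, 300)
  # a guard gap makes the rectangular supports strictly disjoint
  s_tb <- simulate_signals(p_tb, ens, motion_model(),
                           band_profiles(p_tb, "ideal", guard_mm = 0.3))
  s_no <- simulate_signals(p_no, ens, motion_model(),
                           band_profiles(p_no, "ideal", guard_mm = 0.3))
  for (b in paste0("slice_", 1:6)) {
    expect_equal(s_tb$signal[s_tb$band == b], s_no$signal[s_no$band == b],
                 tolerance = 1e-14)
  }
})

test_that("longitudinal magnetization stays within physical bounds under all motions", {
  params <- sequence_params(n_excitations = 300)
  prof <- band_profiles(params, "ideal")
  motions <- list(
    motion_model(),
    motion_model("sinusoidal", heart_rate_bpm = 120, amplitude_mm = 7),
    motion_model("isochromat_flow", velocity_cm_s = 20))
  for (mot in motions) {
    ens <- isochromat_ensemble(params$geometry, 100, mot,
                               duration_ms = 300 * params$TR_ms,
                               profiles = prof)
    s <- simulate_signals(params, ens, mot, prof)
    mz <- attr(s, "mz_final")
    expect_true(all(mz >= -1 & mz <= 1))
    expect_true(all(is.finite(s$signal)))
  }
})

test_that("an ensemble that misses the motion excursion is rejected", {
  params <- sequence_params(n_excitations = 100)
  prof <- band_profiles(params, "ideal")
  ens <- isochromat_ensemble(params$geometry, 300, margin_mm = 0.5)
  mot <- motion_model("sinusoidal", heart_rate_bpm = 120, amplitude_mm = 10)
  expect_error(simulate_signals(params, ens, mot, prof), "cover")
})

test_that("spins flowing in receive the guaranteed number of band excitations", {
  # track upstream spins through the entry transition band: an entering spin
  # must be excited at least floor(band / (v * group period)) times inside
  # the band before it can reach an imaged slice
  params <- sequence_params(n_excitations = 2000)
  prof <- band_profiles(params, "ideal")
  P_ms <- params$n_groups * params$TR_ms
  tb <- prof$bands[prof$bands$band == "tb_bottom", ]
  m <- seq_len(params$n_excitations)
  grp <- ((m - 1) %% params$n_groups) + 1
  for (v_cm_s in c(5, 15, 30)) {
    stopifnot(v_cm_s <= tb$thickness_mm / (P_ms / 1e3) / 10)
    mot <- motion_model("isochromat_flow", velocity_cm_s = v_cm_s)
    disp <- motion_displacement(mot, (m - 1) * params$TR_ms)
    guaranteed <- floor(tb$thickness_mm / (v_cm_s * 10 * P_ms / 1e3))
    for (z0 in tb$center_mm - tb$thickness_mm / 2 - c(1, 5, 20)) {
      z <- z0 + disp
      w <- approx(prof$z_mm, prof$mat[, match(tb$band, prof$bands$band)],
                  z, yleft = 0, yright = 0)$y
      n_in_band <- sum(w > 0 & grp == tb$group)
      expect_gte(n_in_band, guaranteed)
    }
  }
})

test_that("a one-point dictionary atom equals the direct simulation", {
  params <- sequence_params(n_excitations = 200)
  prof <- band_profiles(params, "ideal")
  dict <- build_dictionary(300, params, prof)
  ens <- isochromat_ensemble(params$geometry, 300)
  s <- simulate_signals(params, ens, motion_model(), prof)
  expect_equal(dict$atoms[, 1, 1], s$signal[s$band == "slice_1"],
               tolerance = 1e-12)
})

test_that("normalized steady-state amplitude decreases monotonically in T1", {
  params <- sequence_params(n_excitations = 1000)
  prof <- band_profiles(params, "ideal")
  dict <- build_dictionary(seq(50, 2000, by = 25), params, prof)
  for (j in seq_along(dict$slice_bands)) {
    expect_true(all(diff(dict$amp[, j]) < 0))
  }
})

test_that("dictionaries reject a non-monotone grid and round-trip through disk", {
  expect_error(build_dictionary(c(100, 50), sequence_params(n_excitations = 10)),
               "T1_grid_ms")
  d <- small_dict()
  path <- withr::local_tempfile(fileext = ".rds")
  write_dictionary(d, path)
  d2 <- read_dictionary(path)
  expect_equal(d2$atoms, d$atoms)
  expect_equal(d2$T1_grid_ms, d$T1_grid_ms)
})
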