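test_that("golden-angle ray geometry follows the canonical increment", {
  r1 <- golden_angle_rays(1, 65)
  expect_equal(r1$angles_rad, 0)
  ga <- 180 * (sqrt(5) - 1) / 2
  r6 <- golden_angle_rays(6, 65)
  expect_equal(r6$angles_rad * 180 / pi, ((0:5) * ga) %% 180,
               tolerance = 1e-10)
  d <- diff(golden_angle_rays(40, 65)$angles_rad * 180 / pi) %% 180
  expect_true(all(abs(d - ga %% 180) < 1e-9))
  # spokes are symmetric through the k-space center
  expect_equal(r6$kr, -rev(r6$kr))
  # block mode repeats each angle for a full phase-cycling period
  rb <- golden_angle_rays(12, 65, excitations_per_angle = 6)
  expect_equal(rb$angles_rad, rep(c(0, ga * pi / 180), each = 6))
})

test_that("the multiband radial forward model is linear and reduces correctly", {
  n <- 32
  ph <- image_phantom(n, 2)
  M <- 24
  rays <- golden_angle_rays(M, n + 1)
  sch <- phase_schedule(2, M)
  full <- forward_group_kspace(ph$slices, ph$tb, sch, rays)
  no_tb <- forward_group_kspace(ph$slices, NULL, sch, rays)
  zero_tb <- forward_group_kspace(ph$slices, matrix(0, n, n), sch, rays)
  expect_equal(no_tb$data, zero_tb$data, tolerance = 1e-12)
  # all-zero slices leave only the band-phased band spokes
  zs <- list(matrix(0, n, n), matrix(0, n, n))
  only_tb <- forward_group_kspace(zs, ph$tb, sch, rays)
  raw_tb <- forward_group_kspace(list(ph$tb, zs[[2]]), NULL,
                                 phase_schedule(2, M, "off"), rays)
  expect_equal(only_tb$data, sweep(raw_tb$data, 2, sch$tb, `*`),
               tolerance = 1e-10)
  # linearity in the image
  doubled <- forward_group_kspace(lapply(ph$slices, function(x) 2 * x),
                                  ph$tb, sch, rays)
  expect_equal(doubled$data - no_tb$data, full$data, tolerance = 1e-9)
})

test_that("a single slice is recovered by demodulated adjoint reconstruction", {
  ph <- image_phantom(64, 1)
  rays <- golden_angle_rays(128, 65)
  sch <- phase_schedule(1, 128, "off")
  ks <- forward_group_kspace(ph$slices, NULL, sch, rays)
  rec <- reconstruct_slice(ks, 1)
  expect_lt(recon_nrmse(rec, ph$slices[[1]], fov_mask(64)), 0.1)
})

test_that("ray-count multiples of the multiband factor are enforced", {
  ph <- image_phantom(16, 3)
  rays <- golden_angle_rays(10, 17)
  sch <- phase_schedule(3, 10)
  ks <- forward_group_kspace(ph$slices, ph$tb, sch, rays)
  expect_error(reconstruct_slice(ks, 1), "multiple")
})

test_that("artifact energy is a normalized relative error", {
  x <- matrix(rnorm(64), 8, 8) + 0i
  expect_equal(artifact_energy(x, x), 0)
  expect_equal(artifact_energy(2 * x, x), 1, tolerance = 1e-12)
  expect_error(artifact_energy(x, 0 * x), "zero-norm")
})

test_that("residual band artifact localizes on slice 1 and is nulled by band spoiling", {
  n <- 32
  Ns <- 3
  M <- 2 * Ns * 20
  ph <- image_phantom(n, Ns)
  rays <- golden_angle_rays(M, n + 1, excitations_per_angle = 2 * Ns)
  energies <- function(mode) {
    sch <- phase_schedule(Ns, M, mode)
    with_tb <- forward_group_kspace(ph$slices, ph$tb, sch, rays)
    without <- forward_group_kspace(ph$slices, NULL, sch, rays)
    vapply(seq_len(Ns), function(b) {
      rw <- reconstruct_slice(with_tb, b)
      r0 <- reconstruct_slice(without, b)
      c(rel = artifact_energy(rw, r0), abs2 = sum(Mod(rw - r0)^2))
    }, numeric(2))
  }
  off <- energies("off")
  expect_gt(off["abs2", 1] / sum(off["abs2", ]), 0.99)
  spoiled <- energies("eq_spoil")
  expect_true(all(spoiled["rel", ] < 1e-10))
  # spoiling strictly reduces the artifact relative to the unspoiled case
  expect_true(all(spoiled["rel", ] < off["rel", 1]))
})

test_that("slowly drifting band amplitude is still suppressed a hundredfold", {
  n <- 32
  Ns <- 3
  M <- 2 * Ns * 20
  ph <- image_phantom(n, Ns)
  rays <- golden_angle_rays(M, n + 1, excitations_per_angle = 2 * Ns)
  # 1% linear drift per 2 Ns excitations
  drift <- 1 + 0.01 * (seq_len(M) - 1) / (2 * Ns)
  resid <- function(mode) {
    sch <- phase_schedule(Ns, M, mode)
    with_tb <- forward_group_kspace(ph$slices, ph$tb, sch, rays,
                                    tb_amplitude = drift)
    without <- forward_group_kspace(ph$slices, NULL, sch, rays)
    max(vapply(seq_len(Ns), function(b)
      artifact_energy(reconstruct_slice(with_tb, b),
                      reconstruct_slice(without, b)), numeric(1)))
  }
  expect_gt(resid("off") / resid("eq_spoil"), 100)
})
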