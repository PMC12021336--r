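test_that("the forward two-compartment model matches a direct convolution oracle", {
  aif <- gamma_variate_aif()
  p <- pk_params(0.8, 1.5, 0.07, 2)
  ct <- forward_2cm(aif, p)
  oracle <- conv_oracle(aif$t_s, aif$conc_mM, 0.8, 1.5, 0.07, 2)
  expect_equal(ct$conc_mM, oracle, tolerance = 1e-9)
})

test_that("forward model identities: pure vascular, impulse and constant input", {
  aif <- gamma_variate_aif()
  # Ktrans = 0 leaves only the delayed vascular term
  ct0 <- forward_2cm(aif, pk_params(0, 1, 0.12, 3))
  shifted <- approx(aif$t_s, aif$conc_mM, aif$t_s - 3, yleft = 0,
                    yright = tail(aif$conc_mM, 1))$y
  expect_equal(ct0$conc_mM, 0.12 * shifted, tolerance = 1e-12)
  # impulse input leaves the exponential residue (trapezoid boundary weight)
  n <- 61
  imp <- conc_curve(0:(n - 1), c(1, rep(0, n - 1)))
  cti <- forward_2cm(imp, pk_params(1.2, 3, 0, 0))
  expected <- (1.2 / 60) * exp(-(3 / 60) * imp$t_s) * 0.5
  expect_equal(cti$conc_mM[-1], expected[-1], tolerance = 1e-9)
  # constant input converges to c0 * Ktrans / kep
  cb <- conc_curve(seq(0, 900, by = 1), rep(1.5, 901))
  ctc <- forward_2cm(cb, pk_params(0.9, 2, 0, 0))
  expect_equal(tail(ctc$conc_mM, 1), 1.5 * 0.9 / 2, tolerance = 1e-3)
})

test_that("halving the time step changes the forward curve by less than half a percent", {
  p <- pk_params(1, 2, 0.05, 0)
  t1 <- seq(0, 90, by = 1)
  t2 <- seq(0, 90, by = 0.5)
  c1 <- forward_2cm(gamma_variate_aif(t1), p)
  c2 <- forward_2cm(gamma_variate_aif(t2), p)
  on1 <- c1$conc_mM[c1$t_s >= 5]
  on2 <- c2$conc_mM[match(c1$t_s, c2$t_s)][c1$t_s >= 5]
  expect_lt(max(abs(on1 - on2)) / max(on1), 0.005)
})

test_that("noiseless fits recover the generating parameters (inverse crime)", {
  aif <- gamma_variate_aif()
  for (truth in list(pk_params(1.0, 2.0, 0.05, 1),
                     pk_params(0.3, 0.8, 0.10, 0),
                     pk_params(2.0, 4.0, 0.02, 3))) {
    fit <- fit_2cm(forward_2cm(aif, truth), aif)
    expect_lt(abs(fit$params$ktrans - truth$ktrans) / truth$ktrans, 0.01)
    expect_lt(abs(fit$params$kep - truth$kep) / truth$kep, 0.01)
    expect_lt(abs(fit$params$vb - truth$vb) / max(truth$vb, 0.01), 0.01)
    expect_lt(abs(fit$params$dt_delay_s - truth$dt_delay_s), 0.1)
  }
})

test_that("a zero tissue curve yields a zero-flow fit with a warning", {
  aif <- gamma_variate_aif()
  expect_warning(fit <- fit_2cm(conc_curve(aif$t_s, aif$conc_mM * 0), aif),
                 "zero")
  expect_equal(fit$params$ktrans, 0)
  expect_equal(fit$params$vb, 0)
  expect_error(fit_2cm(conc_curve(aif$t_s, aif$conc_mM),
                       conc_curve(aif$t_s, aif$conc_mM * 0)), "blood")
})

test_that("fit objects expose broom-style tidiers", {
  aif <- gamma_variate_aif()
  fit <- fit_2cm(forward_2cm(aif, pk_params(1, 2, 0.05, 1)), aif)
  td <- tidy(fit)
  expect_equal(td$term, c("ktrans", "kep", "vb", "dt_delay"))
  expect_equal(td$estimate[1], 1, tolerance = 0.01)
  gl <- glance(fit)
  expect_lt(gl$rmse, 1e-4)
  expect_true(gl$converged)
})

test_that("pixel-wise maps are uniform on a uniform phantom and robust to outliers", {
  aif <- gamma_variate_aif(seq(0, 60, by = 1))
  ct <- forward_2cm(aif, pk_params(1, 2, 0.05, 0))
  n <- 8
  mask <- matrix(TRUE, n, n)
  movie <- array(rep(ct$conc_mM, each = n * n), c(n, n, length(aif$t_s)))
  maps <- ktrans_map(movie, aif$t_s, aif, mask, fit_delay = FALSE)
  expect_lt(sd(maps$ktrans[mask]) / mean(maps$ktrans[mask]), 0.02)
  expect_equal(mean(maps$ktrans_raw[mask]), 1, tolerance = 0.01)
  # single corrupted pixel is removed by the median filter
  movie2 <- movie
  movie2[4, 4, ] <- movie2[4, 4, ] * 5
  maps2 <- ktrans_map(movie2, aif$t_s, aif, mask, fit_delay = FALSE)
  expect_gt(maps2$ktrans_raw[4, 4], 3)
  expect_equal(maps2$ktrans[4, 4], 1, tolerance = 0.05)
  expect_error(ktrans_map(movie, aif$t_s, aif, mask & FALSE), "empty mask")
})

test_that("two-region phantoms recover their regional flows", {
  ph <- dce_sax_phantom(n = 20, defect = pk_params(0.3, 1.0, 0.03, 1))
  maps <- ktrans_map(ph$conc, ph$t_s, ph$aif, ph$masks$myocardium)
  nm <- mean(maps$ktrans_raw[ph$masks$normal])
  dm <- mean(maps$ktrans_raw[ph$masks$defect])
  expect_lt(abs(nm - 1.0), 0.05)
  expect_lt(abs(dm - 0.3), 0.05 * 0.3 + 0.02)
})

test_that("AHA 16-segment summaries respect symmetry and rotation", {
  n <- 40
  x <- matrix(seq_len(n) - (n + 1) / 2, n, n)
  r <- sqrt(x^2 + t(x)^2)
  mask <- r >= 8 & r <= 15
  uniform <- matrix(2, n, n)
  s <- aha16_summary(uniform, mask, "basal", insertion_angle_deg = 90)
  expect_equal(s$segment, 1:6)
  expect_true(all(abs(s$mean - 2) < 1e-12))
  # rotating the insertion by 60 degrees permutes the segment values
  grad <- atan2(t(x), x)
  s0 <- aha16_summary(grad, mask, "basal", insertion_angle_deg = 0)
  s60 <- aha16_summary(grad, mask, "basal", insertion_angle_deg = 60)
  expect_equal(s60$mean[1:5], s0$mean[2:6], tolerance = 1e-9)
  # apical level has four segments with the AHA numbering offset
  sa <- aha16_summary(uniform, mask, "apical")
  expect_equal(sa$segment, 13:16)
  expect_error(aha16_summary(uniform, mask & FALSE, "mid"), "empty")
})

test_that("an inferior defect depresses only the inferior segments", {
  ph <- dce_sax_phantom(n = 24, defect = pk_params(0.3, 1.0, 0.03, 1),
                        defect_angle_deg = c(240, 300))
  maps <- ktrans_map(ph$conc, ph$t_s, ph$aif, ph$masks$myocardium,
                     fit_delay = FALSE)
  s <- aha16_summary(maps$ktrans_raw, ph$masks$myocardium, "mid",
                     insertion_angle_deg = 120)
  # the defect wedge (240-300 deg) is the third segment from the insertion
  lows <- s$mean[s$segment == 9]
  highs <- s$mean[s$segment != 9]
  expect_lt(max(lows), min(highs) - 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_bullseye_json(s, path)
  back <- jsonlite::read_json(path)
  expect_equal(sort(as.integer(names(back))), 7:12)
})
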