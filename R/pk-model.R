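# Two-compartment pharmacokinetic model: forward convolution, nonlinear
# least-squares fitting, pixel-wise Ktrans maps and AHA 16-segment bullseye
# summaries.

#' Pharmacokinetic parameters
#'
#' Parameters of the two-compartment model
#' `Ctis(t) = Cbld(t - dt) (x) Ktrans exp(-kep t) + Vb Cbld(t - dt)`:
#' transfer constant into the extravascular extracellular space (`Ktrans`,
#' reported as the myocardial blood-flow index), washout rate `kep`, vascular
#' fraction `Vb` and the blood-to-tissue delay `dt`.
#'
#' @param ktrans Transfer constant, 1/min.
#' @param kep Washout rate constant, 1/min.
#' @param vb Vascular fraction, dimensionless in \[0, 1\].
#' @param dt_delay_s Delay between blood and tissue enhancement, s.
#' @return A `tbp_pk_params` list.
#' @export
pk_params <- function(ktrans, kep, vb = 0, dt_delay_s = 0) {
  stopifnot(ktrans >= 0, kep >= 0, vb >= 0, vb <= 1, dt_delay_s >= 0)
  structure(list(ktrans = ktrans, kep = kep, vb = vb,
                 dt_delay_s = dt_delay_s),
            class = "tbp_pk_params")
}

shift_curve <- function(t_s, c_mM, dt_delay_s) {
  if (dt_delay_s == 0) return(c_mM)
  approx(t_s, c_mM, t_s - dt_delay_s, yleft = 0,
         yright = c_mM[length(c_mM)])$y
}

conv_exp <- function(t_s, cb, kep_per_s, dt) {
  # trapezoidal discretization of int cb(tau) exp(-kep (t - tau)) dtau
  n <- length(cb)
  out <- numeric(n)
  decay <- exp(-kep_per_s * dt)
  # running recursion: I_i = decay * I_{i-1} + dt/2 * (cb_i + decay * cb_{i-1})
  for (i in 2:n) out[i] <- decay * out[i - 1] +
      dt / 2 * (cb[i] + decay * cb[i - 1])
  out
}

#' Forward two-compartment tissue curve
#'
#' Discretized convolution (trapezoidal rule) of the delayed blood curve with
#' the exponential residue `Ktrans exp(-kep t)` plus the vascular term. Rate
#' constants are given in 1/min and converted to 1/s internally; time grids
#' are in seconds.
#'
#' @param cbld A [conc_curve()] blood (arterial input) curve on a uniform
#'   grid.
#' @param p A [pk_params()].
#' @return A [conc_curve()] tissue curve on the same grid.
#' @export
forward_2cm <- function(cbld, p) {
  stopifnot(inherits(p, "tbp_pk_params"))
  dt <- assert_uniform(cbld)
  cb <- shift_curve(cbld$t_s, cbld$conc_mM, p$dt_delay_s)
  ktrans_s <- p$ktrans / 60
  kep_s <- p$kep / 60
  ctis <- ktrans_s * conv_exp(cbld$t_s, cb, kep_s, dt) + p$vb * cb
  conc_curve(cbld$t_s, ctis)
}

# linear profile fit: given kep and delay, (Ktrans, Vb) solve a 2-column
# nonnegative least-squares problem
profile_fit <- function(y, t_s, cb, kep, dt) {
  x1 <- conv_exp(t_s, cb, kep / 60, dt) / 60
  X <- cbind(x1, cb)
  coef <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0))
  if (coef[1] < 0 || coef[2] < 0 || coef[2] > 1) {
    # constrained refits on the boundary
    cands <- list(
      c(max(0, sum(x1 * y) / sum(x1 * x1)), 0),
      c(0, min(1, max(0, sum(cb * y) / sum(cb * cb)))),
      c(pmax(0, coef[1]), min(1, pmax(0, coef[2]))))
    rss <- vapply(cands, function(cf)
      sum((y - X %*% cf)^2), numeric(1))
    coef <- cands[[which.min(rss)]]
  }
  res <- y - X %*% coef
  list(ktrans = coef[1], vb = coef[2], rss = sum(res^2))
}

best_kep <- function(y, t_s, cb, dt, kep_grid) {
  rss <- vapply(kep_grid, function(k) profile_fit(y, t_s, cb, k, dt)$rss,
                numeric(1))
  j <- which.min(rss)
  lo <- kep_grid[max(1, j - 1)]
  hi <- kep_grid[min(length(kep_grid), j + 1)]
  op <- optimize(function(lk) profile_fit(y, t_s, cb, exp(lk), dt)$rss,
                 c(log(lo), log(hi)))
  exp(op$minimum)
}

#' Fit the two-compartment model
#'
#' Nonlinear least squares over (`Ktrans`, `kep`, `Vb`) with the delay
#' handled by a grid search (0 to `dt_max_s` at the sample interval) plus
#' local refinement. For each candidate delay the fit is solved by profiling:
#' `kep` is optimized on a log grid while (`Ktrans`, `Vb`) solve the inner
#' linear problem; the best solution is then polished by
#' Levenberg-Marquardt least squares started from the profile solution and
#' from two fixed fallback initializations (`Ktrans, kep, Vb` =
#' 1, 2, 0.05 and 0.3, 0.5, 0.1).
#'
#' @param ctis Tissue [conc_curve()].
#' @param cbld Blood [conc_curve()] on the same grid.
#' @param dt_max_s Largest delay searched, s (default 5).
#' @param fit_delay Set `FALSE` to fix the delay at 0.
#' @param kep_grid Coarse washout-rate grid for profiling, 1/min.
#' @return A `tbp_pk_fit`: list with `params` ([pk_params()]), `rss`,
#'   `fitted` curve, `n`, `converged`. Supports [tidy()] and [glance()].
#' @export
fit_2cm <- function(ctis, cbld, dt_max_s = 5, fit_delay = TRUE,
                    kep_grid = exp(seq(log(0.02), log(30), length.out = 25))) {
  stopifnot(nrow(ctis) == nrow(cbld),
            max(abs(ctis$t_s - cbld$t_s)) < 1e-9)
  if (all(cbld$conc_mM == 0)) stop("blood curve is identically zero")
  dt <- assert_uniform(cbld)
  y <- ctis$conc_mM
  t_s <- ctis$t_s
  if (all(y == 0)) {
    warning("tissue curve is identically zero: returning a zero-flow fit")
    p <- pk_params(0, 0, 0, 0)
    return(structure(list(params = p, rss = 0,
                          fitted = conc_curve(t_s, y * 0), n = length(y),
                          converged = TRUE),
                     class = "tbp_pk_fit"))
  }
  delays <- if (fit_delay) seq(0, dt_max_s, by = dt) else 0
  eval_delay <- function(d) {
    cb <- shift_curve(t_s, cbld$conc_mM, d)
    kep <- best_kep(y, t_s, cb, dt, kep_grid)
    pf <- profile_fit(y, t_s, cb, kep, dt)
    list(d = d, kep = kep, ktrans = pf$ktrans, vb = pf$vb, rss = pf$rss)
  }
  fits <- lapply(delays, eval_delay)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  if (fit_delay && length(delays) > 1) {
    op <- optimize(function(d) {
      cb <- shift_curve(t_s, cbld$conc_mM, d)
      profile_fit(y, t_s, cb, best$kep, dt)$rss
    }, c(max(0, best$d - dt), min(dt_max_s, best$d + dt)))
    ref <- eval_delay(op$minimum)
    if (ref$rss < best$rss) best <- ref
  }
  # Levenberg-Marquardt polish with multi-start
  cb <- shift_curve(t_s, cbld$conc_mM, best$d)
  model <- function(ktrans, kep, vb)
    ktrans / 60 * conv_exp(t_s, cb, kep / 60, dt) + vb * cb
  starts <- list(c(best$ktrans, best$kep, best$vb),
                 c(1, 2, 0.05), c(0.3, 0.5, 0.1))
  polish <- function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ model(ktrans, kep, vb),
        start = list(ktrans = max(st[1], 1e-6), kep = max(st[2], 1e-3),
                     vb = max(st[3], 0)),
        lower = c(0, 1e-4, 0), upper = c(Inf, Inf, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(fit)
      list(ktrans = cf[["ktrans"]], kep = cf[["kep"]], vb = cf[["vb"]],
           rss = sum(stats::resid(fit)^2), ok = TRUE)
    }, error = function(e) list(rss = Inf, ok = FALSE))
  }
  pol <- lapply(starts, polish)
  pol_rss <- vapply(pol, `[[`, numeric(1), "rss")
  converged <- TRUE
  if (min(pol_rss) < best$rss) {
    pb <- pol[[which.min(pol_rss)]]
    best$ktrans <- pb$ktrans; best$kep <- pb$kep; best$vb <- pb$vb
    best$rss <- pb$rss
  } else if (all(!vapply(pol, `[[`, logical(1), "ok"))) {
    converged <- FALSE
  }
  p <- pk_params(best$ktrans, best$kep, min(1, max(0, best$vb)), best$d)
  structure(list(params = p, rss = best$rss,
                 fitted = forward_2cm(conc_curve(t_s, cbld$conc_mM), p),
                 n = length(y), converged = converged),
            class = "tbp_pk_fit")
}

#' @export
print.tbp_pk_fit <- function(x, ...) {
  cat(sprintf(
    "<tbp_pk_fit> Ktrans %.3f /min, kep %.3f /min, Vb %.3f, delay %.2f s (RSS %.3g, n=%d)\n",
    x$params$ktrans, x$params$kep, x$params$vb, x$params$dt_delay_s,
    x$rss, x$n))
  invisible(x)
}

#' @export
tidy.tbp_pk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ktrans", "kep", "vb", "dt_delay"),
    estimate = c(x$params$ktrans, x$params$kep, x$params$vb,
                 x$params$dt_delay_s),
    unit = c("1/min", "1/min", "fraction", "s"))
}

#' @export
glance.tbp_pk_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, rmse = sqrt(x$rss / x$n), n = x$n,
                 converged = x$converged)
}

#' @export
autoplot.tbp_pk_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(t_s = object$fitted$t_s, conc_mM = object$fitted$conc_mM,
                   what = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$conc_mM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "[Gd] (mM)",
                  title = sprintf("Ktrans = %.2f /min", object$params$ktrans))
}

median_filter_masked <- function(img, mask, size = 3) {
  h <- (size - 1) / 2
  out <- img
  nx <- nrow(img); ny <- ncol(img)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j]) next
    ii <- max(1, i - h):min(nx, i + h)
    jj <- max(1, j - h):min(ny, j + h)
    vals <- img[ii, jj][mask[ii, jj]]
    out[i, j] <- median(vals)
  }
  out
}

#' Pixel-wise Ktrans (and kep, Vb, delay) maps
#'
#' Fits the two-compartment model in every masked pixel of a concentration
#' movie against a common blood curve, then median-filters the Ktrans map
#' within the mask (3 x 3 neighborhood restricted to masked pixels).
#'
#' @param conc_movie 3-D array (x, y, time) of tissue concentrations, mM.
#' @param t_s Frame times, s.
#' @param cbld Blood [conc_curve()] on the same grid.
#' @param mask Logical matrix of pixels to fit.
#' @param median_filter Apply the 3 x 3 median filter to Ktrans?
#' @param ... Passed to [fit_2cm()] (e.g. `fit_delay = FALSE`).
#' @return A `tbp_pk_maps`: list of matrices `ktrans` (filtered),
#'   `ktrans_raw`, `kep`, `vb`, `dt_delay`, `rss` and the `mask`. Supports
#'   [tidy()].
#' @export
ktrans_map <- function(conc_movie, t_s, cbld, mask, median_filter = TRUE,
                       ...) {
  stopifnot(length(dim(conc_movie)) == 3, is.logical(mask))
  if (!any(mask)) stop("empty mask")
  nx <- dim(conc_movie)[1]; ny <- dim(conc_movie)[2]
  stopifnot(nrow(mask) == nx, ncol(mask) == ny)
  mk <- function() matrix(NA_real_, nx, ny)
  maps <- list(ktrans_raw = mk(), kep = mk(), vb = mk(), dt_delay = mk(),
               rss = mk())
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    fit <- fit_2cm(conc_curve(t_s, conc_movie[i, j, ]), cbld, ...)
    maps$ktrans_raw[i, j] <- fit$params$ktrans
    maps$kep[i, j] <- fit$params$kep
    maps$vb[i, j] <- fit$params$vb
    maps$dt_delay[i, j] <- fit$params$dt_delay_s
    maps$rss[i, j] <- fit$rss
  }
  maps$ktrans <- if (median_filter)
    median_filter_masked(maps$ktrans_raw, mask) else maps$ktrans_raw
  structure(c(maps, list(mask = mask)), class = "tbp_pk_maps")
}

#' @export
tidy.tbp_pk_maps <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  msk <- x$mask
  out <- tibble::tibble(
    ktrans = x$ktrans[msk], ktrans_raw = x$ktrans_raw[msk],
    kep = x$kep[msk], vb = x$vb[msk],
    dt_delay = x$dt_delay[msk], rss = x$rss[msk])
  out$x <- idx[, 1]
  out$y <- idx[, 2]
  dplyr::relocate(out, "x", "y")
}

#' @export
autoplot.tbp_pk_maps <- function(object, ...) {
  df <- tidy.tbp_pk_maps(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ktrans)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "Ktrans (1/min)")
}

#' AHA 16-segment summary of a parameter map
#'
#' Averages a map over the equiangular segments of the American Heart
#' Association 16-segment model: six segments for basal and mid-ventricular
#' slices, four for apical slices, advancing counterclockwise from the
#' anterior right-ventricular insertion angle. Segment numbers follow the
#' AHA convention (basal 1-6, mid 7-12, apical 13-16).
#'
#' @param map Parameter matrix.
#' @param mask Logical annular myocardium mask.
#' @param level `"basal"`, `"mid"` or `"apical"`.
#' @param insertion_angle_deg Angle of the anterior RV insertion point,
#'   degrees counterclockwise from the +x image axis.
#' @param center Optional c(x, y) ventricle center; defaults to the mask
#'   centroid.
#' @return Tibble with `segment` (AHA number), `mean`, `n`.
#' @export
aha16_summary <- function(map, mask, level = c("basal", "mid", "apical"),
                          insertion_angle_deg = 90, center = NULL) {
  level <- match.arg(level)
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(center)) center <- c(mean(idx[, 1]), mean(idx[, 2]))
  nseg <- if (level == "apical") 4L else 6L
  offset <- switch(level, basal = 0L, mid = 6L, apical = 12L)
  ang <- (atan2(idx[, 2] - center[2], idx[, 1] - center[1]) * 180 / pi -
            insertion_angle_deg) %% 360
  seg <- pmin(nseg, floor(ang / (360 / nseg)) + 1L)
  vals <- map[mask]
  out <- tibble::tibble(segment = seg + offset, value = vals) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  missing <- setdiff(offset + seq_len(nseg), out$segment)
  if (length(missing))
    stop("empty segment(s): ", paste(missing, collapse = ", "))
  out
}

#' Export AHA segment summaries as JSON
#'
#' @param summaries Tibble(s) from [aha16_summary()] (rows are segments).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_bullseye_json <- function(summaries, path) {
  df <- dplyr::bind_rows(summaries)
  obj <- setNames(as.list(df$mean), as.character(df$segment))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
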