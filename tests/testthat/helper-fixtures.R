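# Shared fixtures, built once per test run.

# protocol pulse pair at the reference geometry
ref_pulses <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- protocol_pulses(slice_geometry())
    cache
  }
})

# small dictionary on a coarse grid (static, ideal profiles) for unit tests
small_dict <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- sequence_params(n_excitations = 600)
      cache <<- build_dictionary(seq(60, 600, by = 20), params,
                                 band_profiles(params, "ideal"))
    }
    cache
  }
})

# independent trapezoidal convolution oracle (direct double sum)
conv_oracle <- function(t_s, cb, ktrans, kep, vb, dt_delay = 0) {
  dt <- t_s[2] - t_s[1]
  cbs <- approx(t_s, cb, t_s - dt_delay, yleft = 0,
                yright = cb[length(cb)])$y
  n <- length(t_s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tau <- t_s[seq_len(i)]
    integrand <- cbs[seq_len(i)] * exp(-(kep / 60) * (t_s[i] - tau))
    w <- rep(dt, i)
    w[c(1, i)] <- dt / 2
    if (i == 1) w <- 0
    out[i] <- (ktrans / 60) * sum(w * integrand) + vb * cbs[i]
  }
  out
}
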