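make_sine_recording <- function(freq, amp = 10, dur = 12, fs = 1000) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  bench_recording(time = t, pressure = 100 + amp * sin(2 * pi * freq * t),
                  flow = rep(0, length(t)), diameter = rep(24, length(t)))
}

test_that("the zero-phase low-pass preserves the passband and kills the stopband", {
  rec <- make_sine_recording(0.5)
  rec$pressure <- rep(123.4, nrow(rec)) # constant: DC gain 1
  out <- lowpass(rec)
  expect_lt(max(abs(out$pressure - 123.4)), 1e-9)
  # 0.5 Hz inflation signal passes essentially untouched
  rec <- make_sine_recording(0.5)
  out <- lowpass(rec)
  mid <- rec$time > 2 & rec$time < 10
  amp <- (max(out$pressure[mid]) - min(out$pressure[mid])) / 2
  expect_lt(abs(amp - 10) / 10, 0.01)
  # 150 Hz noise attenuated by more than 20 dB
  rec <- make_sine_recording(150)
  out <- lowpass(rec)
  amp150 <- (max(out$pressure[mid]) - min(out$pressure[mid])) / 2
  expect_lt(amp150 / 10, 10^(-20 / 20))
  expect_error(bench_recording(time = c(0, 1e-3, 3e-3), pressure = 1:3,
                               flow = 1:3, diameter = 1:3), "uniform")
})

test_that("bent_length matches a brute-force polyline and is monotone in deflection", {
  expect_identical(bent_length(150, 0), 150)
  w <- seq(0, 8, by = 1)
  L <- bent_length(150, w)
  expect_true(all(diff(L) > 0))
  expect_true(all(L >= 150))
  # 1e6-segment polyline summation oracle
  span <- 150; wmax <- 5
  x <- seq(0, span, length.out = 1e6 + 1)
  y <- wmax * 16 * x^2 * (span - x)^2 / span^4
  poly <- sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_lt(abs(bent_length(span, wmax) - poly), 1e-6)
})

test_that("volume adjustment reduces to raw integration without deflection and is odd in flow", {
  cv <- constant_da_curve(1.0e-3)
  proto <- bench_protocol(deflection = FALSE, mains_amplitude = 0,
                          pressure_noise_sd = 0, diameter_noise_sd = 0,
                          n_precond = 2, n_experimental = 3, seed = 5)
  rec <- gen_bench_recording(cv, proto)
  pv <- adjusted_pv_curve(rec)
  # no deflection channel activity: adjusted volume equals the raw integral
  rec0 <- rec
  rec0$deflection <- NULL
  pv0 <- adjusted_pv_curve(rec0)
  expect_equal(pv$ensemble$volume, pv0$ensemble$volume, tolerance = 1e-10)
  # reversing the pump flow inverts the volume increments
  recf <- rec0
  recf$flow <- -recf$flow
  pvf <- adjusted_pv_curve(recf)
  v <- pv0$ensemble$volume - pv0$ensemble$volume[1]
  vf <- pvf$ensemble$volume - pvf$ensemble$volume[1]
  expect_equal(vf, -v, tolerance = 1e-9)
})

test_that("a noiseless synthetic recording is inverted exactly by the pipeline", {
  truth_da <- 1.6e-3
  cv <- constant_da_curve(truth_da)
  proto <- bench_protocol(deflection = FALSE, mains_amplitude = 0,
                          pressure_noise_sd = 0, diameter_noise_sd = 0, seed = 3)
  rec <- gen_bench_recording(cv, proto)
  res <- distensibility_from_recording(rec)
  expect_lt(abs(res$Da_mean - truth_da) / truth_da, 0.005)
  # ten identical noiseless cycles: essentially zero spread (the residual
  # comes from discrete sample-to-bin assignment at segment edges)
  expect_lt(res$Da_sd / res$Da_mean, 5e-3)
  # mid-cycle radius recovered through the volume route within 1%
  pv <- adjusted_pv_curve(rec)
  ap <- cmgraft:::area_from_volume(pv$ensemble, pv$span, 100)
  R_rec <- sqrt(ap$area[ap$pressure == 120] / pi)
  R_true <- approx(cv$pressure, cv$radius, xout = 120)$y
  expect_lt(abs(R_rec - R_true) / R_true, 0.01)
  # rigid tube: distensibility indistinguishable from zero
  rigid <- pr_curve(seq(30, 220, 2), rep(12, 96))
  rres <- distensibility_from_recording(gen_bench_recording(rigid, proto))
  expect_lt(abs(rres$Da_mean), 1e-6)
})

test_that("pipeline distensibility is unbiased under nominal noise across truth levels", {
  for (truth_da in c(0.4e-3, 1.0e-3, 1.6e-3)) {
    rec <- gen_bench_recording(constant_da_curve(truth_da),
                               bench_protocol(seed = 17))
    res <- distensibility_from_recording(rec)
    expect_lt(abs(res$Da_mean - truth_da) / truth_da, 0.03)
    expect_lt(res$Da_sd / res$Da_mean, 0.05)
  }
})

test_that("the bending correction removes the elongation bias", {
  truth_da <- 1.0e-3
  cv <- constant_da_curve(truth_da)
  rec <- gen_bench_recording(cv, bench_protocol(deflection = TRUE,
                                                deflection_max = 8, seed = 9))
  with_corr <- distensibility_from_recording(rec)$Da_mean
  rec_no <- rec
  rec_no$deflection <- NULL
  without <- distensibility_from_recording(rec_no)$Da_mean
  expect_lt(abs(with_corr - truth_da) / truth_da, 0.02)
  expect_gt(without, with_corr) # uncorrected estimate is biased high
})

test_that("the pipeline is idempotent and insensitive to pre-filtering", {
  rec <- gen_bench_recording(constant_da_curve(1.2e-3), bench_protocol(seed = 4))
  r1 <- distensibility_from_recording(rec)
  r2 <- distensibility_from_recording(rec)
  expect_identical(r1$per_cycle, r2$per_cycle)
  r3 <- distensibility_from_recording(lowpass(rec))
  expect_equal(r3$Da_mean, r1$Da_mean, tolerance = 1e-12)
})
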