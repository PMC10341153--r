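test_that("transformation stresses shift linearly with temperature", {
  p <- nitinol_params()
  # identity at the reference temperature
  expect_equal(nitinol_transformation_stress(p, "s_AS", p$T_ref), p$sigma_s_AS)
  # hand evaluation of the Clausius-Clapeyron form
  p2 <- nitinol_params(sigma_s_AS = 400, C_AS = 6)
  expect_equal(nitinol_transformation_stress(p2, "s_AS", p2$T_ref + 10), 460)
  # all plateaus rise monotonically with temperature
  Ts <- seq(p$A_f + 1, p$M_d - 1, length.out = 10)
  for (br in c("s_AS", "f_AS", "s_SA", "f_SA")) {
    v <- nitinol_transformation_stress(p, br, Ts)
    expect_true(all(diff(v) > 0), info = br)
  }
  expect_error(nitinol_transformation_stress(p, "s_AS", p$M_d + 5),
               "superelastic window")
})

test_that("small-strain load-unload is purely austenitic and retraces", {
  p <- nitinol_params()
  small <- 0.8 * p$sigma_s_AS / p$E_A
  path <- nitinol_stress_path(p, c(0, small / 2, small, small / 2, 0), T = 37)
  expect_equal(path$stress, p$E_A * c(0, small / 2, small, small / 2, 0),
               tolerance = 1e-10)
  expect_equal(path$xi, rep(0, 5))
})

test_that("a full superelastic loop matches the flag-diagram corners and closes", {
  p <- nitinol_params()
  T <- 37
  # closed-form corner states of the flag diagram at T_ref
  e_y <- p$sigma_s_AS / p$E_A              # forward onset
  e_m <- p$sigma_f_AS / p$E_M + p$eps_L    # full transformation
  e_r <- p$sigma_s_SA / p$E_M + p$eps_L    # reverse onset on unloading
  e_f <- p$sigma_f_SA / p$E_A              # reverse finish
  up <- seq(0, e_m, length.out = 400)
  down <- seq(e_m, 0, length.out = 400)[-1]
  path <- nitinol_stress_path(p, c(up, down), T = T)
  stress_up <- approx(up, path$stress[seq_along(up)], xout = c(e_y, e_m))$y
  expect_lt(abs(stress_up[1] - p$sigma_s_AS), 3)
  expect_lt(abs(stress_up[2] - p$sigma_f_AS), 3)
  stress_down <- approx(rev(down), rev(path$stress[-seq_along(up)]),
                        xout = c(e_f, e_r))$y
  expect_lt(abs(stress_down[2] - p$sigma_s_SA), 3)
  expect_lt(abs(stress_down[1] - p$sigma_f_SA), 3)
  # loop closure: zero residual stress and strain, positive dissipated area
  n <- length(path$stress)
  expect_equal(path$stress[n], 0, tolerance = 1e-8)
  expect_equal(path$xi[n], 0, tolerance = 1e-10)
  area <- sum(diff(c(up, down)) *
                (path$stress[-1] + path$stress[-n]) / 2)
  expect_gt(area, 0)
})

test_that("the stress path is rate-independent under repeated points", {
  p <- nitinol_params()
  hist1 <- c(0, 0.01, 0.03, 0.05, 0.03, 0.01, 0)
  hist2 <- rep(hist1, each = 3) # duplicated samples, same sequence of states
  s1 <- nitinol_stress_path(p, hist1, T = 37)$stress
  s2 <- nitinol_stress_path(p, hist2, T = 37)$stress
  expect_equal(s2[seq(1, length(s2), by = 3)], s1, tolerance = 1e-12)
})

test_that("any monotone return to zero strain leaves no residual stress", {
  p <- nitinol_params()
  set.seed(7)
  for (i in 1:20) {
    peak <- runif(1, 0.002, 0.055)
    mid <- runif(1, 0, peak)
    hist <- c(seq(0, peak, length.out = 50),
              seq(peak, mid, length.out = 20),
              seq(mid, peak * runif(1, 0.8, 1), length.out = 20),
              seq(peak * 0.9, 0, length.out = 60))
    s <- nitinol_stress_path(p, hist, T = runif(1, 25, 50))$stress
    expect_equal(s[length(s)], 0, tolerance = 1e-6)
  }
})

test_that("heating shifts both plateaus by their own temperature slopes", {
  p <- nitinol_params()
  dT <- 10
  e_probe <- 0.02 # mid-plateau strain
  up <- seq(0, 0.05, length.out = 200)
  down <- seq(0.05, 0, length.out = 200)[-1]
  lo <- nitinol_stress_path(p, c(up, down), T = p$T_ref)
  hi <- nitinol_stress_path(p, c(up, down), T = p$T_ref + dT)
  # forward plateau onset stress rises by C_AS * dT
  onset <- function(path) {
    i <- which(path$xi > 1e-6)[1]
    path$stress[i - 1]
  }
  expect_lt(abs((onset(hi) - onset(lo)) - p$C_AS * dT), 5)
  # reverse plateau (probed on the unloading branch) rises by C_SA * dT
  rev_stress <- function(path) {
    i <- length(up) + which(path$xi[-seq_along(up)] < 0.5)[1]
    path$stress[i]
  }
  expect_lt(abs((rev_stress(hi) - rev_stress(lo)) - p$C_SA * dT), 5)
  expect_error(nitinol_stress_path(p, c(0, 0.2), T = 37), "superelastic range")
})
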