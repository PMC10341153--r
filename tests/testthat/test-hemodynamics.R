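test_that("compliance of a rigid tube is zero and of a linear vessel is exact", {
  P <- seq(50, 200, by = 1)
  rigid <- compliance_from_curve(pr_curve(P, rep(12, length(P))), 100)
  expect_equal(rigid$Ca, 0)
  expect_equal(rigid$Da, 0)
  # R(P) = R0 (1 + cP): A is quadratic in P, centered differences are exact;
  # pointwise Da = 2c / (1 + cP)
  c0 <- 1e-4
  cv <- pr_curve(P, 12 * (1 + c0 * P))
  res <- compliance_from_curve(cv, 100, mode = "pointwise")
  expect_equal(res$profile$Da[P == 100], 2 * c0 / (1 + c0 * 100),
               tolerance = 1e-6)
  # linear V(P): Cv constant equal to the slope (mm^3 -> mL)
  vol <- data.frame(pressure = P, volume = 5000 + 12 * P,
                    area = rep(400, length(P)))
  cvv <- compliance_from_curve(vol, 100)
  expect_equal(cvv$Cv, 12 / 1000, tolerance = 1e-9)
  expect_error(compliance_from_curve(cv, 300), "outside sampled range")
})

test_that("distensibility computation is invariant under unit round trips", {
  P <- seq(50, 200, by = 1)
  cv <- constant_da_curve(1.2e-3, pressures = P)
  direct <- compliance_from_curve(cv, 100)$Da
  # mm -> cm -> mm
  back <- compliance_from_curve(pr_curve(P, (cv$radius / 10) * 10), 100)$Da
  expect_equal(back, direct, tolerance = 1e-9)
})

test_that("a known analytic distensibility is recovered on a 151-point grid", {
  P <- seq(50, 200, by = 1)
  for (da in c(0.4e-3, 1.0e-3, 1.6e-3)) {
    res <- compliance_from_curve(constant_da_curve(da, pressures = P),
                                 100, mode = "pointwise")
    interior <- res$profile$Da[P > 50 & P < 200]
    expect_lt(max(abs(interior - da) / da), 0.005)
  }
})

test_that("Moens-Korteweg wave speed follows its square-root scalings", {
  v <- moens_korteweg_pwv(Einc = 0.5, h = 1, r = 10, rho = 1050)
  expect_equal(v, sqrt(0.5e6 * 1e-3 / (2 * 1e-2 * 1050)), tolerance = 1e-12)
  # quadrupling the structural stiffness Einc*h doubles PWV
  expect_equal(moens_korteweg_pwv(2, 1, 10) / moens_korteweg_pwv(0.5, 1, 10), 2)
  # doubling the radius divides PWV by sqrt(2)
  expect_equal(moens_korteweg_pwv(0.5, 1, 20), v / sqrt(2))
  expect_error(moens_korteweg_pwv(-1, 1, 10), "positive")
})

test_that("the Bramwell-Hill inverse-square law maps PWV to distensibility ratios", {
  expect_equal(pwv_distensibility_ratio(1), 1)
  expect_equal(pwv_distensibility_ratio(0.5), 4)
  # a 22% PWV reduction is a 1.64-fold distensibility increase
  expect_equal(pwv_distensibility_ratio(0.78), 1 / 0.78^2, tolerance = 1e-12)
  expect_equal(signif(pwv_distensibility_ratio(0.78), 2), 1.6)
})
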