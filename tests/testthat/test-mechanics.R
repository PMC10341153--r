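test_that("the ring restoring force vanishes at the shape-set radius and obeys beam scaling", {
  st <- default_stent()
  f <- ring_stiffness(st, T = 36)
  expect_equal(f(st$d / 2), 0)
  # pushes outward below d/2, resists above
  expect_gt(f(st$d / 2 - 0.5), 0)
  expect_lt(f(st$d / 2 + 0.5), 0)
  # doubling strut thickness scales the force by 8 at fixed small deflection
  # (I = w t^3 / 12; small excursion keeps the struts austenitic)
  st1 <- stent_design(d = 24, l = 12, s = 2, n = 12, w = 0.35, r = 0.05, t = 0.2)
  st2 <- stent_design(d = 24, l = 12, s = 2, n = 12, w = 0.35, r = 0.05, t = 0.4)
  dR <- 0.05
  F1 <- ring_stiffness(st1, T = 36)(12 - dR)
  F2 <- ring_stiffness(st2, T = 36)(12 - dR)
  expect_equal(F2 / F1, 8, tolerance = 1e-9)
  # per-ring force scales as 1/l^3 (fixed-guided beam); the axial smearing
  # by the ring pitch is factored out explicitly
  st3 <- stent_design(d = 24, l = 10, s = 2, n = 12, w = 0.35, r = 0.05, t = 0.2)
  st4 <- stent_design(d = 24, l = 20, s = 2, n = 12, w = 0.35, r = 0.05, t = 0.2)
  pitch <- function(s) sqrt(s$l^2 - (pi * s$d / (2 * s$n))^2) + s$s
  F3 <- ring_stiffness(st3, T = 36)(12 - dR) * pitch(st3)
  F4 <- ring_stiffness(st4, T = 36)(12 - dR) * pitch(st4)
  l_eff <- function(s) s$l - 2 * s$r
  expect_equal(F4 / F3, (l_eff(st3) / l_eff(st4))^3, tolerance = 1e-9)
  expect_error(f(24 * 1.31 / 2 + 3), "validity band")
})

test_that("the ring force is conservative on an elastic excursion cycle", {
  st <- default_stent()
  f <- ring_stiffness(st, T = 36)
  R <- seq(11.8, 12.3, length.out = 200)
  Fup <- f(R)
  work_up <- sum(diff(R) * (Fup[-1] + Fup[-length(Fup)]) / 2)
  Fdn <- f(rev(R))
  work_dn <- sum(diff(rev(R)) * (Fdn[-1] + Fdn[-length(Fdn)]) / 2)
  expect_equal(work_up + work_dn, 0, tolerance = 1e-12)
})

test_that("fabric tension is slack below engagement and matches the Ogden membrane beyond", {
  fab <- default_fabric()
  ps <- 1.10
  R_eng <- fab$D_nominal / (2 * ps)
  expect_lt(fabric_tension(fab, 0.9 * R_eng, ps), 1e-6)
  expect_lt(fabric_tension(fab, 0.99 * R_eng, ps), 1e-6)
  # 5% beyond engagement: closed-form incompressible Ogden membrane tube
  lam <- 1.05
  R <- lam * R_eng
  lr <- 1 / (lam * ps)
  og <- fab$ogden
  soft <- 1 - fab$temp_softening * (36 - fab$T_ref)
  sig <- sum(2 * soft * og$mu / og$alpha * (lam^og$alpha - lr^og$alpha))
  T_closed <- sig * fab$h / (lam * ps)
  expect_equal(fabric_tension(fab, R, ps, T = 36), T_closed, tolerance = 0.01)
  # tension is non-decreasing in radius
  Rg <- seq(0.8 * R_eng, 1.1 * R_eng, length.out = 300)
  expect_true(all(diff(fabric_tension(fab, Rg, ps)) >= -1e-12))
})

test_that("equilibrium radius matches limits, monotonicity and the dense-grid oracle", {
  asm <- default_assembly()
  # unloaded, slack fabric: the stent sits at its shape-set radius
  expect_equal(equilibrium_radius(asm, load_case(P = 0, prestretch = 1)),
               asm$stent$d / 2, tolerance = 1e-8)
  # radius is monotone in pressure
  cv <- pressure_radius_curve(asm, seq(0, 200, by = 10))
  expect_true(all(diff(cv$radius) > 0))
  # dense-grid force-balance oracle over random assemblies and loads
  set.seed(11)
  space <- default_design_space()
  n_ok <- 0
  while (n_ok < 30) {
    x <- space$lower + runif(6) * (space$upper - space$lower)
    names(x) <- space$names
    st <- stent_design(d = x["d"], l = x["l"], s = 2, n = x["n"],
                       w = x["w"], r = x["r"], t = x["t"])
    a <- graft_assembly(st, default_fabric())
    ld <- load_case(P = runif(1, 0, 150), T = runif(1, 21, 40), prestretch = 1.10)
    R_pkg <- tryCatch(equilibrium_radius(a, ld), error = function(e) NULL)
    if (is.null(R_pkg)) next
    expect_lt(abs(R_pkg - oracle_equilibrium(a, ld)), 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("radial compression makes the assembly more distensible than the bare fabric", {
  asm <- default_assembly()
  cv <- pressure_radius_curve(asm, seq(90, 110, by = 5))
  Da_asm <- compliance_from_curve(cv, 100)$Da
  fab <- default_fabric()
  P <- seq(90, 110, by = 5)
  Rf <- vapply(P, function(p) fabric_only_radius(fab, p), numeric(1))
  Da_fab <- compliance_from_curve(pr_curve(P, Rf), 100)$Da
  # leftward shift of the pressure-diameter curve: larger dR/dP at 100 mmHg
  expect_gt(Da_asm, 2 * Da_fab)
})

test_that("temperature and prestretch move the pressure-radius response in the observed directions", {
  asm <- default_assembly()
  p <- seq(50, 200, by = 2)
  cv36 <- pressure_radius_curve(asm, p, T = 36)
  cv21 <- pressure_radius_curve(asm, p, T = 21)
  # warmer fabric is softer: higher mid-range slope once fibers engage
  sel <- p >= 120 & p <= 180
  expect_gt(mean(diff(cv36$radius[sel])), mean(diff(cv21$radius[sel])) * 1.01)
  # pointwise distensibility in the engaged region is higher at 36 degC
  da130 <- function(cv) compliance_from_curve(cv, 130, "pointwise")$Da
  expect_gt(da130(cv36), da130(cv21))
  # longitudinal prestretch engages the fabric earlier and lowers the curve
  cv10 <- pressure_radius_curve(asm, p, prestretch = 1.0)
  expect_true(all(cv36$radius <= cv10$radius + 1e-9))
  expect_lt(cv36$radius[length(p)], cv10$radius[length(p)])
  expect_lt(da130(cv36), da130(cv10))
})

test_that("strut stress follows beam kinematics with the apex concentration factor", {
  st <- default_stent()
  zero <- strut_stress_estimate(st, excursion = 0, T = 36)
  expect_equal(zero$stress, 0)
  expect_equal(zero$strain, 0)
  # linear in excursion below the transformation onset
  e1 <- strut_stress_estimate(st, excursion = 0.2, T = 36)$stress
  e2 <- strut_stress_estimate(st, excursion = 0.4, T = 36)$stress
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
  # halving the apex radius raises the concentration-adjusted stress
  st_r <- stent_design(d = st$d, l = st$l, s = st$s, n = st$n, w = st$w,
                       r = st$r / 2, t = st$t)
  expect_gt(strut_stress_estimate(st_r, excursion = 0.4, T = 36)$stress, e2)
  expect_gt(kt_factor(st_r), kt_factor(st))
})

test_that("pressure-radius curves are continuous through the engagement transition", {
  asm <- default_assembly()
  p <- seq(100, 140, by = 0.5)
  cv <- pressure_radius_curve(asm, p)
  expect_true(all(diff(cv$radius) >= 0))
  # C0 across the knee: radius steps vanish with grid refinement
  pf <- seq(110, 130, by = 0.05)
  cvf <- pressure_radius_curve(asm, pf)
  expect_lt(max(diff(cvf$radius)), 0.15 * max(diff(cv$radius)))
  # approximately C1: no slope jump on the order of the slope itself
  slopes <- diff(cv$radius) / diff(p)
  expect_lt(max(abs(diff(slopes))), 0.75 * max(slopes))
  # a singleton grid agrees with the scalar solver
  single <- pressure_radius_curve(asm, 100)
  expect_equal(single$radius,
               equilibrium_radius(asm, load_case(P = 100)), tolerance = 1e-12)
})
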