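# Shared fixtures built in code.

fixture_ogden_truth <- function() ogden_params(c(60, 30, 10), c(8, 2, -2))

# Separable convex quadratic "distensibility" evaluator with a known
# interior argmin, on the default 6-factor space. Values sit on the same
# 1e-3 /mmHg scale as real distensibilities so relative convergence
# tolerances behave comparably.
fixture_quadratic_evaluator <- function(space = default_design_space()) {
  m <- space$lower + c(0.55, 0.40, 0.60, 0.45, 0.50, 0.35) *
    (space$upper - space$lower)
  a <- 0.5e-3 / ((space$upper - space$lower) / 4)^2
  list(f = function(x) {
    x <- x[space$names]
    1.6e-3 + sum(a * (as.numeric(x) - m)^2)
  },
  argmin = m, minimum = 1.6e-3, space = space)
}

# Dense-grid force-balance oracle for the equilibrium solver: three passes
# of 2001-point grids minimizing the squared net-force residual.
oracle_equilibrium <- function(assembly, load, c0 = 1) {
  stent <- assembly$stent
  fabric <- assembly$fabric
  P <- mmhg_to_mpa(load$P)
  F_stent <- ring_stiffness(stent, T = load$T, c0 = c0)
  g <- function(R)
    P * R + F_stent(R) - fabric_tension(fabric, R, load$prestretch, load$T)
  lo <- 0.75 * stent$d / 2
  hi <- stent$d / 2 * (1 + 0.3 * (1 - 1e-9))
  for (pass in 1:3) {
    R <- seq(lo, hi, length.out = 2001)
    i <- which.min(g(R)^2)
    h <- (hi - lo) / 2000
    lo <- max(lo, R[i] - h)
    hi <- min(hi, R[i] + h)
  }
  (lo + hi) / 2
}

# Fabric-only equilibrium (no stent): the uncompressed graft inflated on
# its own, solved on the hoop balance P*R = T_fabric(R).
fabric_only_radius <- function(fabric, P_mmhg, prestretch = 1.10, T = 36) {
  g <- function(R) mmhg_to_mpa(P_mmhg) * R - fabric_tension(fabric, R, prestretch, T)
  uniroot(g, c(fabric$D_nominal / 4, fabric$D_nominal), tol = 1e-10)$root
}
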