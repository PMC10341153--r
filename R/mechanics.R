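# Reduced-order axisymmetric graft mechanics.
#
# The two layers interact only through a shared internal radius R. Hoop
# equilibrium of the composite membrane (Laplace) reads
#     P * R + F_stent(R) = T_fabric(R)
# with P in MPa, R in mm, and both F_stent (outward restoring line tension
# of the z-stent rings, positive below the shape-set radius d/2) and
# T_fabric (hoop line tension of the engaged fabric) in N/mm.

# Effective bending length of a strut: the apex arcs stiffen the ends.
strut_eff_length <- function(stent) max(stent$l - 2 * stent$r, 0.5 * stent$l)

# Axial pitch of one stent ring: zig-zag height plus spacing.
ring_pitch <- function(stent) {
  half_chord <- pi * stent$d / (2 * stent$n)
  sqrt(stent$l^2 - half_chord^2) + stent$s
}

#' Stress-concentration factor at the stent apices
#'
#' Notch-type law `Kt = 1 + 0.5 * sqrt(t / r)`, equal to 1.5 at the `t = r`
#' reference, increasing as the apex radius `r` shrinks. Override with a
#' fixed number via the `Kt` argument of [strut_stress_estimate()].
#'
#' @param stent a [stent_design()].
#' @return dimensionless factor `>= 1`.
#' @export
kt_factor <- function(stent) 1 + 0.5 * sqrt(stent$t / stent$r)

# Apex bending strain of a strut for a radial excursion dR of the ring.
# The circumferential opening per z-period is 2*pi*dR/(2n) at the strut tip,
# bent over the effective strut length as a fixed-guided beam.
strut_bending_strain <- function(stent, excursion) {
  l_eff <- strut_eff_length(stent)
  3 * stent$t * (pi * abs(excursion) / stent$n) / l_eff^2
}

#' Strut stress and strain estimate for a radial excursion
#'
#' Outer-fiber bending stress at the apices from fixed-guided beam
#' kinematics, multiplied by the apex stress-concentration factor
#' ([kt_factor()]). The nominal bending strain maps to stress through the
#' monotone loading branch of the superelastic model, so the estimate
#' softens onto the transformation plateau when the excursion is large.
#'
#' @param stent a [stent_design()].
#' @param nitinol a [nitinol_params()]; defaults to the stent's material.
#' @param excursion radial excursion `|R - d/2|` in mm; must be within 30%
#'   of `d/2`.
#' @param T temperature (degrees C).
#' @param Kt optional fixed stress-concentration factor overriding
#'   [kt_factor()].
#' @return list with `stress` (MPa, concentration-adjusted), `strain`
#'   (concentration-adjusted total strain), and `nominal_stress` (MPa).
#' @export
strut_stress_estimate <- function(stent, nitinol = stent$material,
                                  excursion, T = 36, Kt = NULL) {
  if (any(abs(excursion) > 0.3 * stent$d / 2))
    stop("excursion outside the +/-30% validity band of the ring model")
  if (is.null(Kt)) Kt <- kt_factor(stent)
  eps_b <- strut_bending_strain(stent, excursion)
  sig_nom <- nitinol_monotone_stress(nitinol, eps_b, T)
  pl <- nitinol_plateaus(nitinol, T)
  sig_kt <- Kt * sig_nom
  strain <- ifelse(sig_nom <= pl$s_AS, sig_kt / nitinol$E_A, Kt * eps_b)
  list(stress = Kt * sig_nom, strain = strain, nominal_stress = sig_nom)
}

# Linearized (austenitic) line-tension stiffness of the stent, N/mm of
# tension per mm of radial displacement. Each z-period contributes two
# fixed-guided struts (stiffness 12*E*I/l_eff^3 each); the per-ring radial
# stiffness 2n * 12*E_A*I/l_eff^3 is spread over the circumference and the
# axial ring pitch.
ring_line_stiffness <- function(stent, E = stent$material$E_A, c0 = 1) {
  I <- stent$w * stent$t^3 / 12
  K_ring <- c0 * 2 * stent$n * 12 * E * I / strut_eff_length(stent)^3
  K_ring / (2 * pi * ring_pitch(stent))
}

#' Radial restoring response of the z-stent rings
#'
#' Returns a function mapping internal radius (mm) to the outward restoring
#' line tension (N/mm) of the stent: positive below the shape-set radius
#' `d/2` (the stent pushes outward), negative above it (the stent resists
#' expansion). The response is linear with the austenitic stiffness
#' `k ~ n * E_A * I / l^3` (with `I = w*t^3/12`) while the strut bending
#' stress is below the forward transformation onset, and follows the
#' transformation plateau of the superelastic model beyond it, through the
#' secant of the monotone loading branch.
#'
#' @param stent a [stent_design()].
#' @param nitinol a [nitinol_params()]; defaults to the stent's material.
#' @param T temperature (degrees C) within the superelastic window.
#' @param c0 dimensionless calibration constant of the beam model (default 1).
#' @return function of radius `R` (mm) returning line tension (N/mm);
#'   errors if called outside `|R - d/2| <= 0.3 * d/2`.
#' @examples
#' f <- ring_stiffness(default_stent(), T = 36)
#' f(12) # zero at the shape-set radius d/2
#' @export
ring_stiffness <- function(stent, nitinol = stent$material, T = 36, c0 = 1) {
  check_superelastic_window(nitinol, T)
  R0 <- stent$d / 2
  k <- ring_line_stiffness(stent, E = nitinol$E_A, c0 = c0)
  force(T)
  function(R) {
    dR <- R - R0
    if (any(abs(dR) > 0.3 * R0))
      stop(sprintf("radius %.3f mm outside the +/-30%% validity band of d/2 = %.3f mm",
                   R[which(abs(dR) > 0.3 * R0)[1]], R0))
    eps_b <- strut_bending_strain(stent, dR)
    # secant softening once the nominal strut stress enters transformation
    sec <- ifelse(eps_b > 0,
                  nitinol_monotone_stress(nitinol, eps_b, T) / (nitinol$E_A * eps_b),
                  1)
    -k * dR * sec
  }
}

#' Hoop line tension of the fabric layer
#'
#' The folded fabric carries no hoop load while the circumference `2*pi*R`
#' is below its engagement circumference
#' `C_engage = pi * D_nominal / prestretch^kappa`; beyond engagement the
#' tension is the incompressible Ogden membrane value
#' `T = sigma_theta * h / (lambda_theta * lambda_z)` with plane-stress
#' Cauchy hoop stress
#' `sigma_theta = sum_i (2*mu_i/alpha_i) * (lambda_theta^alpha_i - lambda_r^alpha_i)`,
#' `lambda_r = 1/(lambda_theta * lambda_z)`, and `lambda_z` the longitudinal
#' prestretch. The onset is smoothed by the C1 ramp
#' `1 - exp(-((lambda_theta - 1)/w)^2)` over the configured engagement
#' width `w`, emulating gradual fold unfolding; 5% beyond engagement the
#' ramp is within 0.2% of 1 for the default width.
#'
#' @param fabric a [fabric_layer()].
#' @param radius internal radius in mm (vectorized).
#' @param prestretch longitudinal stretch `>= 1`.
#' @param T temperature (degrees C); the Ogden moduli soften linearly by
#'   `temp_softening` per degree above the fabric's fit temperature.
#' @return hoop line tension, N/mm (non-negative).
#' @export
fabric_tension <- function(fabric, radius, prestretch = 1, T = fabric$T_ref) {
  if (any(radius <= 0)) stop("radius must be positive")
  soft <- max(1 - fabric$temp_softening * (T - fabric$T_ref), 0.5)
  C_eng <- pi * fabric$D_nominal / prestretch^fabric$kappa
  lam <- 2 * pi * radius / C_eng
  out <- numeric(length(lam))
  eng <- lam > 1
  if (any(eng)) {
    lt <- lam[eng]
    lr <- 1 / (lt * prestretch)
    sig <- numeric(length(lt))
    og <- fabric$ogden
    for (i in seq_along(og$mu)) {
      a <- og$alpha[i]
      sig <- sig + (2 * soft * og$mu[i] / a) * (lt^a - lr^a)
    }
    ramp <- 1 - exp(-((lt - 1) / fabric$smoothing_width)^2)
    out[eng] <- pmax(ramp * sig * fabric$h / (lt * prestretch), 0)
  }
  out
}

#' Equilibrium internal radius of the assembly under load
#'
#' Solves the hoop (Laplace) balance
#' `P*R + F_stent(R) = T_fabric(R)` by bracketed root finding
#' ([stats::uniroot]) on the net-force residual. At zero pressure with a
#' slack fabric the solution is the stent's shape-set radius `d/2`.
#'
#' @param assembly a [graft_assembly()].
#' @param load a [load_case()] (scalar pressure).
#' @param tol radius tolerance in mm (default 1e-9).
#' @param c0 passed to [ring_stiffness()].
#' @return internal radius in mm.
#' @examples
#' equilibrium_radius(default_assembly(), load_case(P = 0, prestretch = 1))
#' @export
equilibrium_radius <- function(assembly, load, tol = 1e-9, c0 = 1) {
  stopifnot(inherits(assembly, "graft_assembly"), inherits(load, "load_case"))
  if (length(load$P) != 1L) stop("`load$P` must be a single pressure")
  stent <- assembly$stent
  fabric <- assembly$fabric
  P <- mmhg_to_mpa(load$P)
  F_stent <- ring_stiffness(stent, T = load$T, c0 = c0)
  R0 <- stent$d / 2
  R_eng <- fabric$D_nominal / (2 * load$prestretch^fabric$kappa)
  g <- function(R)
    P * R + F_stent(R) - fabric_tension(fabric, R, load$prestretch, load$T)
  lo <- 0.75 * R0
  band_hi <- R0 * (1 + 0.3 * (1 - 1e-9))
  hi <- min(max(1.05 * R0, 1.10 * R_eng), band_hi)
  glo <- g(lo)
  if (glo < 0)
    stop(sprintf("no outward force at the lower bracket (P = %.3g mmHg)", load$P))
  ghi <- g(hi)
  it <- 0
  while (ghi > 0 && it < 60) {
    hi <- min(hi * 1.02, band_hi)
    ghi <- g(hi)
    it <- it + 1
    if (hi >= band_hi && ghi > 0)
      stop(sprintf(paste0(
        "equilibrium escapes the ring validity band at P = %.3g mmHg ",
        "(residual %.3g N/mm at R = %.3f mm): stent too soft for this load"),
        load$P, ghi, hi))
  }
  uniroot(g, c(lo, hi), tol = tol)$root
}

#' Pressure-radius curve of an assembly
#'
#' Vectorized [equilibrium_radius()] over a pressure grid, with the load
#' metadata recorded. Solver failures are annotated with the offending
#' pressure.
#'
#' @param assembly a [graft_assembly()].
#' @param pressures strictly increasing pressure grid, mmHg, within
#'   `[0, 250]`.
#' @param T temperature (degrees C).
#' @param prestretch longitudinal stretch.
#' @param ... passed to [equilibrium_radius()].
#' @return object of class `pressure_radius_curve`: data frame with columns
#'   `pressure` (mmHg) and `radius` (mm) plus `temperature`/`prestretch`
#'   attributes.
#' @export
pressure_radius_curve <- function(assembly, pressures = seq(0, 200, by = 2),
                                  T = 36, prestretch = 1.10, ...) {
  if (is.unsorted(pressures, strictly = TRUE))
    stop("`pressures` must be strictly increasing")
  radii <- vapply(pressures, function(p) {
    tryCatch(
      equilibrium_radius(assembly, load_case(P = p, T = T, prestretch = prestretch), ...),
      error = function(e)
        stop(sprintf("equilibrium failed at %.4g mmHg: %s", p, conditionMessage(e)),
             call. = FALSE))
  }, numeric(1))
  pr_curve(pressures, radii, T = T, prestretch = prestretch)
}

#' Construct a pressure-radius curve from samples
#'
#' @param pressure strictly increasing pressures (mmHg).
#' @param radius positive, non-decreasing internal radii (mm).
#' @param T,prestretch load metadata.
#' @return object of class `pressure_radius_curve`.
#' @export
pr_curve <- function(pressure, radius, T = NA_real_, prestretch = NA_real_) {
  if (is.unsorted(pressure, strictly = TRUE))
    stop("pressures must be strictly increasing")
  if (any(radius <= 0)) stop("radii must be positive")
  if (any(diff(radius) < -1e-9 * max(radius)))
    stop("radii must be non-decreasing in pressure")
  structure(data.frame(pressure = pressure, radius = radius),
            class = c("pressure_radius_curve", "data.frame"),
            temperature = T, prestretch = prestretch)
}

#' @export
print.pressure_radius_curve <- function(x, ...) {
  cat(sprintf(
    "Pressure-radius curve: %d points, %.4g-%.4g mmHg, R %.4g-%.4g mm (T = %s degC, prestretch = %s)\n",
    nrow(x), min(x$pressure), max(x$pressure), min(x$radius), max(x$radius),
    format(attr(x, "temperature")), format(attr(x, "prestretch"))))
  invisible(x)
}
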