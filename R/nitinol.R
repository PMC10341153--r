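#' Superelastic nitinol parameters
#'
#' Parameters of a one-dimensional, flag-shaped (Auricchio-style) superelastic
#' model with linear hardening on the transformation plateaus and no
#' plasticity. Transformation stresses are stored at a reference temperature
#' and shifted linearly with temperature (Clausius-Clapeyron-type slopes
#' `C_AS`, `C_SA`). The stent operates superelastically only between the
#' austenite finish temperature `A_f` and the martensite deformation
#' temperature `M_d`.
#'
#' Defaults are plausible values for medical-grade superelastic nitinol
#' tubing; they are engineering stand-ins, not fitted to any specific
#' material lot. `C_SA` and `A_f` are chosen consistently so that the
#' reverse-finish plateau extrapolates to zero near `A_f` and remains
#' positive at room temperature.
#'
#' @param E_A austenite Young modulus (MPa).
#' @param E_M martensite Young modulus (MPa).
#' @param sigma_s_AS,sigma_f_AS forward (austenite-to-martensite)
#'   transformation start/finish stresses at `T_ref` (MPa).
#' @param sigma_s_SA,sigma_f_SA reverse transformation start/finish stresses
#'   at `T_ref` (MPa).
#' @param eps_L maximum transformation strain (dimensionless).
#' @param C_AS,C_SA stress-temperature slopes for forward/reverse branches
#'   (MPa per degree C).
#' @param T_ref reference temperature for the stored stresses (degrees C).
#' @param A_f austenite finish temperature (degrees C).
#' @param M_d martensite deformation temperature (degrees C).
#' @return object of class `nitinol_params`.
#' @examples
#' nitinol_params()
#' @export
nitinol_params <- function(E_A = 60000, E_M = 30000,
                           sigma_s_AS = 400, sigma_f_AS = 500,
                           sigma_s_SA = 200, sigma_f_SA = 100,
                           eps_L = 0.04, C_AS = 6, C_SA = 4,
                           T_ref = 37, A_f = 12, M_d = 60) {
  if (E_A <= 0 || E_M <= 0) stop("moduli must be positive")
  if (!(sigma_f_AS > sigma_s_AS && sigma_s_AS > sigma_s_SA &&
        sigma_s_SA > sigma_f_SA && sigma_f_SA > 0))
    stop("plateau stresses must satisfy sigma_f_AS > sigma_s_AS > sigma_s_SA > sigma_f_SA > 0")
  if (eps_L <= 0 || eps_L > 0.12) stop("eps_L must be in (0, 0.12]")
  if (C_AS <= 0 || C_SA <= 0) stop("stress-temperature slopes must be positive")
  if (!(A_f < M_d)) stop("A_f must be below M_d")
  structure(list(E_A = E_A, E_M = E_M,
                 sigma_s_AS = sigma_s_AS, sigma_f_AS = sigma_f_AS,
                 sigma_s_SA = sigma_s_SA, sigma_f_SA = sigma_f_SA,
                 eps_L = eps_L, C_AS = C_AS, C_SA = C_SA,
                 T_ref = T_ref, A_f = A_f, M_d = M_d),
            class = "nitinol_params")
}

#' @export
print.nitinol_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Superelastic nitinol parameters (reference %.4g degC):\n",
    "  E_A = %.4g MPa, E_M = %.4g MPa, eps_L = %.4g\n",
    "  forward plateau %.4g -> %.4g MPa (C_AS = %.3g MPa/degC)\n",
    "  reverse plateau %.4g -> %.4g MPa (C_SA = %.3g MPa/degC)\n",
    "  superelastic window: A_f = %.4g degC to M_d = %.4g degC\n"),
    x$T_ref, x$E_A, x$E_M, x$eps_L,
    x$sigma_s_AS, x$sigma_f_AS, x$C_AS,
    x$sigma_s_SA, x$sigma_f_SA, x$C_SA, x$A_f, x$M_d))
  invisible(x)
}

check_superelastic_window <- function(params, T) {
  if (any(T < params$A_f | T > params$M_d))
    stop(sprintf(
      "temperature %.3g degC outside the superelastic window [%.3g, %.3g]",
      T[which(T < params$A_f | T > params$M_d)[1]], params$A_f, params$M_d))
  invisible(TRUE)
}

#' Temperature-shifted transformation stress
#'
#' Linear Clausius-Clapeyron-type shift of a stored plateau stress:
#' `sigma(T) = sigma(T_ref) + C * (T - T_ref)` with `C = C_AS` for the
#' forward branches and `C = C_SA` for the reverse branches.
#'
#' @param params a [nitinol_params()] object.
#' @param which one of `"s_AS"`, `"f_AS"`, `"s_SA"`, `"f_SA"`.
#' @param T temperature in degrees C, inside `[A_f, M_d]`.
#' @return stress in MPa (floored at a small positive value so that reverse
#'   plateaus remain physical near `A_f`).
#' @examples
#' p <- nitinol_params(sigma_s_AS = 400, C_AS = 6)
#' nitinol_transformation_stress(p, "s_AS", p$T_ref + 10) # 460 MPa
#' @export
nitinol_transformation_stress <- function(params,
                                          which = c("s_AS", "f_AS", "s_SA", "f_SA"),
                                          T) {
  which <- match.arg(which)
  check_superelastic_window(params, T)
  ref <- switch(which,
                s_AS = params$sigma_s_AS, f_AS = params$sigma_f_AS,
                s_SA = params$sigma_s_SA, f_SA = params$sigma_f_SA)
  C <- if (grepl("AS$", which)) params$C_AS else params$C_SA
  pmax(ref + C * (T - params$T_ref), 1e-6)
}

# All four plateaus at once, as a list.
nitinol_plateaus <- function(params, T) {
  list(s_AS = nitinol_transformation_stress(params, "s_AS", T),
       f_AS = nitinol_transformation_stress(params, "f_AS", T),
       s_SA = nitinol_transformation_stress(params, "s_SA", T),
       f_SA = nitinol_transformation_stress(params, "f_SA", T))
}

# Monotone-loading stress at strain eps >= 0 (virgin curve of the flag
# diagram): austenite elasticity, forward plateau with linear hardening,
# then martensite elasticity. Used by the ring model for branch-dependent
# stiffness; continuous and non-decreasing in eps.
nitinol_monotone_stress <- function(params, eps, T) {
  pl <- nitinol_plateaus(params, T)
  eps <- abs(eps)
  e_s <- pl$s_AS / params$E_A
  # plateau: sigma = s_AS + dS * xi, eps = sigma/E(xi) + xi*eps_L (E mixed)
  # approximate plateau with linear segment between its end states:
  e_f <- pl$f_AS / params$E_M + params$eps_L
  s <- numeric(length(eps))
  el <- eps <= e_s
  s[el] <- params$E_A * eps[el]
  mid <- eps > e_s & eps <= e_f
  s[mid] <- pl$s_AS + (pl$f_AS - pl$s_AS) * (eps[mid] - e_s) / (e_f - e_s)
  hi <- eps > e_f
  s[hi] <- pl$f_AS + params$E_M * (eps[hi] - e_f)
  s
}

#' Stress response of superelastic nitinol along a strain history
#'
#' Incremental one-dimensional flag-shaped superelasticity: elastic loading
#' with the austenite modulus up to the forward transformation start, a
#' hardening forward plateau that accumulates transformation strain up to
#' `eps_L`, martensite elasticity beyond full transformation, and unloading
#' that reverses through the lower plateau. A closed load-unload cycle
#' returns to the origin (no plasticity), and the model is rate-independent:
#' only the sequence of strain values matters.
#'
#' The elastic modulus mixes linearly with the martensite fraction `xi`:
#' `E(xi) = E_A + xi * (E_M - E_A)`. Strains are tensile (`>= 0`); small
#' negative strains are treated as austenite-elastic.
#'
#' @param params a [nitinol_params()] object.
#' @param strain numeric vector, piecewise-monotone strain history.
#' @param T temperature in degrees C within `[A_f, M_d]`.
#' @return list with `stress` (MPa), `xi` (martensite fraction) at each step.
#' @examples
#' p <- nitinol_params()
#' path <- nitinol_stress_path(p, c(0, 0.003, 0), T = 37)
#' path$stress[3] # back to zero
#' @export
nitinol_stress_path <- function(params, strain, T = 37) {
  check_superelastic_window(params, T)
  pl <- nitinol_plateaus(params, T)
  eps_max <- params$eps_L + pl$f_AS / params$E_M + 0.02
  if (any(strain > eps_max))
    stop(sprintf("strain %.4g exceeds the modeled superelastic range (%.4g)",
                 max(strain), eps_max))
  Emix <- function(xi) params$E_A + xi * (params$E_M - params$E_A)
  dS_AS <- pl$f_AS - pl$s_AS
  dS_SA <- pl$s_SA - pl$f_SA # positive
  n <- length(strain)
  stress <- numeric(n)
  xi_out <- numeric(n)
  xi <- 0
  for (k in seq_len(n)) {
    eps <- strain[k]
    if (eps < 0) { # austenite-elastic in mild compression
      stress[k] <- params$E_A * eps
      xi_out[k] <- xi
      next
    }
    s_tr <- Emix(xi) * (eps - xi * params$eps_L)
    fwd <- function(x) Emix(x) * (eps - x * params$eps_L) - (pl$s_AS + dS_AS * x)
    rev <- function(x) Emix(x) * (eps - x * params$eps_L) - (pl$f_SA + dS_SA * x)
    if (xi < 1 && s_tr > pl$s_AS + dS_AS * xi + 1e-12) {
      # forward transformation
      if (fwd(1) >= 0) xi <- 1
      else xi <- uniroot(fwd, c(xi, 1), tol = 1e-13)$root
      s_tr <- Emix(xi) * (eps - xi * params$eps_L)
    } else if (xi > 0 && s_tr < pl$f_SA + dS_SA * xi - 1e-12) {
      # reverse transformation
      if (rev(0) <= 0) xi <- 0
      else xi <- uniroot(rev, c(0, xi), tol = 1e-13)$root
      s_tr <- Emix(xi) * (eps - xi * params$eps_L)
    }
    stress[k] <- s_tr
    xi_out[k] <- xi
  }
  list(stress = stress, xi = xi_out)
}
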