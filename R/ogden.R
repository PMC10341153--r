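#' Ogden hyperelastic parameters for the graft fabric
#'
#' Container for an isotropic, incompressible Ogden model with up to three
#' `(mu_i, alpha_i)` term pairs. The strain energy convention is
#' \deqn{W = \sum_i \frac{2\mu_i}{\alpha_i^2}
#'   (\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i} + \lambda_3^{\alpha_i} - 3),}
#' under which the ground-state shear modulus is `sum(mu)`. Fitted parameter
#' values are convention-dependent: files written by [write_material_json()]
#' carry the tag `"ogden_2mu_over_alpha_sq"` so they cannot be silently
#' re-read under a different normalization.
#'
#' @param mu numeric vector (MPa), shear-modulus-like coefficients; `sum(mu)`
#'   must be positive.
#' @param alpha numeric vector, dimensionless exponents, all non-zero and
#'   finite; same length as `mu` (1 to 3 terms).
#' @return an object of class `ogden_params`.
#' @examples
#' ogden_params(mu = c(60, 30, 10), alpha = c(8, 2, -2))
#' @export
ogden_params <- function(mu, alpha) {
  if (length(mu) != length(alpha) || length(mu) < 1L || length(mu) > 3L)
    stop("`mu` and `alpha` must have equal length between 1 and 3")
  if (!all(is.finite(mu)) || !all(is.finite(alpha)))
    stop("Ogden parameters must be finite")
  if (any(alpha == 0))
    stop("Ogden exponents `alpha` must be non-zero")
  if (sum(mu) <= 0)
    stop("ground-state shear modulus sum(mu) must be positive")
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha)),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat("Ogden parameters (convention W = sum 2*mu/alpha^2 * (...)):\n")
  for (i in seq_along(x$mu))
    cat(sprintf("  term %d: mu = %.6g MPa, alpha = %.6g\n",
                i, x$mu[i], x$alpha[i]))
  cat(sprintf("  ground-state shear modulus: %.6g MPa\n", sum(x$mu)))
  invisible(x)
}

#' Ground-state shear modulus of an Ogden material
#'
#' @param params an [ogden_params()] object.
#' @return `sum(mu)` in MPa. The small-strain Young modulus of the
#'   incompressible material is three times this value.
#' @export
ogden_shear_modulus <- function(params) sum(params$mu)

#' Nominal stress of an incompressible Ogden material in uniaxial tension
#'
#' Uses incompressible uniaxial kinematics (lateral stretches equal to
#' `stretch^(-1/2)`), giving the first Piola-Kirchhoff (nominal) stress
#' \deqn{P(\lambda) = \sum_i \frac{2\mu_i}{\alpha_i}
#'   \left(\lambda^{\alpha_i - 1} - \lambda^{-\alpha_i/2 - 1}\right).}
#'
#' @param params an [ogden_params()] object.
#' @param stretch numeric vector of axial stretches, all positive.
#' @return nominal stress in MPa, same length as `stretch`.
#' @examples
#' p <- ogden_params(1, 2) # one-term Ogden with alpha = 2 is neo-Hookean
#' ogden_uniaxial_stress(p, 1.5) # equals mu * (l - l^-2)
#' @export
ogden_uniaxial_stress <- function(params, stretch) {
  if (!inherits(params, "ogden_params")) stop("`params` must be ogden_params")
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("`stretch` must be positive and finite")
  s <- numeric(length(stretch))
  for (i in seq_along(params$mu)) {
    a <- params$alpha[i]
    s <- s + (2 * params$mu[i] / a) * (stretch^(a - 1) - stretch^(-a / 2 - 1))
  }
  s
}

#' Uniaxial tensile test record
#'
#' @param stretch numeric vector of axial stretches (dimensionless, >= 0
#'   strain corresponds to stretch >= 1). Alternatively supply `strain`.
#' @param stress numeric vector of nominal stresses (MPa).
#' @param strain optional engineering strain; converted as `stretch = 1 + strain`.
#' @param temperature test temperature in degrees C.
#' @param specimen specimen label.
#' @return object of class `uniaxial_test` (a data frame with attributes).
#' @export
uniaxial_test <- function(stretch = NULL, stress, strain = NULL,
                          temperature = 21, specimen = "specimen") {
  if (is.null(stretch)) {
    if (is.null(strain)) stop("supply `stretch` or `strain`")
    stretch <- 1 + strain
  }
  if (length(stretch) != length(stress))
    stop("`stretch` and `stress` lengths differ")
  if (any(stretch <= 0)) stop("stretches must be positive")
  df <- data.frame(stretch = as.numeric(stretch), stress = as.numeric(stress))
  structure(df, class = c("uniaxial_test", "data.frame"),
            temperature = temperature, specimen = specimen)
}

# Fixed multi-start list for the Ogden fit. Exponent patterns bracket the
# typical strongly strain-stiffening response of woven fabric; mu magnitudes
# are rescaled so the small-strain slope 3*sum(mu) matches the data.
ogden_fit_starts <- function(n_terms) {
  pats <- list(c(8, 2, -2), c(6, 3, -3), c(4, 1, -1), c(2, 4, -2),
               c(10, 5, -5), c(3, 2, -4))
  lapply(pats, function(a) a[seq_len(n_terms)])
}

#' Fit Ogden parameters to uniaxial tension data
#'
#' Multi-start Levenberg-Marquardt least squares (via [minpack.lm::nls.lm])
#' of [ogden_uniaxial_stress()] against measured nominal stress. The `mu`
#' coefficients are optimized on a log scale (kept positive); exponents are
#' free. Each start in a fixed list of exponent patterns is rescaled so that
#' the model's small-strain slope matches a finite-difference estimate from
#' the data, and the best converged fit by residual norm is returned.
#'
#' @param test a [uniaxial_test()] object, or data frame with columns
#'   `stretch` (or `strain`) and `stress`.
#' @param n_terms number of Ogden terms (1-3, default 3).
#' @param control passed to [minpack.lm::nls.lm.control]; defaults to
#'   `ftol = 1e-10, maxiter = 500`.
#' @return object of class `ogden_fit`: list with elements `params`
#'   ([ogden_params()]), `residual_norm`, `rmse`, `converged`, and `starts`
#'   (per-start residual norms).
#' @examples
#' truth <- ogden_params(c(60, 30, 10), c(8, 2, -2))
#' dat <- uniaxial_test(stretch = seq(1, 1.3, length.out = 40),
#'                      stress = ogden_uniaxial_stress(truth, seq(1, 1.3, length.out = 40)))
#' fit <- fit_ogden(dat)
#' fit$rmse
#' @export
fit_ogden <- function(test, n_terms = 3L,
                      control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                           maxiter = 500)) {
  if (!is.null(test$strain) && is.null(test$stretch))
    test$stretch <- 1 + test$strain
  lam <- test$stretch
  sig <- test$stress
  keep <- is.finite(lam) & is.finite(sig)
  lam <- lam[keep]; sig <- sig[keep]
  npar <- 2L * n_terms
  if (length(lam) < max(10L, npar))
    stop("underdetermined fit: need at least max(10, 2*n_terms) samples")
  if (diff(range(lam)) <= 0) stop("data must span a stretch range")
  if (any(sig < -1e-8 * max(abs(sig)))) stop("stresses must be non-negative")

  # small-strain slope estimate, dP/dlambda -> 3*sum(mu) as lambda -> 1
  o <- order(lam)
  slope0 <- (sig[o][min(5L, length(sig))] - sig[o][1]) /
    (lam[o][min(5L, length(lam))] - lam[o][1])
  slope0 <- max(slope0, 1e-6)

  resid_fun <- function(par) {
    mu <- exp(par[seq_len(n_terms)])
    alpha <- par[n_terms + seq_len(n_terms)]
    if (any(abs(alpha) < 1e-6)) return(rep(1e6, length(lam)))
    p <- ogden_params(mu, alpha)
    ogden_uniaxial_stress(p, lam) - sig
  }

  best <- NULL
  start_norms <- numeric(0)
  for (a0 in ogden_fit_starts(n_terms)) {
    mu0 <- rep(slope0 / 3 / n_terms, n_terms)
    par0 <- c(log(mu0), a0)
    fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = resid_fun,
                                       control = control),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    start_norms <- c(start_norms, rn)
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("Ogden fit failed from every start")
  par <- best$fit$par
  params <- ogden_params(exp(par[seq_len(n_terms)]),
                         par[n_terms + seq_len(n_terms)])
  converged <- best$fit$info %in% 1:4
  if (!converged)
    warning("Ogden fit did not fully converge; returning best-so-far")
  structure(list(params = params,
                 residual_norm = best$rn,
                 rmse = best$rn / sqrt(length(lam)),
                 converged = converged,
                 starts = start_norms,
                 data = data.frame(stretch = lam, stress = sig)),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf("Ogden fit: %d terms, residual norm %.3e (%s)\n",
              length(x$params$mu), x$residual_norm,
              if (x$converged) "converged" else "best-so-far"))
  print(x$params)
  invisible(x)
}
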