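# Compliance, distensibility and wave-speed metrics.

# Centered 3-point first derivative on a (possibly non-uniform) strictly
# increasing grid; one-sided differences at the ends.
grid_derivative <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for derivatives")
  d <- numeric(n)
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  d[2:(n - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(n - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(n - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:n]
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

# Monotone interpolation (Fritsch-Carlson) used for reference-pressure
# lookups on non-decreasing quantities; falls back to linear on short grids.
mono_interp <- function(x, y, xout) {
  if (length(x) >= 4L && !is.unsorted(y))
    splinefun(x, y, method = "monoH.FC")(xout)
  else approx(x, y, xout = xout, rule = 2)$y
}

#' Compliance and distensibility from a pressure-radius or pressure-volume curve
#'
#' Computes volume compliance `Cv = dV/dP` (mL/mmHg), area compliance
#' `Ca = dA/dP` (mm^2/mmHg) with `A = pi*R^2`, and distensibility
#' `Da = Ca/Aref` (1/mmHg), both pressure-resolved and as scalars at a
#' reference pressure. Derivatives use centered 3-point finite differences
#' on the grid (one-sided at the ends); `Aref` is found by monotone
#' interpolation at `ref_pressure`.
#'
#' `mode` selects the normalizing area of the distensibility array:
#' `"reference"` divides the whole `Ca(P)` array by the single area at
#' `ref_pressure`; `"pointwise"` divides by the local area `A(P)`. The
#' scalar `Da` at the reference pressure is identical in the two modes.
#'
#' @param curve a [pr_curve()] object, or a data frame with columns
#'   `pressure` and one of `radius` (mm), `area` (mm^2) or `volume` (mm^3).
#' @param ref_pressure reference pressure in mmHg; must lie inside the
#'   sampled range.
#' @param mode `"reference"` or `"pointwise"` (see above). Required choice;
#'   defaults to `"reference"`.
#' @param length_mm tube length used to convert area to volume compliance
#'   when only radii are supplied; `NA` (default) leaves `Cv` as `NA`.
#' @return object of class `compliance_result`: list with scalars `Cv`,
#'   `Ca`, `Da`, `Aref`, `ref_pressure`, `mode`, and a data frame `profile`
#'   with the pressure-resolved arrays.
#' @examples
#' cv <- pr_curve(seq(50, 200, 1), 12 * (1 + 4e-4 * seq(50, 200, 1)))
#' compliance_from_curve(cv, ref_pressure = 100, mode = "pointwise")$Da
#' @export
compliance_from_curve <- function(curve, ref_pressure = 100,
                                  mode = c("reference", "pointwise"),
                                  length_mm = NA_real_) {
  mode <- match.arg(mode)
  P <- curve$pressure
  if (is.null(P)) stop("`curve` must have a `pressure` column")
  if (length(P) < 3L) stop("need at least 3 samples")
  if (is.unsorted(P, strictly = TRUE))
    stop("pressures must be strictly increasing")
  if (ref_pressure < min(P) || ref_pressure > max(P))
    stop(sprintf("reference pressure %.4g mmHg outside sampled range [%.4g, %.4g]",
                 ref_pressure, min(P), max(P)))
  if (!is.null(curve$radius)) {
    A <- pi * curve$radius^2
    V <- if (is.finite(length_mm)) A * length_mm else rep(NA_real_, length(P))
  } else if (!is.null(curve$area) && is.null(curve$volume)) {
    A <- curve$area
    V <- if (is.finite(length_mm)) A * length_mm else rep(NA_real_, length(P))
  } else if (!is.null(curve$volume)) {
    V <- curve$volume
    if (!is.null(curve$area)) A <- curve$area
    else if (is.finite(length_mm)) A <- V / length_mm
    else stop("volume input needs an `area` column or `length_mm`")
  } else stop("`curve` must have a `radius`, `area` or `volume` column")

  Ca <- grid_derivative(P, A)
  Cv <- if (all(is.finite(V))) grid_derivative(P, V) / 1000 else rep(NA_real_, length(P))
  Aref <- mono_interp(P, A, ref_pressure)
  Da <- if (mode == "reference") Ca / Aref else Ca / A
  ca_ref <- approx(P, Ca, xout = ref_pressure, rule = 2)$y
  cv_ref <- if (all(is.finite(V))) approx(P, Cv, xout = ref_pressure, rule = 2)$y else NA_real_
  structure(list(Cv = cv_ref, Ca = ca_ref, Da = ca_ref / Aref,
                 Aref = Aref, ref_pressure = ref_pressure, mode = mode,
                 profile = data.frame(pressure = P, area = A, volume = V,
                                      Ca = Ca, Cv = Cv, Da = Da)),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Compliance at %.4g mmHg (mode %s):\n",
    "  Ca = %.4g mm^2/mmHg, Da = %.4g 1/mmHg, Aref = %.4g mm^2"),
    x$ref_pressure, x$mode, x$Ca, x$Da, x$Aref))
  if (is.finite(x$Cv)) cat(sprintf(", Cv = %.4g mL/mmHg", x$Cv))
  cat("\n")
  invisible(x)
}

#' Moens-Korteweg pulse wave velocity
#'
#' `PWV = sqrt(Einc * h / (2 * r * rho))` with the incremental elastic
#' modulus `Einc` in MPa, wall thickness `h` and radius `r` in mm, and blood
#' density `rho` in kg/m^3 (default 1050). Inputs are converted to SI
#' internally; the result is in m/s. The product `Einc * h` is the
#' structural stiffness: quadrupling it doubles the wave speed.
#'
#' @param Einc incremental elastic modulus (MPa).
#' @param h wall thickness (mm).
#' @param r internal radius (mm).
#' @param rho blood density (kg/m^3).
#' @return pulse wave velocity in m/s.
#' @examples
#' moens_korteweg_pwv(Einc = 0.5, h = 1, r = 10, rho = 1050)
#' @export
moens_korteweg_pwv <- function(Einc, h, r, rho = 1050) {
  if (any(c(Einc, h, r, rho) <= 0)) stop("all arguments must be positive")
  sqrt((Einc * 1e6) * (h * 1e-3) / (2 * (r * 1e-3) * rho))
}

#' Distensibility ratio implied by a pulse wave velocity ratio
#'
#' Bramwell-Hill inverse-square law: distensibility scales with
#' `1/PWV^2`, so a PWV ratio `PWV2/PWV1 = q` implies a distensibility
#' ratio `D2/D1 = 1/q^2`. A 22% reduction in PWV (`q = 0.78`) therefore
#' corresponds to a 1.6-fold increase in distensibility.
#'
#' @param pwv_ratio positive ratio of pulse wave velocities (after/before).
#' @return distensibility ratio (after/before).
#' @examples
#' pwv_distensibility_ratio(0.78)
#' @export
pwv_distensibility_ratio <- function(pwv_ratio) {
  if (any(pwv_ratio <= 0)) stop("`pwv_ratio` must be positive")
  1 / pwv_ratio^2
}
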