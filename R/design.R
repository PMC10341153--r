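#' Z-stent design parameters
#'
#' The seven geometric parameters of the laser-cut z-stent: shape-set
#' diameter `d`, strut length `l`, inter-stent spacing `s`, circumferential
#' step `n` (number of z-periods around the circumference), strut width `w`,
#' apex radius of curvature `r`, and strut thickness `t`. All lengths in mm.
#'
#' In the reduced-order model `n` may be non-integer, in which case it is a
#' homogenized z-period density; a manufacturable design rounds it.
#'
#' @param d shape-set stent diameter (mm).
#' @param l strut length (mm); struts must span the circumference
#'   (`2*n*l >= pi*d`) and satisfy `l > pi*d/(2*n)` so the zig-zag has a
#'   real axial height.
#' @param s stent spacing along the graft axis (mm).
#' @param n circumferential step, `>= 3`.
#' @param w strut width (mm).
#' @param r apex radius of curvature (mm).
#' @param t strut thickness (mm).
#' @param material a [nitinol_params()] object.
#' @return object of class `stent_design`.
#' @examples
#' default_stent()
#' @export
stent_design <- function(d, l, s, n, w, r, t, material = nitinol_params()) {
  vals <- c(d = d, l = l, s = s, n = n, w = w, r = r, t = t)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all stent dimensions must be positive and finite")
  if (n < 3) stop("circumferential step `n` must be at least 3")
  if (2 * n * l < pi * d)
    stop("struts must span the circumference: 2*n*l >= pi*d")
  if (l <= pi * d / (2 * n))
    stop("strut length too short for the zig-zag geometry: l > pi*d/(2*n)")
  if (w >= d / 5 || t >= d / 5)
    stop("strut cross-section must be small compared to the diameter")
  if (!inherits(material, "nitinol_params"))
    stop("`material` must be nitinol_params")
  structure(list(d = d, l = l, s = s, n = n, w = w, r = r, t = t,
                 material = material),
            class = "stent_design")
}

#' @export
print.stent_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Z-stent design: d = %.3g mm, l = %.3g mm, s = %.3g mm, n = %.3g,\n",
    "  w = %.3g mm, r = %.3g mm, t = %.3g mm (nitinol E_A = %.3g MPa)\n"),
    x$d, x$l, x$s, x$n, x$w, x$r, x$t, x$material$E_A))
  invisible(x)
}

#' Woven fabric layer of the graft
#'
#' The inner, pleated woven PET layer, modeled as an incompressible Ogden
#' membrane that is slack (folded) below its engagement circumference and
#' bears hoop load beyond it. Longitudinal prestretch shrinks the engagement
#' circumference through an area-conserving fold model,
#' `C_engage = pi * D_nominal / prestretch^kappa`.
#'
#' @param D_nominal uncompressed (nominal) fabric diameter (mm).
#' @param h wall thickness (mm).
#' @param ogden an [ogden_params()] object for the fabric.
#' @param smoothing_width engagement smoothing width as a hoop-stretch
#'   fraction (default 0.02, i.e. 2% of the engagement circumference); the
#'   physical folds of the pleated fabric provide gradual engagement, the
#'   smooth ramp keeps root finding stable.
#' @param kappa prestretch-slack coupling exponent (default 1, isochoric
#'   fold geometry).
#' @param temp_softening fractional reduction of the Ogden moduli per degree
#'   C above `T_ref` (default 0.01/degC), a first-order account of the
#'   thermal softening of the polymer fabric.
#' @param T_ref temperature at which the Ogden parameters were fitted
#'   (degrees C, default 21 = lab temperature).
#' @return object of class `fabric_layer`.
#' @export
fabric_layer <- function(D_nominal, h, ogden,
                         smoothing_width = 0.02, kappa = 1,
                         temp_softening = 0.01, T_ref = 21) {
  if (D_nominal <= 0 || h <= 0) stop("fabric dimensions must be positive")
  if (!inherits(ogden, "ogden_params")) stop("`ogden` must be ogden_params")
  if (smoothing_width <= 0 || smoothing_width > 0.2)
    stop("`smoothing_width` must be in (0, 0.2]")
  if (temp_softening < 0 || temp_softening > 0.05)
    stop("`temp_softening` must be in [0, 0.05] per degC")
  structure(list(D_nominal = D_nominal, h = h, ogden = ogden,
                 smoothing_width = smoothing_width, kappa = kappa,
                 temp_softening = temp_softening, T_ref = T_ref),
            class = "fabric_layer")
}

#' Two-layer graft assembly
#'
#' A [stent_design()] shape-set to a diameter smaller than the nominal
#' diameter of its [fabric_layer()], so that the stent holds the fabric
#' circumferentially compressed (folded) at rest. The compression ratio
#' `1 - d/D_nominal` must lie in (0, 0.3]; practical designs target
#' 0.10-0.15.
#'
#' @param stent a [stent_design()].
#' @param fabric a [fabric_layer()].
#' @return object of class `graft_assembly` with the derived
#'   `compression_ratio`.
#' @examples
#' default_assembly()
#' @export
graft_assembly <- function(stent, fabric) {
  if (!inherits(stent, "stent_design")) stop("`stent` must be stent_design")
  if (!inherits(fabric, "fabric_layer")) stop("`fabric` must be fabric_layer")
  cr <- 1 - stent$d / fabric$D_nominal
  if (cr <= 0 || cr > 0.3)
    stop(sprintf("compression ratio 1 - d/D_nominal = %.3f outside (0, 0.3]", cr))
  structure(list(stent = stent, fabric = fabric, compression_ratio = cr),
            class = "graft_assembly")
}

#' @export
print.graft_assembly <- function(x, ...) {
  cat(sprintf("Graft assembly: compression ratio %.3f\n", x$compression_ratio))
  print(x$stent)
  cat(sprintf("  fabric: D_nominal = %.3g mm, h = %.3g mm, mu_sum = %.3g MPa\n",
              x$fabric$D_nominal, x$fabric$h, sum(x$fabric$ogden$mu)))
  invisible(x)
}

#' Load case for the reduced-order evaluator
#'
#' @param P intraluminal pressure, mmHg, in `[0, 250]`.
#' @param T temperature, degrees C.
#' @param prestretch longitudinal stretch ratio in `[1, 1.3]` (1.10 is the
#'   expected implantation prestretch).
#' @return object of class `load_case`.
#' @export
load_case <- function(P = 100, T = 36, prestretch = 1.10) {
  if (any(P < 0 | P > 250)) stop("pressure must lie in [0, 250] mmHg")
  if (prestretch < 1 || prestretch > 1.3)
    stop("prestretch must lie in [1.0, 1.3]")
  structure(list(P = P, T = T, prestretch = prestretch), class = "load_case")
}

#' Reference designs
#'
#' `default_stent()`, `default_fabric()` and `default_assembly()` return the
#' package's reference 24 mm z-stent inside a 28.8 mm woven PET layer
#' (compression ratio 1/6, calibrated so that fiber engagement begins just
#' above the 100 mmHg reference pressure under 10% implantation
#' prestretch). The fabric Ogden parameters are the truth set used by the
#' synthetic uniaxial generator; the stent dimensions are a plausible
#' interior point of the optimization space.
#'
#' @return a `stent_design`, `fabric_layer` or `graft_assembly`.
#' @export
default_stent <- function() {
  stent_design(d = 24, l = 12, s = 2, n = 12, w = 0.35, r = 0.5, t = 0.35)
}

#' @rdname default_stent
#' @export
default_fabric <- function() {
  fabric_layer(D_nominal = 28.8, h = 0.36,
               ogden = ogden_params(mu = c(60, 30, 10), alpha = c(8, 2, -2)))
}

#' @rdname default_stent
#' @export
default_assembly <- function() graft_assembly(default_stent(), default_fabric())
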