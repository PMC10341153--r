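# Seed-deterministic synthetic data generators: uniaxial tensile tests,
# hydraulic-bench recordings with known ground truth, and the literature-
# derived physiological distensibility envelope.

#' Bench protocol settings for the synthetic generator
#'
#' Defaults mirror the study conditions: stress-controlled inflation cycles
#' between 50 and 200 mmHg at 0.3 Hz (valid 0.2-0.5 Hz), sampled at 1 kHz,
#' ten preconditioning plus ten experimental cycles, 50 Hz mains
#' interference on the pressure channel. Noise magnitudes are engineering
#' choices (sensor data sheets, not study values): pressure white noise
#' SD 0.2 mmHg plus a 0.5 mmHg mains sinusoid, diameter sensor noise
#' SD 0.01 mm.
#'
#' @param p_range inflation pressure range, mmHg.
#' @param freq loading frequency, Hz, in `[0.2, 0.5]`.
#' @param fs sampling rate, Hz.
#' @param n_precond,n_experimental cycle counts.
#' @param mains_amplitude 50 Hz interference amplitude on pressure, mmHg.
#' @param mains_freq utility frequency, Hz.
#' @param pressure_noise_sd white pressure noise SD, mmHg.
#' @param diameter_noise_sd diameter sensor noise SD, mm.
#' @param deflection logical: emulate pressure-driven beam bending of the
#'   graft between the supports.
#' @param deflection_max mid-span deflection at peak pressure, mm.
#' @param span support distance, mm.
#' @param temperature,prestretch load case metadata.
#' @param seed integer seed; mandatory for any stochastic output.
#' @return list of class `bench_protocol`.
#' @export
bench_protocol <- function(p_range = c(50, 200), freq = 0.3, fs = 1000,
                           n_precond = 10, n_experimental = 10,
                           mains_amplitude = 0.5, mains_freq = 50,
                           pressure_noise_sd = 0.2, diameter_noise_sd = 0.01,
                           deflection = TRUE, deflection_max = 5, span = 150,
                           temperature = 36, prestretch = 1.10, seed = 1L) {
  if (freq < 0.2 || freq > 0.5)
    stop("loading frequency must lie in [0.2, 0.5] Hz")
  if (p_range[1] >= p_range[2] || p_range[1] < 0 || p_range[2] > 250)
    stop("pressure range must be increasing within [0, 250] mmHg")
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(p_range = p_range, freq = freq, fs = fs,
                 n_precond = n_precond, n_experimental = n_experimental,
                 mains_amplitude = mains_amplitude, mains_freq = mains_freq,
                 pressure_noise_sd = pressure_noise_sd,
                 diameter_noise_sd = diameter_noise_sd,
                 deflection = deflection, deflection_max = deflection_max,
                 span = span, temperature = temperature,
                 prestretch = prestretch, seed = as.integer(seed)),
            class = "bench_protocol")
}

#' Generate a synthetic uniaxial tensile test
#'
#' Samples the stress-stretch curve of a known material model and adds
#' seeded multiplicative Gaussian noise, storing the generating truth as an
#' attribute for recovery tests.
#'
#' @param truth an [ogden_params()] object, or any function
#'   `stretch -> stress (MPa)`.
#' @param stretch_range range of stretches (default `c(1, 1.4)`).
#' @param n number of samples (default 60).
#' @param noise_sd multiplicative noise SD (default 0.02).
#' @param seed integer seed.
#' @param temperature test temperature, degrees C.
#' @return a [uniaxial_test()] with attribute `truth`.
#' @export
gen_uniaxial <- function(truth, stretch_range = c(1, 1.4), n = 60,
                         noise_sd = 0.02, seed = 1L, temperature = 21) {
  model <- if (inherits(truth, "ogden_params"))
    function(l) ogden_uniaxial_stress(truth, l) else match.fun(truth)
  lam <- seq(stretch_range[1], stretch_range[2], length.out = n)
  sig0 <- model(lam)
  set.seed(as.integer(seed))
  sig <- sig0 * (1 + rnorm(n, sd = noise_sd))
  out <- uniaxial_test(stretch = lam, stress = sig, temperature = temperature)
  attr(out, "truth") <- truth
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate a synthetic hydraulic-bench recording
#'
#' Emulates the hydraulic circuit: the programmable pump inflates the graft
#' through stress-controlled cosine pressure cycles over the protocol
#' range; the external diameter follows the supplied ground-truth
#' pressure-radius curve (plus sensor noise); the graft bends between the
#' supports as a beam fixed at both ends, with mid-span deflection
#' proportional to transmural pressure, so that the internal volume is
#' `pi R(P)^2 * bent_length(span, deflection)`; the pump flow is the time
#' derivative of that true volume (exercising the pipeline's integration);
#' and the pressure channel carries 50 Hz mains interference plus white
#' noise. The generating truth (curve and reference distensibility) is
#' attached for recovery tests.
#'
#' @param truth a [pr_curve()] (or a `graft_assembly`, from which the curve
#'   is computed over an extended pressure grid under the protocol's load
#'   case).
#' @param protocol a [bench_protocol()].
#' @return a [bench_recording()] with attribute `ground_truth` (list with
#'   `curve`, `Da_ref` at 100 mmHg and the protocol).
#' @export
gen_bench_recording <- function(truth, protocol = bench_protocol()) {
  stopifnot(inherits(protocol, "bench_protocol"))
  if (inherits(truth, "graft_assembly")) {
    grid <- seq(max(protocol$p_range[1] - 10, 0),
                min(protocol$p_range[2] + 10, 250), by = 2)
    truth <- pressure_radius_curve(truth, grid, T = protocol$temperature,
                                   prestretch = protocol$prestretch)
  }
  stopifnot(inherits(truth, "pressure_radius_curve"))
  if (min(truth$pressure) > protocol$p_range[1] ||
      max(truth$pressure) < protocol$p_range[2])
    stop("truth curve must cover the protocol pressure range")
  Rfun <- splinefun(truth$pressure, truth$radius, method = "monoH.FC")

  n_cyc <- protocol$n_precond + protocol$n_experimental
  dt <- 1 / protocol$fs
  time <- seq(0, n_cyc / protocol$freq - dt, by = dt)
  ph <- (1 - cos(2 * pi * protocol$freq * time)) / 2
  P0 <- protocol$p_range[1] + diff(protocol$p_range) * ph
  R <- Rfun(P0)
  defl <- if (protocol$deflection) protocol$deflection_max * ph else rep(0, length(time))
  len <- if (protocol$deflection) bent_length_interp(protocol$span, defl)
         else rep(protocol$span, length(time))
  V <- pi * R^2 * len # mm^3
  flow <- c(0, diff(V)) / dt
  flow[1] <- flow[2]
  flow_mls <- flow / 1000

  set.seed(protocol$seed)
  pressure <- P0 +
    protocol$mains_amplitude * sin(2 * pi * protocol$mains_freq * time) +
    rnorm(length(time), sd = protocol$pressure_noise_sd)
  diameter <- 2 * R + rnorm(length(time), sd = protocol$diameter_noise_sd)

  rec <- bench_recording(time = time, pressure = pressure, flow = flow_mls,
                         diameter = diameter, deflection = defl,
                         temperature = protocol$temperature,
                         prestretch = protocol$prestretch,
                         span = protocol$span,
                         n_precond = protocol$n_precond,
                         n_experimental = protocol$n_experimental)
  da <- compliance_from_curve(truth, ref_pressure = 100, mode = "reference")$Da
  attr(rec, "ground_truth") <- list(curve = truth, Da_ref = da,
                                    protocol = protocol)
  rec
}

#' Analytic constant-distensibility truth curve
#'
#' Pressure-radius curve of an idealized vessel with a prescribed, constant
#' pointwise distensibility: `A(P) = A0 * exp(Da * (P - P0))`, so that
#' `dA/dP / A = Da` exactly at every pressure. Useful as generator ground
#' truth for end-to-end recovery tests.
#'
#' @param Da distensibility, 1/mmHg.
#' @param R0 radius at `P0`, mm.
#' @param P0 anchor pressure, mmHg (default 100).
#' @param pressures sampling grid, mmHg.
#' @return a [pr_curve()].
#' @export
constant_da_curve <- function(Da, R0 = 13, P0 = 100,
                              pressures = seq(30, 220, by = 2)) {
  A <- pi * R0^2 * exp(Da * (pressures - P0))
  pr_curve(pressures, sqrt(A / pi))
}

#' Physiological aortic distensibility envelope
#'
#' Tabulated lower/upper bounds of the distensibility of healthy,
#' normotensive adult aortas as a function of pressure, used for the
#' "within physiological range" check on optimized designs. The shipped
#' table (`inst/extdata/aortic_distensibility_envelope_synthetic.csv`) is a
#' synthetic reconstruction with literature-derived magnitudes (adult
#' thoracic aortas; distensibility falls with pressure), editable by the
#' user; it is not measured data.
#'
#' @param pressure optional pressures (mmHg) at which to interpolate the
#'   bounds.
#' @param file alternative envelope CSV with columns
#'   `pressure_mmHg, lower_per_mmHg, upper_per_mmHg`.
#' @return data frame with columns `pressure`, `lower`, `upper` (1/mmHg).
#' @examples
#' reference_aorta(100)
#' @export
reference_aorta <- function(pressure = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "aortic_distensibility_envelope_synthetic.csv",
                        package = "cmgraft")
  tab <- read.csv(file, comment.char = "#")
  out <- data.frame(pressure = tab$pressure_mmHg,
                    lower = tab$lower_per_mmHg, upper = tab$upper_per_mmHg)
  if (any(out$lower >= out$upper)) stop("envelope must satisfy lower < upper")
  mid <- out$pressure >= 80 & out$pressure <= 150
  if (any(diff(out$lower[mid]) > 0) || any(diff(out$upper[mid]) > 0))
    stop("envelope bounds must be non-increasing over 80-150 mmHg")
  if (is.null(pressure)) return(out)
  data.frame(pressure = pressure,
             lower = approx(out$pressure, out$lower, pressure, rule = 2)$y,
             upper = approx(out$pressure, out$upper, pressure, rule = 2)$y)
}
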