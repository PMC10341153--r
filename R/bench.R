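# Hydraulic-bench recording pipeline: filtering, cycle segmentation,
# flow-to-volume integration, the bending correction, and distensibility.

#' Bench recording container
#'
#' Synchronized, uniformly sampled time series from the hydraulic circuit:
#' intraluminal pressure, programmed pump flow and external diameter
#' (optionally a mid-span radial deflection channel), with the protocol
#' metadata needed by the pipeline.
#'
#' @param time time vector in s, uniform sampling (nominally 1 kHz).
#' @param pressure pressure in mmHg.
#' @param flow pump volume flow rate in mL/s (positive inflates).
#' @param diameter external diameter in mm.
#' @param deflection optional mid-span radial deflection in mm (bending of
#'   the graft between the supports).
#' @param temperature bath temperature (degrees C).
#' @param prestretch longitudinal prestretch.
#' @param span distance between the rigid supports (mm).
#' @param n_precond,n_experimental expected numbers of preconditioning and
#'   experimental cycles (default 10 + 10).
#' @return object of class `bench_recording` (a data frame with attributes).
#' @export
bench_recording <- function(time, pressure, flow, diameter, deflection = NULL,
                            temperature = 36, prestretch = 1.10, span = 150,
                            n_precond = 10, n_experimental = 10) {
  n <- length(time)
  if (length(pressure) != n || length(flow) != n || length(diameter) != n)
    stop("all channels must share the length of `time`")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("sampling must be uniform")
  df <- data.frame(time = time, pressure = pressure, flow = flow,
                   diameter = diameter)
  if (!is.null(deflection)) {
    if (length(deflection) != n) stop("`deflection` length mismatch")
    df$deflection <- deflection
  }
  structure(df, class = c("bench_recording", "data.frame"),
            fs = 1 / dt[1], temperature = temperature,
            prestretch = prestretch, span = span,
            n_precond = n_precond, n_experimental = n_experimental,
            filtered = FALSE)
}

#' @export
print.bench_recording <- function(x, ...) {
  cat(sprintf(paste0(
    "Bench recording: %.1f s at %.0f Hz, %.4g-%.4g mmHg, ",
    "T = %.3g degC, prestretch %.3g, span %.4g mm%s\n"),
    max(x$time) - min(x$time), attr(x, "fs"),
    min(x$pressure), max(x$pressure), attr(x, "temperature"),
    attr(x, "prestretch"), attr(x, "span"),
    if (isTRUE(attr(x, "filtered"))) " (filtered)" else ""))
  invisible(x)
}

#' Zero-phase low-pass filter of a bench recording
#'
#' Order-4 Butterworth low-pass at 50 Hz (removing the utility frequency
#' and higher-frequency noise), applied forward-backward
#' ([signal::filtfilt]) to every channel so that no phase lag is introduced
#' between the pressure and diameter signals. DC gain is exactly 1.
#'
#' @param recording a [bench_recording()] with uniform sampling.
#' @param cutoff cut-off frequency in Hz (default 50).
#' @param order Butterworth order (default 4).
#' @return the filtered recording (attribute `filtered = TRUE`).
#' @export
lowpass <- function(recording, cutoff = 50, order = 4) {
  stopifnot(inherits(recording, "bench_recording"))
  fs <- attr(recording, "fs")
  if (cutoff >= fs / 2) stop("cut-off must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- recording
  for (ch in setdiff(names(recording), "time"))
    out[[ch]] <- filtfilt_padded(bf, recording[[ch]], ceiling(3 * fs / cutoff))
  attr(out, "filtered") <- TRUE
  out
}

# Forward-backward filtering with odd-reflection end padding, which
# suppresses the startup transients of the raw forward-backward pass (a
# constant signal passes through exactly).
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  mu <- mean(x)
  x <- x - mu
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(pad + 1):(pad + n)] + mu
}

#' Arc length of the graft bent between its supports
#'
#' The graft between the two rigid supports is assumed to deflect like a
#' beam fixed at both ends under a distributed load, with unit-peak shape
#' `y(x) = w_max * 16 * x^2 (L - x)^2 / L^4`. The bent length is the arc
#' length `int_0^L sqrt(1 + y'(x)^2) dx`, evaluated by adaptive quadrature
#' ([stats::integrate], relative tolerance 1e-12).
#'
#' @param span support distance `L` in mm.
#' @param max_deflection mid-span peak deflection `w_max` in mm
#'   (vectorized, `>= 0`).
#' @return arc length in mm, `>= span` with equality iff the deflection
#'   is zero.
#' @examples
#' bent_length(150, 5) - 150
#' @export
bent_length <- function(span, max_deflection) {
  if (span <= 0) stop("span must be positive")
  if (any(max_deflection < 0)) stop("deflection must be non-negative")
  one <- function(w) {
    if (w == 0) return(span)
    dy <- function(x) 32 * w * x * (span - x) * (span - 2 * x) / span^4
    integrate(function(x) sqrt(1 + dy(x)^2), 0, span,
              rel.tol = 1e-12, subdivisions = 400L)$value
  }
  vapply(max_deflection, one, numeric(1))
}

# Fast tabulated version used on per-sample deflection traces: exact
# bent_length() on a 64-point grid of the squared deflection (arc length is
# smooth in w^2), interpolated with a natural spline.
bent_length_interp <- function(span, deflection) {
  rng <- range(deflection)
  if (diff(rng) < 1e-12) return(rep(bent_length(span, rng[1]), length(deflection)))
  wg <- sqrt(seq(rng[1]^2, rng[2]^2, length.out = 64))
  lg <- bent_length(span, wg)
  splinefun(wg^2, lg, method = "natural")(deflection^2)
}

# Cycle segmentation by upward midline crossings of the (low-passed)
# pressure after removal of a linear drift. A band-pass would serve the
# same drift-proofing purpose but its long low-frequency memory distorts
# the crossings of the final cycles, which are exactly the experimental
# ones. Returns a list of index ranges, one per full cycle.
segment_cycles <- function(recording) {
  p <- recording$pressure
  t <- recording$time
  pb <- unname(residuals(lm(p ~ t)))
  up <- which(pb[-length(pb)] < 0 & pb[-1] >= 0)
  # debounce: keep crossings separated by at least a quarter of the median
  # spacing, so filter ripple cannot split a cycle
  if (length(up) >= 2L) {
    gap <- stats::median(diff(up))
    up <- up[c(TRUE, diff(up) > gap / 4)]
  }
  if (length(up) < 2L) stop("could not segment cycles from the pressure signal")
  lapply(seq_len(length(up) - 1L), function(i) up[i]:(up[i + 1L]))
}

#' Adjusted pressure-volume data from a bench recording
#'
#' Integrates the pump flow to volume (cumulative trapezoid), subtracts the
#' elongation-induced volume of pressure-driven bending
#' `dV_bend(t) = A(t) * (bent_length(span, deflection(t)) - span)` so the
#' volume corresponds to radial inflation only, segments the cycles from
#' the band-passed pressure signal, and extracts the loading (inflation)
#' branch of each experimental cycle onto a uniform pressure grid by binned
#' averaging. Requires a filtered recording (applies [lowpass()] if not).
#'
#' @param recording a [bench_recording()].
#' @param grid_spacing pressure grid spacing in mmHg (default 1).
#' @param margin fraction of the pressure range trimmed at the cycle
#'   extremes (default 0.03) to avoid the turning-point transients.
#' @return list with `cycles` (per experimental cycle, data frames of
#'   `pressure`, `volume` (adjusted, mm^3, relative to the cycle start),
#'   `area` (mm^2, from the diameter channel)), `ensemble` (grid-averaged
#'   loading branch across cycles) and `grid` metadata.
#' @export
adjusted_pv_curve <- function(recording, grid_spacing = 1, margin = 0.03) {
  stopifnot(inherits(recording, "bench_recording"))
  if (!isTRUE(attr(recording, "filtered"))) recording <- lowpass(recording)
  span <- attr(recording, "span")
  n_pre <- attr(recording, "n_precond")
  n_exp <- attr(recording, "n_experimental")

  V_raw <- as.numeric(pracma::cumtrapz(recording$time, recording$flow)) * 1000 # mL -> mm^3
  A_t <- pi * (recording$diameter / 2)^2
  if (!is.null(recording$deflection)) {
    dl <- bent_length_interp(span, pmax(recording$deflection, 0)) - span
    V_adj <- V_raw - A_t * dl
  } else V_adj <- V_raw

  segs <- segment_cycles(recording)
  # a run of m cycles yields m or m-1 complete crossing-to-crossing segments
  if (length(segs) < n_exp)
    warning(sprintf("expected %d experimental cycles, segmented only %d; using all",
                    n_exp, length(segs)))
  take <- utils::tail(segs, min(n_exp, length(segs)))

  pmin_g <- max(vapply(take, function(i) min(recording$pressure[i]), numeric(1)))
  pmax_g <- min(vapply(take, function(i) max(recording$pressure[i]), numeric(1)))
  rng <- (pmax_g - pmin_g) * margin
  grid <- seq(ceiling(pmin_g + rng), floor(pmax_g - rng), by = grid_spacing)

  branch <- function(idx) {
    p <- recording$pressure[idx]
    i0 <- which.min(p); i1 <- which.max(p)
    if (i0 > i1) { # loading wraps the cycle boundary
      sel <- c(idx[i0:length(idx)], idx[seq_len(i1)])
    } else sel <- idx[i0:i1]
    p <- recording$pressure[sel]
    v <- V_adj[sel]; a <- A_t[sel]
    bin <- findInterval(p, grid - grid_spacing / 2)
    ok <- bin >= 1L & bin <= length(grid)
    data.frame(pressure = grid,
               volume = as.numeric(tapply(v[ok], factor(bin[ok], seq_along(grid)), mean)),
               area = as.numeric(tapply(a[ok], factor(bin[ok], seq_along(grid)), mean)))
  }
  cycles <- lapply(take, branch)
  ens <- Reduce(function(a, b) {
    a$volume <- a$volume + b$volume; a$area <- a$area + b$area; a
  }, cycles)
  ens$volume <- ens$volume / length(cycles)
  ens$area <- ens$area / length(cycles)
  list(cycles = cycles, ensemble = ens,
       grid = list(spacing = grid_spacing, pressures = grid),
       span = span)
}

# Area-versus-pressure of one loading branch through the volume route:
# volume changes anchored to the optically measured area at the reference
# pressure, A(P) = A(P_ref) + (V(P) - V(P_ref)) / span.
area_from_volume <- function(branch, span, ref_pressure) {
  ok <- is.finite(branch$volume) & is.finite(branch$area)
  p <- branch$pressure[ok]
  v <- branch$volume[ok]
  a_meas <- branch$area[ok]
  v_ref <- approx(p, v, xout = ref_pressure, rule = 2)$y
  a_ref <- approx(p, a_meas, xout = ref_pressure, rule = 2)$y
  data.frame(pressure = p, area = a_ref + (v - v_ref) / span)
}

# Local-linear slope of y on x in a window around x0 (smoothed derivative).
local_slope <- function(x, y, x0, window) {
  sel <- abs(x - x0) <= window / 2
  if (sum(sel) < 3L) sel <- rank(abs(x - x0)) <= 5
  unname(coef(lm(y[sel] ~ x[sel]))[2])
}

#' Distensibility of a graft from a bench recording
#'
#' End-to-end pipeline composition: zero-phase low-pass filtering, flow
#' integration with the beam-bending volume correction
#' ([adjusted_pv_curve()]), per-cycle loading-branch extraction, and
#' distensibility `Da = Ca/Aref`. The lumen area follows the volume route,
#' anchored to the optical diameter at the reference pressure; the
#' reference-pressure scalars use a local-linear slope over a
#' `smooth_window` wide pressure band (default 15 mmHg) to suppress
#' sensor-noise amplification by differentiation, and the pressure-resolved
#' arrays come from [compliance_from_curve()] on the ensemble-averaged
#' branch.
#'
#' @param recording a [bench_recording()].
#' @param ref_pressure reference pressure, mmHg.
#' @param mode `"reference"` or `"pointwise"` distensibility normalization
#'   (see [compliance_from_curve()]).
#' @param smooth_window width (mmHg) of the local-linear derivative window.
#' @param ... passed to [adjusted_pv_curve()].
#' @return a `compliance_result` with extra fields `per_cycle` (Da per
#'   experimental cycle), `Da_mean`, `Da_sd`.
#' @export
distensibility_from_recording <- function(recording, ref_pressure = 100,
                                          mode = c("reference", "pointwise"),
                                          smooth_window = 15, ...) {
  mode <- match.arg(mode)
  pv <- adjusted_pv_curve(recording, ...)
  per <- vapply(pv$cycles, function(cyc) {
    ap <- area_from_volume(cyc, pv$span, ref_pressure)
    ca <- local_slope(ap$pressure, ap$area, ref_pressure, smooth_window)
    aref <- approx(ap$pressure, ap$area, xout = ref_pressure, rule = 2)$y
    ca / aref
  }, numeric(1))
  ens <- area_from_volume(pv$ensemble, pv$span, ref_pressure)
  res <- compliance_from_curve(ens, ref_pressure = ref_pressure, mode = mode)
  res$Ca <- local_slope(ens$pressure, ens$area, ref_pressure, smooth_window)
  res$Da <- res$Ca / res$Aref
  res$per_cycle <- per
  res$Da_mean <- mean(per)
  res$Da_sd <- sd(per)
  res
}
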