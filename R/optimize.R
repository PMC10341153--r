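# Iterative Box-Behnken response-surface optimization of the stent design
# toward a target distensibility.

#' Design space for the stent optimization
#'
#' @param names factor names (fields of [stent_design()]).
#' @param lower,upper named or positional finite bounds, `lower < upper`.
#' @return list of class `design_space`.
#' @export
design_space <- function(names, lower, upper) {
  if (length(lower) != length(names) || length(upper) != length(names))
    stop("bounds must match `names` in length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  structure(list(names = names, lower = unname(lower), upper = unname(upper)),
            class = "design_space")
}

#' Default 6-factor optimization space
#'
#' The six stent factors carried through the optimization:
#' strut length `l` (6-14 mm), circumferential step `n` (8-16),
#' strut width `w` (0.2-0.8 mm), apex radius `r` (0.2-1 mm),
#' strut thickness `t` (0.2-0.8 mm) and shape-set diameter `d` (22-28 mm,
#' i.e. compression ratios 0.03-0.24 against the default 28.8 mm fabric).
#' Bounds are chosen so that every corner satisfies the z-stent geometric
#' feasibility constraints.
#'
#' @return a [design_space()].
#' @export
default_design_space <- function() {
  design_space(names = c("l", "n", "w", "r", "t", "d"),
               lower = c(6, 8, 0.2, 0.2, 0.2, 22),
               upper = c(14, 16, 0.8, 1.0, 0.8, 28))
}

#' Distensibility evaluator over a design space
#'
#' Returns the function `design vector -> Da` used by the optimizer: it
#' builds the stent from the named vector (unspecified [stent_design()]
#' fields come from `base_stent`), assembles it with `fabric`, solves the
#' equilibrium on a short pressure grid around the reference pressure and
#' returns the distensibility `Da = Ca/Aref` (1/mmHg) at `ref_pressure`
#' under the configured load case, or the mean over `band` when given.
#'
#' @param fabric a [fabric_layer()] (default [default_fabric()]).
#' @param base_stent template supplying the non-optimized fields
#'   (default [default_stent()]).
#' @param T,prestretch load case (defaults 36 degC, 1.10).
#' @param ref_pressure reference pressure, mmHg.
#' @param band optional pressure band `c(lo, hi)`; the evaluator then
#'   returns the band-averaged pointwise distensibility.
#' @return function mapping a named design vector to Da (1/mmHg).
#' @examples
#' ev <- make_graft_evaluator()
#' ev(c(l = 12, n = 12, w = 0.35, r = 0.5, t = 0.35, d = 24))
#' @export
make_graft_evaluator <- function(fabric = default_fabric(),
                                 base_stent = default_stent(),
                                 T = 36, prestretch = 1.10,
                                 ref_pressure = 100, band = NULL) {
  force(fabric); force(base_stent)
  function(x) {
    args <- list(d = base_stent$d, l = base_stent$l, s = base_stent$s,
                 n = base_stent$n, w = base_stent$w, r = base_stent$r,
                 t = base_stent$t, material = base_stent$material)
    args[names(x)] <- as.list(as.numeric(x))
    stent <- do.call(stent_design, args)
    assembly <- graft_assembly(stent, fabric)
    if (is.null(band)) {
      grid <- ref_pressure + seq(-10, 10, by = 5)
      curve <- pressure_radius_curve(assembly, grid, T = T, prestretch = prestretch)
      compliance_from_curve(curve, ref_pressure = ref_pressure,
                            mode = "reference")$Da
    } else {
      grid <- seq(band[1] - 5, band[2] + 5, by = 5)
      curve <- pressure_radius_curve(assembly, grid, T = T, prestretch = prestretch)
      prof <- compliance_from_curve(curve, ref_pressure = mean(band),
                                    mode = "pointwise")$profile
      sel <- prof$pressure >= band[1] & prof$pressure <= band[2]
      mean(prof$Da[sel])
    }
  }
}

run_bbd_cycle <- function(evaluator, space, center, half_ranges) {
  des <- bbd_points(length(space$names), center, half_ranges,
                    bounds = list(lower = space$lower, upper = space$upper))
  y <- apply(des$physical, 1, function(row) {
    x <- as.numeric(row); names(x) <- space$names
    tryCatch(evaluator(x), error = function(e) NA_real_)
  })
  list(design = des, y = y)
}

#' Optimize a stent design toward a target distensibility
#'
#' The study's optimization engine: from each multi-start center, iterate
#' (i) a 6-factor Box-Behnken design (49 runs) over the current box,
#' (ii) evaluation of the distensibility at every design point,
#' (iii) a least-squares quadratic response surface of the objective
#' `|Da - Da_target|`, and (iv) a translate-and-shrink descent step
#' ([descend()]) that moves the box center to the surface minimizer and
#' multiplies the half-ranges by `gamma`. Iteration stops when the mean
#' response of consecutive cycles changes by less than `tol` (relative;
#' default 1%), or after `max_cycles`. Multi-start centers are a seeded
#' Latin hypercube over the feasible box; results are returned best first.
#'
#' If more than 20% of a cycle's evaluations fail, the cycle is retried
#' once with halved ranges, then the start is abandoned.
#'
#' @param evaluator function: named design vector -> distensibility
#'   (1/mmHg); see [make_graft_evaluator()].
#' @param space a [design_space()] with exactly 6 factors for the BBD stage.
#' @param target target distensibility, 1/mmHg (default 1.6e-3, the mean
#'   distensibility of healthy adult aortas at 100 mmHg).
#' @param starts number of Latin-hypercube multi-starts (default 5).
#' @param seed integer seed controlling the multi-start draw (mandatory
#'   determinism: identical seeds give identical traces).
#' @param gamma half-range shrink factor per cycle (default 0.7).
#' @param max_cycles cycle cap per start (default 30).
#' @param tol relative mean-response convergence tolerance (default 0.01).
#' @param init_half_fraction initial half-ranges as a fraction of the bound
#'   width (default 0.25).
#' @param floor_fraction half-range floor as a fraction of the bound width
#'   (default 0.01).
#' @param mean_mode `"response"` (default): the convergence statistic is
#'   the mean evaluator response over the 49 design points; `"center"`
#'   uses the center-point response instead.
#' @return list of class `optimization_result_set`: per-start results
#'   (class `optimization_result`) sorted by objective, each with
#'   `best_design`, `best_Da`, `objective`, `trace` (per-cycle mean/best
#'   response), `cycles_used`, `converged`, `start`.
#' @export
optimize_graft <- function(evaluator, space = default_design_space(),
                           target = 1.6e-3, starts = 5L, seed = 1L,
                           gamma = 0.7, max_cycles = 30L, tol = 0.01,
                           init_half_fraction = 0.25, floor_fraction = 0.01,
                           mean_mode = c("response", "center")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(inherits(space, "design_space"))
  k <- length(space$names)
  if (k != 6L) stop("the Box-Behnken stage expects exactly 6 active factors")
  width <- space$upper - space$lower
  half0 <- init_half_fraction * width
  floor_half <- floor_fraction * width
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(as.integer(starts), k)
  centers <- sweep(U, 2, width - 2 * half0, `*`)
  centers <- sweep(centers, 2, space$lower + half0, `+`)

  one_start <- function(si) {
    center <- centers[si, ]
    half <- half0
    trace <- data.frame(cycle = integer(), mean_response = numeric(),
                        best_response = numeric(), objective = numeric())
    best <- list(obj = Inf, design = NULL, Da = NA_real_)
    prev_mean <- NA_real_
    converged <- FALSE
    cycles <- 0L
    while (cycles < max_cycles) {
      cycles <- cycles + 1L
      cyc <- run_bbd_cycle(evaluator, space, center, half)
      if (mean(!is.finite(cyc$y)) > 0.2) {
        half <- half / 2
        cyc <- run_bbd_cycle(evaluator, space, center, half)
        if (mean(!is.finite(cyc$y)) > 0.2) {
          return(structure(list(best_design = best$design, best_Da = best$Da,
                                objective = best$obj, trace = trace,
                                cycles_used = cycles, converged = FALSE,
                                status = "failed", start = si),
                           class = "optimization_result"))
        }
      }
      obj <- abs(cyc$y - target)
      ibest <- which.min(obj)
      if (is.finite(obj[ibest]) && obj[ibest] < best$obj) {
        bd <- as.numeric(cyc$design$physical[ibest, ])
        names(bd) <- space$names
        best <- list(obj = obj[ibest], design = bd, Da = cyc$y[ibest])
      }
      mean_resp <- if (mean_mode == "response") mean(cyc$y, na.rm = TRUE)
                   else cyc$y[nrow(cyc$design$coded)]
      trace <- rbind(trace, data.frame(cycle = cycles, mean_response = mean_resp,
                                       best_response = cyc$y[ibest],
                                       objective = obj[ibest]))
      if (is.finite(prev_mean) &&
          abs(mean_resp - prev_mean) < tol * abs(prev_mean)) {
        converged <- TRUE
        break
      }
      prev_mean <- mean_resp
      fit <- fit_rsm(cyc$design$coded, obj)
      step <- descend(fit, center, half, gamma = gamma,
                      floor_half = floor_half,
                      bounds = list(lower = space$lower, upper = space$upper))
      half <- step$half_ranges
      # keep the whole next box feasible so no design point needs clipping
      center <- pmin(pmax(step$center, space$lower + half), space$upper - half)
    }
    structure(list(best_design = best$design, best_Da = best$Da,
                   objective = best$obj, trace = trace,
                   cycles_used = cycles, converged = converged,
                   status = if (converged) "converged" else "max_cycles",
                   start = si),
              class = "optimization_result")
  }

  results <- lapply(seq_len(starts), one_start)
  ord <- order(vapply(results, `[[`, numeric(1), "objective"))
  structure(results[ord], class = "optimization_result_set")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "Optimization start %d: %s in %d cycles, Da = %.4g /mmHg (objective %.3g)\n",
    x$start, x$status, x$cycles_used, x$best_Da, x$objective))
  if (!is.null(x$best_design)) {
    cat("  best design:",
        paste(sprintf("%s = %.4g", names(x$best_design), x$best_design),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.optimization_result_set <- function(x, ...) {
  cat(sprintf("Optimization with %d starts (best first):\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}
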