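# Box-Behnken designs, quadratic response surfaces, and the
# translate-and-shrink descent step.

# Canonical Box-Behnken blocks: the sets of factors varied at +/-1 while
# the rest sit at the center. k = 3..5 use all pairs; k = 6 and 7 use the
# standard cyclic triple sets.
bbd_blocks <- function(k) {
  if (k %in% 3:5) {
    utils::combn(k, 2, simplify = FALSE)
  } else if (k == 6) {
    list(c(1, 2, 4), c(2, 3, 5), c(3, 4, 6), c(4, 5, 1), c(5, 6, 2), c(6, 1, 3))
  } else if (k == 7) {
    list(c(4, 5, 6), c(1, 6, 7), c(2, 5, 7), c(1, 2, 4),
         c(3, 4, 7), c(1, 3, 5), c(2, 3, 6))
  } else stop("Box-Behnken designs supported for k in 3..7")
}

#' Box-Behnken design points
#'
#' Canonical Box-Behnken design for `k` factors with a single center point:
#' each block of 2 (for `k <= 5`) or 3 (for `k = 6, 7`) factors takes all
#' `+/-1` sign combinations while the remaining factors sit at the center.
#' The 6-factor design has 48 edge points plus the center, 49 runs in
#' total; every row has exactly 0 or `block size` non-zero coded entries,
#' and each factor appears 12 times at `+1`, 12 times at `-1` and 25 times
#' at `0`.
#'
#' @param k number of factors (3-7).
#' @param center numeric length-`k` center in physical units.
#' @param half_ranges positive length-`k` half-ranges.
#' @param bounds optional `list(lower, upper)` hard feasibility bounds;
#'   physical points escaping them are clipped with a warning.
#' @return list with `coded` (runs x k matrix in \{-1, 0, +1\}) and
#'   `physical` (same size, `center + coded * half_ranges`, clipped).
#' @examples
#' nrow(bbd_points(6, rep(0, 6), rep(1, 6))$coded) # 49
#' @export
bbd_points <- function(k, center, half_ranges, bounds = NULL) {
  if (length(center) != k || length(half_ranges) != k)
    stop("`center` and `half_ranges` must have length k")
  if (any(half_ranges <= 0)) stop("half-ranges must be positive")
  blocks <- bbd_blocks(k)
  signs2 <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(blocks[[1]]))))
  rows <- lapply(blocks, function(b) {
    m <- matrix(0, nrow(signs2), k)
    m[, b] <- signs2
    m
  })
  coded <- rbind(do.call(rbind, rows), rep(0, k))
  dimnames(coded) <- list(NULL, names(center))
  physical <- sweep(coded, 2, half_ranges, `*`)
  physical <- sweep(physical, 2, center, `+`)
  if (!is.null(bounds)) {
    lo <- rep_len(bounds$lower, k); up <- rep_len(bounds$upper, k)
    clipped <- sweep(physical, 2, lo, pmax)
    clipped <- sweep(clipped, 2, up, pmin)
    if (any(abs(clipped - physical) > 1e-9 * pmax(1, abs(physical))))
      warning("design points escaped the feasibility bounds and were clipped")
    physical <- clipped
  }
  list(coded = coded, physical = physical)
}

# Full quadratic model matrix in coded units: intercept, k linear, k pure
# quadratic, k(k-1)/2 interactions.
quad_model_matrix <- function(X) {
  k <- ncol(X)
  cols <- list(intercept = rep(1, nrow(X)))
  for (i in seq_len(k)) cols[[paste0("x", i)]] <- X[, i]
  for (i in seq_len(k)) cols[[paste0("x", i, "^2")]] <- X[, i]^2
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    cols[[paste0("x", i, ":x", j)]] <- X[, i] * X[, j]
  do.call(cbind, cols)
}

#' Fit a quadratic response surface to a Box-Behnken cycle
#'
#' Ordinary least squares of the full quadratic model (intercept, linear,
#' pure quadratic and two-factor interaction terms; 28 coefficients for
#' 6 factors) in coded units.
#'
#' @param coded runs x k coded design matrix.
#' @param y responses (length = runs); `NA` responses (failed runs) are
#'   dropped.
#' @return list of class `rsm_fit`: `coefficients` (named), `k`,
#'   `r_squared`, `residuals`, `fitted`.
#' @export
fit_rsm <- function(coded, y) {
  k <- ncol(coded)
  ok <- is.finite(y)
  p <- 1 + 2 * k + k * (k - 1) / 2
  if (sum(ok) < p)
    stop(sprintf("rank deficiency: %d usable responses for %d coefficients",
                 sum(ok), p))
  M <- quad_model_matrix(coded[ok, , drop = FALSE])
  fit <- stats::lm.fit(M, y[ok])
  if (fit$rank < p) stop("rank-deficient quadratic fit (too many failed runs)")
  res <- fit$residuals
  tss <- sum((y[ok] - mean(y[ok]))^2)
  structure(list(coefficients = fit$coefficients, k = k,
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                 residuals = res, fitted = fit$fitted.values),
            class = "rsm_fit")
}

#' Evaluate a fitted response surface
#'
#' @param fit an `rsm_fit`.
#' @param X coded points (vector of length k or matrix).
#' @return predicted responses.
#' @export
rsm_predict <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  drop(quad_model_matrix(X) %*% fit$coefficients)
}

# Gradient and Hessian of the fitted quadratic at coded point x.
rsm_grad_hess <- function(fit, x) {
  k <- fit$k
  b <- fit$coefficients
  lin <- b[1 + seq_len(k)]
  quad <- b[1 + k + seq_len(k)]
  H <- diag(2 * quad, k)
  idx <- 1 + 2 * k
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    idx <- idx + 1
    H[i, j] <- H[j, i] <- b[idx]
  }
  list(g = lin + H %*% x, H = H)
}

#' Translate-and-shrink descent step
#'
#' Minimizes the fitted quadratic objective over the current coded box
#' `[-1, 1]^k` (projected Newton step when the Hessian is positive
#' definite, safeguarded by box-constrained quasi-Newton refinement) and
#' maps the minimizer to physical units as the next design center. The
#' half-ranges shrink by the factor `gamma` and are floored at
#' `floor_half`.
#'
#' @param fit an `rsm_fit` of the objective on the current cycle.
#' @param center,half_ranges current physical center and half-ranges.
#' @param gamma shrink factor in (0, 1] (default 0.7).
#' @param floor_half minimum half-ranges (physical units).
#' @param bounds optional `list(lower, upper)`; the next center is clipped
#'   into them.
#' @return list with `center`, `half_ranges`, `coded_step` (the coded
#'   minimizer).
#' @export
descend <- function(fit, center, half_ranges, gamma = 0.7,
                    floor_half = NULL, bounds = NULL) {
  k <- fit$k
  qobj <- function(x) rsm_predict(fit, x)
  qgr <- function(x) as.numeric(rsm_grad_hess(fit, x)$g)
  x0 <- rep(0, k)
  gh <- rsm_grad_hess(fit, x0)
  ev <- eigen(gh$H, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > 1e-10)) {
    xn <- as.numeric(solve(gh$H, -fit$coefficients[1 + seq_len(k)]))
    x0 <- pmin(pmax(xn, -1), 1)
  }
  opt <- optim(x0, qobj, qgr, method = "L-BFGS-B", lower = -1, upper = 1,
               control = list(factr = 10, maxit = 200))
  xstar <- opt$par
  new_center <- center + xstar * half_ranges
  if (!is.null(bounds))
    new_center <- pmin(pmax(new_center, bounds$lower), bounds$upper)
  new_half <- gamma * half_ranges
  if (!is.null(floor_half)) new_half <- pmax(new_half, floor_half)
  list(center = new_center, half_ranges = new_half, coded_step = xstar)
}

#' Two-level main-effects screening of candidate factors
#'
#' Evaluates the response on a two-level design over the candidate box
#' (full factorial `2^k` for up to 7 factors; a resolution-III fraction
#' built by assigning extra factors to interaction columns of a smaller
#' full factorial otherwise), computes each factor's main effect
#' `mean(response at +1) - mean(response at -1)`, and ranks factors by
#' absolute effect. In fractional designs main effects are aliased with
#' interactions of the generating columns; the returned estimate is the
#' aliased contrast.
#'
#' @param evaluator function taking a named numeric vector (physical units)
#'   and returning a scalar response; failures become `NA` runs.
#' @param space list with `names`, `lower`, `upper` for the candidate
#'   factors (more than 6 candidates expected).
#' @param top number of factors to select (default 6).
#' @return list with `effects` (data frame ranked by `|effect|`),
#'   `selected` (top factor names), `failed` (number of failed runs).
#' @export
main_effects_screen <- function(evaluator, space, top = 6L) {
  k <- length(space$names)
  if (k <= 7) {
    D <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  } else {
    m <- ceiling(log2(k + 1))
    base <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    subsets <- unlist(lapply(2:m, function(s) utils::combn(m, s, simplify = FALSE)),
                      recursive = FALSE)
    extra <- vapply(subsets, function(ss) apply(base[, ss, drop = FALSE], 1, prod),
                    numeric(nrow(base)))
    D <- cbind(base, extra)[, seq_len(k), drop = FALSE]
  }
  colnames(D) <- space$names
  mid <- (space$upper + space$lower) / 2
  half <- (space$upper - space$lower) / 2
  y <- apply(D, 1, function(row) {
    x <- mid + row * half
    names(x) <- space$names
    tryCatch(evaluator(x), error = function(e) NA_real_)
  })
  failed <- sum(!is.finite(y))
  if (failed > 0.2 * length(y))
    stop(sprintf("screening aborted: %d of %d runs failed", failed, length(y)))
  eff <- vapply(seq_len(k), function(j) {
    mean(y[D[, j] > 0], na.rm = TRUE) - mean(y[D[, j] < 0], na.rm = TRUE)
  }, numeric(1))
  ord <- order(abs(eff), decreasing = TRUE)
  list(effects = data.frame(factor = space$names[ord], effect = eff[ord],
                            rank = seq_len(k)),
       selected = space$names[ord][seq_len(min(top, k))],
       failed = failed)
}
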