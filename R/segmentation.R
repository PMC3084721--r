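# Greedy change-point segmentation with piecewise polynomial smoothing.
#
# Candidate breakpoints are data indices; a breakpoint D splits an index
# interval [a, b] into [a, D-1] and [D, b] (left-closed, right-open in index
# space, the last interval being closed).  Every interval must keep at least
# r + 2 points so that residual comparisons between fits remain meaningful.

# Prefix cross-moments of the standardized abscissa.  All candidate-split
# residuals are computed from these in O(r^2) per range; the abscissa is
# standardized once so the small normal-equation systems stay well
# conditioned even for degree 3 on micrometre-scale z ranges.
.prefix_moments <- function(z, F, r) {
  mu <- mean(z)
  sd <- stats::sd(z)
  if (!is.finite(sd) || sd == 0) sd <- 1
  x <- (z - mu) / sd
  Mp <- lapply(0:(2 * r), function(p) cumsum(x^p))
  Bp <- lapply(0:r, function(p) cumsum(x^p * F))
  list(Mp = Mp, Bp = Bp, S2 = cumsum(F^2), mu = mu, sd = sd)
}

# Vectorized SSE of degree-r least-squares fits over index ranges
# [lo_i, hi_i].  Closed-form Cramer solves for r <= 2, small-system solve
# for r = 3.  Values are clamped at zero (cancellation can produce tiny
# negatives on noise-free signals).
.range_sse <- function(cums, lo, hi, r) {
  g <- function(cs, lo, hi) cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)
  m <- lapply(cums$Mp, g, lo = lo, hi = hi)
  b <- lapply(cums$Bp, g, lo = lo, hi = hi)
  s2 <- g(cums$S2, lo, hi)
  sse <- if (r == 0L) {
    s2 - b[[1]]^2 / m[[1]]
  } else if (r == 1L) {
    det <- m[[1]] * m[[3]] - m[[2]]^2
    t0 <- (b[[1]] * m[[3]] - b[[2]] * m[[2]]) / det
    t1 <- (m[[1]] * b[[2]] - m[[2]] * b[[1]]) / det
    s2 - t0 * b[[1]] - t1 * b[[2]]
  } else if (r == 2L) {
    a11 <- m[[1]]; a12 <- m[[2]]; a13 <- m[[3]]
    a22 <- m[[3]]; a23 <- m[[4]]; a33 <- m[[5]]
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    c1 <- b[[1]] * (a22 * a33 - a23^2) - a12 * (b[[2]] * a33 - a23 * b[[3]]) +
      a13 * (b[[2]] * a23 - a22 * b[[3]])
    c2 <- a11 * (b[[2]] * a33 - b[[3]] * a23) -
      b[[1]] * (a12 * a33 - a23 * a13) + a13 * (a12 * b[[3]] - b[[2]] * a13)
    c3 <- a11 * (a22 * b[[3]] - a23 * b[[2]]) -
      a12 * (a12 * b[[3]] - b[[2]] * a13) + b[[1]] * (a12 * a23 - a22 * a13)
    s2 - (c1 * b[[1]] + c2 * b[[2]] + c3 * b[[3]]) / det
  } else {
    out <- numeric(length(lo))
    for (i in seq_along(lo)) {
      M <- matrix(0, r + 1, r + 1)
      for (p in 0:r) for (q in 0:r) M[p + 1, q + 1] <- m[[p + q + 1]][i]
      bb <- vapply(0:r, function(p) b[[p + 1]][i], numeric(1))
      th <- tryCatch(solve(M, bb), error = function(e) rep(0, r + 1))
      out[i] <- s2[i] - sum(th * bb)
    }
    out
  }
  pmax(sse, 0)
}

#' Least-squares polynomial fit on one interval
#'
#' Ordinary least-squares polynomial of degree `r` in `z`, fitted on a basis
#' centered on the interval midpoint (and scaled by its half-width) for
#' conditioning.  The returned coefficients are re-expanded in the raw `z`
#' basis, ascending powers.
#'
#' @param z,F numeric slices of equal length `>= r + 1`.
#' @param r polynomial degree, 0 to 3.
#' @return list with `coefficients` (length `r + 1`, raw basis),
#'   `sse` (sum of squared residuals, nN^2) and the internal centered
#'   representation (`center`, `scale`, `beta`) used for stable evaluation.
#' @export
fit_poly_interval <- function(z, F, r) {
  r <- as.integer(r)
  stopifnot(r >= 0L, r <= 3L, length(z) == length(F), length(z) >= r + 1L)
  c0 <- (min(z) + max(z)) / 2
  h <- max((max(z) - min(z)) / 2, .Machine$double.eps)
  t <- (z - c0) / h
  X <- outer(t, 0:r, `^`)
  if (r >= 1L && max(z) == min(z))
    stop("degenerate design: all z equal with r >= 1", call. = FALSE)
  fit <- stats::lm.fit(X, F)
  if (r >= 1L && fit$rank < r + 1L)
    stop("rank-deficient polynomial design on interval", call. = FALSE)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # expand sum_j beta_j ((z - c0)/h)^j into raw powers of z
  coef <- numeric(r + 1)
  for (j in 0:r) {
    bin <- choose(j, 0:j) * (-c0)^(j:0) / h^j   # coefficients of z^0..z^j
    coef[1:(j + 1)] <- coef[1:(j + 1)] + beta[j + 1] * bin
  }
  sse <- sum(fit$residuals^2)
  list(coefficients = coef, sse = sse, center = c0, scale = h, beta = beta)
}

# Evaluate an interval fit (centered representation) and its derivative.
.poly_eval <- function(fit, z) {
  t <- (z - fit$center) / fit$scale
  drop(outer(t, seq_along(fit$beta) - 1, `^`) %*% fit$beta)
}

.poly_deriv <- function(fit, z) {
  r <- length(fit$beta) - 1L
  if (r == 0L) return(rep(0, length(z)))
  t <- (z - fit$center) / fit$scale
  drop(outer(t, 0:(r - 1), `^`) %*% (fit$beta[-1] * (1:r))) / fit$scale
}

# Exact SSE of a degree-r fit on [a, b] via residuals of a per-range
# centered/scaled basis (no subtractive cancellation).
.direct_sse <- function(z, F, a, b, r) {
  zz <- z[a:b]
  yy <- F[a:b]
  c0 <- (zz[1] + zz[length(zz)]) / 2
  h <- max((zz[length(zz)] - zz[1]) / 2, .Machine$double.eps)
  X <- outer((zz - c0) / h, 0:r, `^`)
  sum(stats::.lm.fit(X, yy)$residuals^2)
}

# Best admissible split of interval [a, b]: returns NULL or
# list(D, sse_left, sse_right, sum).  Ties broken by smallest index.
# Short intervals are scanned exactly; long ones use the locally
# standardized prefix-moment formula to bracket the optimum, then polish it
# with exact refits (the closed-form SSE loses accuracy for small
# sub-ranges of long intervals).
.best_split <- function(z, F, a, b, r) {
  min_len <- r + 2L
  lo <- a + min_len
  hi <- b - min_len + 1L
  if (lo > hi) return(NULL)
  D <- lo:hi
  exact <- function(dd) {
    sl <- vapply(dd, function(d) .direct_sse(z, F, a, d - 1L, r), numeric(1))
    sr <- vapply(dd, function(d) .direct_sse(z, F, d, b, r), numeric(1))
    list(sl = sl, sr = sr)
  }
  L <- b - a + 1L
  if (L <= 300L) {
    e <- exact(D)
    i <- which.min(e$sl + e$sr)    # first minimum = smallest index
    return(list(D = D[i], sse_left = e$sl[i], sse_right = e$sr[i],
                sum = e$sl[i] + e$sr[i]))
  }
  cums <- .prefix_moments(z[a:b], F[a:b], r)
  Dl <- D - a + 1L
  sl0 <- .range_sse(cums, rep(1L, length(Dl)), Dl - 1L, r)
  sr0 <- .range_sse(cums, Dl, rep(L, length(Dl)), r)
  i0 <- which.min(sl0 + sr0)
  win <- unique(pmin(pmax(i0 + (-12:12), 1L), length(D)))
  e <- exact(D[win])
  j <- which.min(e$sl + e$sr)
  list(D = D[win[j]], sse_left = e$sl[j], sse_right = e$sr[j],
       sum = e$sl[j] + e$sr[j])
}

#' Greedy segmentation of a force curve
#'
#' Detects up to `k_max` discontinuity points (jumps, slope or curvature
#' changes) by greedy insertion, in the spirit of Orthogonal Least Squares:
#' starting from a single interval covering all samples, each iteration
#' inserts the one admissible breakpoint that most reduces the total sum of
#' squared residuals of the piecewise degree-`r` polynomial smoother, and
#' stops when `k_max` breakpoints have been placed or the global mean
#' squared error drops to `eps` (whichever comes first).  Every interval
#' keeps at least `r + 2` samples.
#'
#' The MSE test uses `max(eps, 1e-18 * mean(F^2))`: the tiny relative floor
#' recognises numerically exact fits on noise-free signals, where rounding
#' keeps the residual a few ulps above zero.
#'
#' @param curve a preprocessed [force_curve()].
#' @param r polynomial degree of the interval smoothers (0-3).
#' @param k_max maximum number of breakpoints (silently capped at the
#'   feasible maximum for the curve length).
#' @param eps MSE stopping threshold, nN^2 (0 disables early stopping up to
#'   the numerical floor).
#' @return An object of class `fc_segmentation`: `breakpoints` (ordered data
#'   indices), `intervals` (list of `a`, `b`, fit, `sse`), `mse_history`,
#'   `r`, `stop_reason` (`"kmax"` or `"mse_threshold"`).
#' @export
segment_curve <- function(curve, r = 2L, k_max = 6L, eps = 0) {
  stopifnot(inherits(curve, "force_curve"), k_max >= 0, eps >= 0)
  r <- as.integer(r)
  stopifnot(r >= 0L, r <= 3L)
  z <- curve$z
  F <- curve$F
  n <- length(z)
  min_len <- r + 2L
  mse_floor <- 1e-18 * mean(F^2)
  thr <- max(eps, mse_floor)

  whole <- fit_poly_interval(z, F, r)
  ivs <- list(list(a = 1L, b = n, fit = whole, sse = whole$sse))
  history <- whole$sse / n
  if (n < 2L * min_len || k_max == 0L) {
    return(structure(list(breakpoints = integer(0), intervals = ivs,
                          mse_history = history, r = r,
                          stop_reason = if (k_max == 0L) "kmax" else "kmax"),
                     class = "fc_segmentation"))
  }
  k_feasible <- n %/% min_len - 1L
  k_max <- min(as.integer(k_max), k_feasible)

  proposals <- list(.best_split(z, F, 1L, n, r))
  stop_reason <- "kmax"
  if (history[1] <= thr) stop_reason <- "mse_threshold"

  while (stop_reason == "kmax" && length(ivs) - 1L < k_max) {
    # pick the interval whose best split lowers the total SSE the most;
    # ties go to the smallest breakpoint index
    best_i <- 0L
    best_gain <- -Inf
    best_D <- Inf
    for (i in seq_along(ivs)) {
      p <- proposals[[i]]
      if (is.null(p)) next
      gain <- ivs[[i]]$sse - p$sum
      tol <- 1e-12 * max(abs(gain), abs(best_gain), 1)
      if (best_i == 0L || gain > best_gain + tol ||
          (abs(gain - best_gain) <= tol && p$D < best_D)) {
        best_i <- i
        best_gain <- gain
        best_D <- p$D
      }
    }
    if (best_i == 0L) break                       # nothing admissible left
    iv <- ivs[[best_i]]
    D <- proposals[[best_i]]$D
    fl <- fit_poly_interval(z[iv$a:(D - 1L)], F[iv$a:(D - 1L)], r)
    fr <- fit_poly_interval(z[D:iv$b], F[D:iv$b], r)
    left <- list(a = iv$a, b = D - 1L, fit = fl, sse = fl$sse)
    right <- list(a = D, b = iv$b, fit = fr, sse = fr$sse)
    ivs <- append(ivs[-best_i], list(left, right), after = best_i - 1L)
    proposals <- append(proposals[-best_i],
                        list(.best_split(z, F, left$a, left$b, r),
                             .best_split(z, F, right$a, right$b, r)),
                        after = best_i - 1L)
    mse <- sum(vapply(ivs, `[[`, numeric(1), "sse")) / n
    history <- c(history, mse)
    if (mse <= thr) stop_reason <- "mse_threshold"
  }
  breakpoints <- vapply(ivs[-1], `[[`, integer(1), "a")
  structure(list(breakpoints = breakpoints, intervals = ivs,
                 mse_history = history, r = r, stop_reason = stop_reason),
            class = "fc_segmentation")
}

#' @export
print.fc_segmentation <- function(x, ...) {
  cat(sprintf("<fc_segmentation> r = %d, %d breakpoint(s), final MSE %.4g, stop: %s\n",
              x$r, length(x$breakpoints), utils::tail(x$mse_history, 1),
              x$stop_reason))
  invisible(x)
}

#' Piecewise-smoothed forces
#'
#' Evaluates each interval's fitted polynomial at its own samples, returning
#' the smoothed force vector of the same length as the curve.
#'
#' @param seg an [segment_curve()] result produced from `curve`.
#' @param curve the same [force_curve()].
#' @return numeric vector of smoothed forces, nN.
#' @export
evaluate_piecewise <- function(seg, curve) {
  stopifnot(inherits(seg, "fc_segmentation"), inherits(curve, "force_curve"))
  out <- numeric(curve$n)
  for (iv in seg$intervals)
    out[iv$a:iv$b] <- .poly_eval(iv$fit, curve$z[iv$a:iv$b])
  out
}

#' Exhaustive segmentation oracle (small problems)
#'
#' Finds the globally SSE-optimal set of `k` breakpoints by complete
#' enumeration, using independent direct least-squares fits per interval.
#' Intended as a test oracle; refuses problems with `n > 300` or `k > 2`.
#'
#' @param curve a [force_curve()].
#' @param r polynomial degree.
#' @param k number of breakpoints (0, 1 or 2).
#' @return list with `breakpoints` (data indices) and `sse` (total).
#' @export
exhaustive_segment_oracle <- function(curve, r, k) {
  stopifnot(inherits(curve, "force_curve"))
  n <- curve$n
  if (n > 300L || k > 2L)
    stop("exhaustive oracle limited to n <= 300 and k <= 2", call. = FALSE)
  r <- as.integer(r)
  z <- curve$z
  F <- curve$F
  min_len <- r + 2L
  sse_rng <- function(a, b) {
    c0 <- mean(z[a:b])
    X <- outer(z[a:b] - c0, 0:r, `^`)
    sum(stats::lm.fit(X, F[a:b])$residuals^2)
  }
  if (k == 0L)
    return(list(breakpoints = integer(0), sse = sse_rng(1L, n)))
  if (k == 1L) {
    D <- (1L + min_len):(n - min_len + 1L)
    tot <- vapply(D, function(d) sse_rng(1L, d - 1L) + sse_rng(d, n),
                  numeric(1))
    i <- which.min(tot)
    return(list(breakpoints = D[i], sse = tot[i]))
  }
  # k == 2: precompute prefix/suffix SSEs, enumerate middle ranges
  pre <- rep(NA_real_, n)
  suf <- rep(NA_real_, n)
  for (d in min_len:(n - 2L * min_len))
    pre[d] <- sse_rng(1L, d)
  for (d in (2L * min_len + 1L):(n - min_len + 1L))
    suf[d] <- sse_rng(d, n)
  best <- Inf
  bp <- c(NA_integer_, NA_integer_)
  for (d1 in (1L + min_len):(n - 2L * min_len + 1L)) {
    for (d2 in (d1 + min_len):(n - min_len + 1L)) {
      tot <- pre[d1 - 1L] + sse_rng(d1, d2 - 1L) + suf[d2]
      if (tot < best) {
        best <- tot
        bp <- c(d1, d2)
      }
    }
  }
  list(breakpoints = bp, sse = best)
}
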