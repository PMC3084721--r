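# Retraction-curve analysis: detection of decreasing (pulling) regions in
# the piecewise-smoothed signal and Freely-Jointed-Chain fits per region.
#
# Orientation: z increases away from the sample, contact at the smallest z.
# Adhesive (pulling) forces are negative, so each stretching event is a
# decreasing branch of the smoothed force ending in an upward rupture jump.

#' Freely Jointed Chain extension
#'
#' Extension of an FJC polymer under a pulling force:
#' `x = Lc * (coth(u) - 1/u)` with `u = F * lk / (kB T)`.  The Langevin
#' factor is evaluated by its series `u/3 - u^3/45` for `u < 1e-4`, which
#' is numerically stable where the direct expression cancels.
#'
#' @param F_mag pulling force magnitude, nN (vectorized, must be > 0).
#' @param Lc contour length, nm.
#' @param lk Kuhn length, nm.
#' @param temperature temperature, K.
#' @return extension, nm (always in `(0, Lc)`).
#' @export
fjc_extension <- function(F_mag, Lc, lk, temperature = 298.15) {
  stopifnot(Lc > 0, lk > 0, temperature > 0)
  if (any(!is.finite(F_mag)) || any(F_mag <= 0))
    stop("F_mag must be strictly positive", call. = FALSE)
  u <- F_mag * lk / (.KB_nNnm * temperature)
  g <- ifelse(u < 1e-4, u / 3 - u^3 / 45, 1 / tanh(u) - 1 / u)
  Lc * g
}

# Inverse FJC: force magnitude producing extension x (bracketed root-find;
# monotone in F).  Used by the synthetic generator.
.fjc_force <- function(x, Lc, lk, temperature = 298.15, tol = 1e-10) {
  stopifnot(x > 0, x < Lc)
  f <- function(F) fjc_extension(F, Lc, lk, temperature) - x
  hi <- 1
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 10
  stats::uniroot(f, c(1e-12, hi), tol = tol)$root
}

#' Detect FJC regions of interest in a segmented retraction curve
#'
#' Candidate regions are the maximal runs of samples on which the piecewise
#' polynomial smoother is strictly decreasing; for degree 2 an interval is
#' split at the parabola vertex and only its decreasing side kept.
#' Contiguous decreasing runs from adjacent segmentation intervals are
#' merged, since one stretching event commonly spans several affine pieces.
#' Each run is then clipped to `z >= Zc + skip_nm` (the first ~100 nm past
#' contact are dominated by non-specific adhesion and are never fitted) and
#' dropped if it retains fewer than `min_region_pts` samples or contains
#' any sample with non-negative force (the FJC model is meaningless there).
#'
#' @param curve preprocessed retraction [force_curve()].
#' @param seg its [segment_curve()] result (degree 1 or 2).
#' @param Zc contact point, nm.
#' @param config an [instrument_config()] (`skip_nm`, `min_region_pts`).
#' @param noise_sd force noise standard deviation, nN (`NULL`: estimated
#'   from the flat end of the curve); an interval only counts as decreasing
#'   when its fitted drop exceeds twice this value, so flat baseline pieces
#'   whose fitted slope is negative by chance are not swept into regions.
#' @return list of index ranges `c(a, b)`; attribute `n_sign_excluded`
#'   counts candidate regions discarded by the positive-force rule.
#' @export
detect_regions <- function(curve, seg, Zc, config = instrument_config(),
                           noise_sd = NULL) {
  stopifnot(inherits(curve, "force_curve"), inherits(seg, "fc_segmentation"),
            is.finite(Zc))
  if (!seg$r %in% c(1L, 2L))
    stop("region detection expects a degree-1 or degree-2 segmentation",
         call. = FALSE)
  if (is.null(noise_sd))
    noise_sd <- sqrt(max(estimate_noise_variance(curve), 0))
  drop_min <- max(2 * noise_sd, 1e-9)
  z <- curve$z
  runs <- list()
  for (iv in seg$intervals) {
    idx <- iv$a:iv$b
    dec <- .poly_deriv(iv$fit, z[idx]) < 0
    if (!any(dec)) next
    # degree <= 2: the derivative is monotone, so TRUE samples form one run
    w <- which(dec)
    a <- idx[w[1]]
    b <- idx[w[length(w)]]
    sig <- .poly_eval(iv$fit, z[a]) - .poly_eval(iv$fit, z[b]) >= drop_min
    runs[[length(runs) + 1L]] <- list(a = a, b = b, sig = sig)
  }
  if (length(runs) == 0L) return(structure(list(), n_sign_excluded = 0L))
  # chain decreasing runs into regions: one stretching event commonly spans
  # several polynomial pieces, and noise interleaves short flat or weakly
  # sloped pieces that are bridged over -- but never chain across an upward
  # jump of the measured force (a rupture separates two events even when
  # both sides are decreasing, as superposed pulls are).  The jump is read
  # from the data (3-sample means on each side): fitted edge values of
  # adjacent affine pieces gap systematically on strongly curved pulls.  A
  # finished region must contain at least one significant run (fitted drop
  # above the noise), so runs of pure baseline never form a region.
  jump_min <- max(4 * noise_sd, 1e-9)
  gap_cap <- 100L
  data_jump <- function(e, s) {
    mean(curve$F[s:min(s + 2L, length(z))]) -
      mean(curve$F[max(e - 2L, 1L):e])
  }
  merged <- list(runs[[1]])
  for (rn in runs[-1]) {
    last <- merged[[length(merged)]]
    if (rn$a - last$b - 1L <= gap_cap &&
        data_jump(last$b, rn$a) < jump_min) {
      last$b <- rn$b
      last$sig <- last$sig || rn$sig
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- rn
    }
  }
  merged <- lapply(Filter(function(rn) rn$sig, merged),
                   function(rn) c(rn$a, rn$b))
  if (length(merged) == 0L) return(structure(list(), n_sign_excluded = 0L))
  z_min <- Zc + config$skip_nm
  out <- list()
  n_sign <- 0L
  for (rn in merged) {
    idx <- rn[1]:rn[2]
    idx <- idx[z[idx] >= z_min]
    if (length(idx) < config$min_region_pts) next
    # the FJC model only makes sense for negative (adhesive) forces: trim
    # non-negative samples at the leading (attachment) edge, but treat
    # non-negative forces deeper inside the region as an inconsistent
    # region and discard it
    pos <- which(curve$F[idx] >= 0)
    if (length(pos)) {
      cut <- max(pos)
      if (cut > 0.4 * length(idx)) {
        n_sign <- n_sign + 1L
        next
      }
      idx <- idx[(cut + 1L):length(idx)]
      if (length(idx) < config$min_region_pts) next
    }
    out[[length(out) + 1L]] <- c(idx[1], idx[length(idx)])
  }
  structure(out, n_sign_excluded = n_sign)
}

#' Fit the FJC model on one region of interest
#'
#' Minimizes the extension-space residual
#' `sum ((z_i - Zc) - Lc * g(|F_i|; lk))^2`, where `g` is the Langevin
#' factor of the FJC extension.  The cost is quadratic in `Lc`, whose
#' constrained minimizer (`Lc >= z_b - Zc`) is closed-form; the remaining
#' 1-D problem in the Kuhn length is solved on a deterministic log-spaced
#' grid (augmented with the small initial value `lk_init`, which sits in
#' the steep convex part of the cost valley) followed by Brent refinement.
#'
#' @param z,F region samples (forces must all be negative), nm / nN.
#' @param Zc contact point, nm.
#' @param z_b upper z bound of the region, nm (`Lc` may not be shorter than
#'   the largest extension `z_b - Zc`).
#' @param temperature temperature, K.
#' @param lk_bounds Kuhn-length bounds, nm.
#' @param lk_init initial Kuhn length, nm.
#' @return An `fjc_region_fit`: `z_a`, `z_b`, `Lc`, `lk`, `N = Lc/lk`,
#'   `F_rupture` (nN, magnitude at the region's last sample), `sse` (nm^2),
#'   `n_pts`, `status`.
#' @export
fit_fjc_region <- function(z, F, Zc, z_b = max(z), temperature = 298.15,
                           lk_bounds = c(1e-3, 5), lk_init = 0.01,
                           reweight = TRUE) {
  stopifnot(length(z) == length(F), length(z) >= 2L)
  if (any(F >= 0))
    stop("FJC fit requires strictly negative forces", call. = FALSE)
  x <- z - Zc
  Fm <- -F
  kBT <- .KB_nNnm * temperature
  Lc_min <- max(z_b - Zc, 0)
  langevin <- function(u) ifelse(u < 1e-4, u / 3 - u^3 / 45,
                                 1 / tanh(u) - 1 / u)
  solve_lk <- function(w) {
    inner <- function(lk) {
      g <- langevin(Fm * lk / kBT)
      s <- sum(w * g^2)
      if (s < 1e-300) return(list(Lc = NA_real_, sse = Inf))
      Lc <- max(sum(w * x * g) / s, Lc_min)
      list(Lc = Lc, sse = sum(w * (x - Lc * g)^2))
    }
    j <- function(lk) inner(lk)$sse
    grid <- sort(unique(c(exp(seq(log(lk_bounds[1]), log(lk_bounds[2]),
                                  length.out = 60)),
                          min(max(lk_init, lk_bounds[1]), lk_bounds[2]))))
    sses <- vapply(grid, j, numeric(1))
    i <- which.min(sses)
    if (!is.finite(sses[i])) return(NULL)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    lk <- if (lo < hi) stats::optimize(j, c(lo, hi), tol = 1e-12)$minimum
          else grid[i]
    if (j(grid[i]) < j(lk)) lk <- grid[i]
    c(inner(lk), lk = lk)
  }
  fin <- solve_lk(rep(1, length(x)))
  if (is.null(fin))
    return(structure(list(z_a = min(z), z_b = z_b, Lc = NA_real_,
                          lk = NA_real_, N = NA_real_, F_rupture = NA_real_,
                          sse = NA_real_, n_pts = length(z),
                          status = "unfit"),
                     class = "fjc_region_fit"))
  if (reweight && length(x) >= 10L) {
    # the extension-space residual is strongly heteroscedastic: force noise
    # maps to extension noise via dx/dF = Lc g'(u) lk / kBT, which spans
    # about two orders of magnitude between the low-tension end and the
    # rupture.  One Gauss-Markov reweighting pass (weights from the first
    # fit, capped at a 1e4 dynamic range) keeps the problem quadratic in Lc
    # while restoring near-efficient estimates.
    u <- Fm * fin$lk / kBT
    gp <- ifelse(u < 1e-4, 1 / 3 - u^2 / 15, 1 / u^2 - 1 / sinh(u)^2)
    dxdF <- fin$Lc * gp * fin$lk / kBT
    w <- 1 / pmax(dxdF, max(dxdF, 1e-300) / 100)^2
    w <- w / mean(w)
    fin2 <- solve_lk(w)
    if (!is.null(fin2)) fin <- fin2
  }
  g_fin <- langevin(Fm * fin$lk / kBT)
  structure(list(z_a = min(z), z_b = z_b, Lc = fin$Lc, lk = fin$lk,
                 N = fin$Lc / fin$lk, F_rupture = Fm[which.max(z)],
                 sse = sum((x - fin$Lc * g_fin)^2), n_pts = length(z),
                 status = "ok"),
            class = "fjc_region_fit")
}

# Contact point for retraction-only data: first sign change of the
# smoothed force from positive (contact repulsion) to non-positive,
# scanning outward from the low-z (contact) end.
.estimate_zc <- function(curve, seg) {
  s <- evaluate_piecewise(seg, curve)
  cross <- which(s[-length(s)] > 0 & s[-1] <= 0)
  if (length(cross) == 0L) return(curve$z[1])
  curve$z[cross[1] + 1L]
}

#' Full analysis of one retraction curve
#'
#' Segments the curve (degree 1, up to 20 breakpoints, MSE threshold at the
#' empirical noise variance by default), detects the decreasing regions of
#' interest, fits each to the FJC model and assembles rupture statistics.
#'
#' @param curve a retraction [force_curve()] (raw or preprocessed).
#' @param Zc contact point, nm; when `NULL` it is taken from the smoothed
#'   force's last positive-to-negative zero crossing (use the paired
#'   approach fit's `Z1` when available).
#' @param config an [instrument_config()].
#' @param r,k_max,eps segmentation settings (`eps = NULL`: empirical noise
#'   variance).
#' @return An object of class `retract_fit`: `Zc`, list `regions` of
#'   [fit_fjc_region()] results, `n_ruptures` (regions + 1, the initial
#'   non-specific detachment counting as one), `deltaL` (nm, gaps between
#'   consecutive rupture positions), `last_adhesion_force` (nN),
#'   `last_rupture_distance` (nm), `status` (`"ok"`, `"no_regions"` or
#'   `"excluded"` when every candidate region failed the force-sign test).
#' @export
process_retract <- function(curve, Zc = NULL, config = instrument_config(),
                            r = 1L, k_max = 20L, eps = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$direction != "retract")
    stop("process_retract expects a retraction curve", call. = FALSE)
  if (!curve$preprocessed) curve <- preprocess_curve(curve, config)
  nv <- estimate_noise_variance(curve)
  if (is.null(eps)) eps <- nv
  seg <- segment_curve(curve, r = r, k_max = k_max, eps = eps)
  if (is.null(Zc)) Zc <- .estimate_zc(curve, seg)
  regions <- detect_regions(curve, seg, Zc, config,
                            noise_sd = sqrt(max(nv, 0)))
  res <- list(Zc = Zc, regions = list(), n_ruptures = 0L,
              deltaL = numeric(0), last_adhesion_force = NA_real_,
              last_rupture_distance = NA_real_, noise_variance = nv,
              segmentation = seg, status = "no_regions")
  if (length(regions) == 0L) {
    if (attr(regions, "n_sign_excluded") > 0L) res$status <- "excluded"
    class(res) <- "retract_fit"
    return(res)
  }
  fits <- list()
  for (rg in regions) {
    idx <- rg[1]:rg[2]
    ft <- fit_fjc_region(curve$z[idx], curve$F[idx], Zc,
                         z_b = curve$z[rg[2]],
                         temperature = config$temperature,
                         lk_bounds = config$lk_bounds,
                         lk_init = config$lk_init)
    if (ft$status == "ok") fits[[length(fits) + 1L]] <- ft
  }
  if (length(fits) == 0L) {
    class(res) <- "retract_fit"
    return(res)
  }
  res$regions <- fits
  res$status <- "ok"
  zb <- vapply(fits, `[[`, numeric(1), "z_b")
  res$n_ruptures <- length(fits) + 1L
  res$deltaL <- diff(zb)
  res$last_adhesion_force <- fits[[length(fits)]]$F_rupture
  res$last_rupture_distance <- zb[length(zb)] - Zc
  class(res) <- "retract_fit"
  res
}

#' Rupture statistics of a processed retraction curve
#'
#' @param result a [process_retract()] result.
#' @return list with `deltaL` (nm, distances between consecutive rupture
#'   positions), `n_ruptures`, `last_adhesion_force` (nN) and
#'   `last_rupture_distance` (nm).
#' @export
rupture_statistics <- function(result) {
  stopifnot(inherits(result, "retract_fit"))
  list(deltaL = result$deltaL, n_ruptures = result$n_ruptures,
       last_adhesion_force = result$last_adhesion_force,
       last_rupture_distance = result$last_rupture_distance)
}

#' @export
print.retract_fit <- function(x, ...) {
  cat(sprintf("<retract_fit> status: %s, %d region(s), n_ruptures = %d\n",
              x$status, length(x$regions), x$n_ruptures))
  if (length(x$regions)) {
    for (ft in x$regions)
      cat(sprintf("  [%.1f, %.1f] nm: Lc = %.1f nm, lk = %.3f nm, N = %.0f, F_rup = %.3g nN\n",
                  ft$z_a, ft$z_b, ft$Lc, ft$lk, ft$N, ft$F_rupture))
  }
  invisible(x)
}
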