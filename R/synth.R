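# Synthetic force curves and force-volume images with known ground truth.
#
# The generators evaluate the same physical forward models the fitters
# assume -- affine baseline + exponential double-layer repulsion +
# continuous Hertz/Hooke contact branch for approach, sawtooth of FJC pulls
# with rupture jumps for retraction -- plus additive Gaussian force noise.
# Defaults mirror the experimental conditions the package targets: ~2700
# samples per curve, a 10 pN/nm cantilever, 1 mM monovalent electrolyte.

#' Ground truth for a synthetic approach curve
#'
#' @param Z1 virtual pre-contact point, nm.
#' @param A electrostatic prefactor, nN.
#' @param kappa inverse Debye length, nm^-1.
#' @param E Young modulus, Pa.
#' @param k_cell cell spring constant, N/m.
#' @param delta0 virtual contact offset, nm.
#' @param Delta1 Hertz-to-Hooke transition indentation, nm.
#' @param noise_sd force noise standard deviation, nN.
#' @param baseline affine baseline `(intercept nN, slope nN/nm)` added to
#'   the raw curve (removed again by preprocessing).
#' @return list of class `approach_truth`.
#' @export
approach_truth <- function(Z1 = 0, A = 0.05, kappa = 0.1, E = 1e6,
                           k_cell = 0.1, delta0 = 0, Delta1 = 50,
                           noise_sd = 0.01, baseline = c(0.01, 2e-6)) {
  stopifnot(A >= 0, kappa > 0, E >= 0, k_cell >= 0,
            delta0 >= 0, Delta1 >= delta0, noise_sd >= 0,
            length(baseline) == 2)
  structure(list(Z1 = Z1, A = A, kappa = kappa, E = E, k_cell = k_cell,
                 delta0 = delta0, Delta1 = Delta1, noise_sd = noise_sd,
                 baseline = baseline),
            class = "approach_truth")
}

# Hertz prefactor a (nN/nm^2) from E (Pa) for a conical tip.
.hertz_a <- function(E, config) {
  2 * (E / 1e9) * tan(config$alpha * pi / 180) / (pi * (1 - config$nu^2))
}

# Contact force model in the indentation domain (truth side).
.contact_force <- function(delta, F1, a, k_cell, delta0, Delta1) {
  ifelse(delta < delta0, F1,
         ifelse(delta <= Delta1, F1 + a * (delta - delta0)^2,
                F1 + a * (Delta1 - delta0)^2 + k_cell * (delta - Delta1)))
}

#' Simulate an approach force curve
#'
#' Below `Z1` the force is the exponential double-layer repulsion; at and
#' beyond `Z1` the contact branch is generated in the indentation domain
#' (flat / Hertz / Hooke, continuous at every transition, anchored at
#' `F1 = A`) and mapped back to `z` by inverting
#' `z - Z1 = delta + (F - F1) / k_c` analytically per branch.  The sample
#' grid is aligned so that `Z1` falls exactly on a sample, keeping the
#' ground truth free of discretisation bias.  An affine baseline and
#' i.i.d. Gaussian noise are added last.
#'
#' @param truth an [approach_truth()].
#' @param n number of samples (>= 500).
#' @param z_range curve span, nm (must bracket `Z1`).
#' @param seed RNG seed (`NULL`: do not touch the RNG state).
#' @param config an [instrument_config()] (`k_c`, `alpha`, `nu`).
#' @return list with `curve` (raw [force_curve()]) and `truth`.
#' @export
simulate_approach_curve <- function(truth = approach_truth(), n = 2700,
                                    z_range = c(-1200, 300) + truth$Z1,
                                    seed = NULL,
                                    config = instrument_config()) {
  stopifnot(inherits(truth, "approach_truth"), n >= 500)
  if (truth$Z1 <= z_range[1] || truth$Z1 >= z_range[2])
    stop("z_range must bracket the contact point Z1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- seq(z_range[1], z_range[2], length.out = n)
  z <- z + (truth$Z1 - z[which.min(abs(z - truth$Z1))])
  F1 <- truth$A
  a <- .hertz_a(truth$E, config)
  k_cell <- truth$k_cell                 # N/m == nN/nm
  k_c <- config$k_c
  F <- numeric(n)
  pre <- z < truth$Z1
  F[pre] <- truth$A * exp(-truth$kappa * (truth$Z1 - z[pre]))
  if (any(!pre)) {
    X <- z[!pre] - truth$Z1              # piezo travel past Z1
    d0 <- truth$delta0
    D1 <- truth$Delta1
    # branch boundaries in piezo travel
    X_hertz_end <- D1 + a * (D1 - d0)^2 / k_c
    delta <- numeric(length(X))
    flat <- X <= d0
    delta[flat] <- X[flat]
    hz <- !flat & X <= X_hertz_end
    if (any(hz)) {
      cc <- a / k_c
      delta[hz] <- if (cc > 0)
        d0 + (-1 + sqrt(1 + 4 * cc * (X[hz] - d0))) / (2 * cc)
      else X[hz]
    }
    hk <- X > X_hertz_end
    if (any(hk))
      delta[hk] <- (X[hk] - a * (D1 - d0)^2 / k_c + k_cell * D1 / k_c) /
        (1 + k_cell / k_c)
    F[!pre] <- .contact_force(delta, F1, a, k_cell, d0, D1)
  }
  F <- F + truth$baseline[1] + truth$baseline[2] * z
  if (truth$noise_sd > 0) F <- F + stats::rnorm(n, 0, truth$noise_sd)
  list(curve = force_curve(z, F, direction = "approach", k_c = k_c),
       truth = truth)
}

#' Ground truth for a synthetic retraction curve
#'
#' Each pull is a named list/vector with `Lc` (nm), `lk` (nm),
#' `rupture_force` (nN, magnitude) and `attach_z` (nm, where the molecule is
#' picked up).  The rupture position of a pull is
#' `Zc + fjc_extension(rupture_force, Lc, lk)`.
#'
#' @param Zc contact point, nm.
#' @param pulls list of pulls, ordered by rupture position.
#' @param noise_sd force noise standard deviation, nN.
#' @param temperature temperature, K.
#' @return list of class `retract_truth` (with derived `rupture_z` per pull).
#' @export
retract_truth <- function(Zc = 0,
                          pulls = list(list(Lc = 312, lk = 0.27,
                                            rupture_force = 0.3,
                                            attach_z = 0)),
                          noise_sd = 0.01, temperature = 298.15) {
  stopifnot(noise_sd >= 0, temperature > 0)
  pulls <- lapply(pulls, function(p) {
    stopifnot(p$Lc > 0, p$lk > 0, p$rupture_force > 0)
    p$rupture_z <- Zc + fjc_extension(p$rupture_force, p$Lc, p$lk,
                                      temperature)
    p
  })
  if (length(pulls) > 1L) {
    rz <- vapply(pulls, `[[`, numeric(1), "rupture_z")
    if (is.unsorted(rz, strictly = TRUE))
      stop("pulls must be ordered by strictly increasing rupture position",
           call. = FALSE)
  }
  structure(list(Zc = Zc, pulls = pulls, noise_sd = noise_sd,
                 temperature = temperature),
            class = "retract_truth")
}

#' Simulate a retraction force curve
#'
#' Generates a sawtooth of FJC pulls: each pull exerts the (negative) FJC
#' force from its attachment point up to its rupture position, obtained by
#' the monotone inversion of the FJC extension (bracketed root-finding to
#' 1e-10 nm); overlapping pulls superpose.  Below the contact point a stiff
#' repulsive ramp is added so the zero-crossing contact-point estimate is
#' well defined.  An affine baseline and Gaussian noise are added last.
#'
#' @param truth a [retract_truth()].
#' @param n number of samples.
#' @param z_range curve span, nm.
#' @param seed RNG seed (`NULL`: leave RNG state alone).
#' @param config an [instrument_config()].
#' @param baseline affine baseline `(intercept, slope)`.
#' @return list with `curve` (raw [force_curve()]) and `truth`.
#' @export
simulate_retract_curve <- function(truth = retract_truth(), n = 2700,
                                   z_range = c(truth$Zc - 40,
                                               truth$Zc + 600),
                                   seed = NULL,
                                   config = instrument_config(),
                                   baseline = c(0.01, 2e-6)) {
  stopifnot(inherits(truth, "retract_truth"), n >= 100)
  if (!is.null(seed)) set.seed(seed)
  z <- seq(z_range[1], z_range[2], length.out = n)
  F <- numeric(n)
  below <- z < truth$Zc
  F[below] <- 0.05 * (truth$Zc - z[below])     # contact repulsion ramp
  for (p in truth$pulls) {
    if (p$rupture_z >= z_range[2])
      stop("pull rupture position ", signif(p$rupture_z, 6),
           " nm outside the simulated z range", call. = FALSE)
    act <- which(z >= max(p$attach_z, truth$Zc) & z <= p$rupture_z)
    if (length(act) == 0L) next
    x <- z[act] - truth$Zc
    x <- pmin(x, p$Lc * (1 - 1e-9))
    Fm <- vapply(x[x > 0], .fjc_force, numeric(1), Lc = p$Lc, lk = p$lk,
                 temperature = truth$temperature)
    F[act[x > 0]] <- F[act[x > 0]] - Fm
  }
  F <- F + baseline[1] + baseline[2] * z
  if (truth$noise_sd > 0) F <- F + stats::rnorm(n, 0, truth$noise_sd)
  list(curve = force_curve(z, F, direction = "retract", k_c = config$k_c),
       truth = truth)
}

#' Simulate a whole force-volume image
#'
#' Two named presets are provided.  `"approach-demo"` plants a Gaussian
#' dome of contact heights (`Z1`, 300 nm high) over uniform electrostatic
#' and mechanical parameters (A = 0.05 nN, Debye length 10 nm, E = 1 MPa,
#' k_cell = 0.1 N/m), noise-free by default so recovery is exact.
#' `"retract-annulus"` plants FJC pulls (around the experimental modes
#' Lc ~ 312 nm, lk ~ 0.27 nm) only on an annulus of pixels around the grid
#' centre, emulating exopolymers distributed around a cell; off-annulus
#' pixels are bare noise.
#'
#' @param preset `"approach-demo"` or `"retract-annulus"`.
#' @param shape grid `(H, W)`.
#' @param seed RNG seed for the whole image.
#' @param dir optional output directory: when given, a JSON manifest, one
#'   curve file per pixel and `truth_*.tsv` maps are written there.
#' @param noise_sd force noise, nN (`NULL`: preset default -- 0 for
#'   `approach-demo`, 0.005 for `retract-annulus`).
#' @param n samples per curve (`NULL`: preset default -- 2700 for approach,
#'   1500 for retraction).
#' @param config an [instrument_config()].
#' @return An `fv_image` with an extra `truth` field (list of matrices).
#' @export
simulate_fvi <- function(preset = c("approach-demo", "retract-annulus"),
                         shape = c(8, 8), seed = 1, dir = NULL,
                         noise_sd = NULL, n = NULL,
                         config = instrument_config()) {
  preset <- match.arg(preset)
  H <- as.integer(shape[1])
  W <- as.integer(shape[2])
  stopifnot(H >= 2, W >= 2)
  set.seed(seed)
  approach <- vector("list", H * W)
  retract <- vector("list", H * W)
  truth <- list()
  cr <- (H - 1) / 2
  cc <- (W - 1) / 2
  if (preset == "approach-demo") {
    if (is.null(noise_sd)) noise_sd <- 0
    if (is.null(n)) n <- 2700
    Z1_map <- matrix(NA_real_, H, W)
    for (rr in 0:(H - 1)) for (co in 0:(W - 1)) {
      Z1 <- 300 * exp(-((rr - cr)^2 + (co - cc)^2) / (2 * (H / 3)^2))
      Z1_map[rr + 1, co + 1] <- Z1
      tr <- approach_truth(Z1 = Z1, noise_sd = noise_sd)
      sim <- simulate_approach_curve(tr, n = n, config = config)
      cv <- sim$curve
      cv$pixel <- c(rr, co)
      approach[[rr * W + co + 1L]] <- cv
    }
    truth$Z1 <- Z1_map
    truth$E <- matrix(1e6, H, W)
    truth$k_cell <- matrix(0.1, H, W)
    truth$A <- matrix(0.05, H, W)
    truth$kappa_inv <- matrix(10, H, W)
  } else {
    if (is.null(noise_sd)) noise_sd <- 0.005
    if (is.null(n)) n <- 1500
    rad <- sqrt(outer((0:(H - 1) - cr)^2, (0:(W - 1) - cc)^2, `+`))
    r_mid <- min(H, W) / 3
    on_ring <- rad >= r_mid - 0.8 & rad <= r_mid + 0.8
    adhesion <- matrix(0, H, W)
    for (rr in 0:(H - 1)) for (co in 0:(W - 1)) {
      if (on_ring[rr + 1, co + 1]) {
        f_rup <- stats::runif(1, 0.12, 0.3)
        lc <- stats::runif(1, 250, 400)
        tr <- retract_truth(Zc = 0,
                            pulls = list(list(Lc = lc, lk = 0.27,
                                              rupture_force = f_rup,
                                              attach_z = 0)),
                            noise_sd = noise_sd)
        adhesion[rr + 1, co + 1] <- f_rup
      } else {
        tr <- retract_truth(Zc = 0, pulls = list(), noise_sd = noise_sd)
      }
      sim <- simulate_retract_curve(tr, n = n, config = config)
      cv <- sim$curve
      cv$pixel <- c(rr, co)
      retract[[rr * W + co + 1L]] <- cv
    }
    truth$adhesion <- adhesion
    truth$on_ring <- on_ring * 1
  }
  fvi <- structure(
    list(width = W, height = H, pixel_size = 5000 / max(H, W),
         config = config, approach = approach, retract = retract,
         truth = truth),
    class = "fv_image")
  if (!is.null(dir)) write_fvi(fvi, dir)
  fvi
}

#' Write an in-memory force-volume image to disk
#'
#' Produces the JSON manifest, one two-column curve file per pixel
#' (`z_force` dialect) and, if present, `truth_*.tsv` maps.
#'
#' @param fvi an `fv_image`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fvi <- function(fvi, dir) {
  stopifnot(inherits(fvi, "fv_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pixels <- list()
  for (rr in 0:(fvi$height - 1)) for (co in 0:(fvi$width - 1)) {
    k <- rr * fvi$width + co + 1L
    entry <- list(row = rr, col = co)
    for (dirn in c("approach", "retract")) {
      cv <- fvi[[dirn]][[k]]
      if (is.null(cv)) next
      fn <- sprintf("pixel_%d_%d_%s.csv", rr, co, dirn)
      utils::write.table(
        data.frame(z = sprintf("%.17g", cv$z), F = sprintf("%.17g", cv$F)),
        file.path(dir, fn), sep = ",", row.names = FALSE,
        col.names = FALSE, quote = FALSE)
      entry[[dirn]] <- fn
    }
    pixels[[length(pixels) + 1L]] <- entry
  }
  man <- list(width = fvi$width, height = fvi$height,
              pixel_size_nm = fvi$pixel_size, dialect = "z_force",
              config = list(k_c = fvi$config$k_c, alpha = fvi$config$alpha,
                            nu = fvi$config$nu,
                            temperature = fvi$config$temperature,
                            c_inf = fvi$config$c_inf,
                            eps_r = fvi$config$eps_r),
              pixels = pixels)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(fvi$truth))
    for (nm in names(fvi$truth))
      write_matrix_tsv(fvi$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")))
  invisible(path)
}
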