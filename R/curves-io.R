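#' Construct a force curve
#'
#' A force curve is one approach or retraction record of an AFM force
#' measurement: paired piezo positions `z` (nm) and forces `F` (nN), with
#' the cantilever spring constant and an optional pixel coordinate.  The
#' orientation convention used throughout the package is that `z` increases
#' along the vector, the probe-sample contact lying at the largest `z` for
#' approach curves and at the smallest `z` for retraction curves.
#'
#' @param z numeric vector of piezo positions, nm.
#' @param F numeric vector of forces, nN, same length as `z`.
#' @param direction `"approach"` or `"retract"`.
#' @param k_c cantilever spring constant, nN/nm.
#' @param pixel optional integer `(row, col)` grid coordinate (0-based).
#' @param preprocessed logical; has [preprocess_curve()] been applied?
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, F, direction = c("approach", "retract"),
                        k_c = 0.0104, pixel = NULL, preprocessed = FALSE) {
  direction <- match.arg(direction)
  z <- as.numeric(z)
  F <- as.numeric(F)
  if (length(z) != length(F))
    stop("z and F must have the same length", call. = FALSE)
  if (length(z) < 10L)
    stop("a force curve needs at least 10 samples, got ", length(z),
         call. = FALSE)
  if (!all(is.finite(z)) || !all(is.finite(F)))
    stop("non-finite value in force curve data", call. = FALSE)
  if (!is.finite(k_c) || k_c <= 0)
    stop("k_c must be a positive spring constant (nN/nm)", call. = FALSE)
  structure(
    list(z = z, F = F, direction = direction, k_c = k_c,
         pixel = pixel, n = length(z), preprocessed = isTRUE(preprocessed)),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s, n = %d, z in [%.1f, %.1f] nm, k_c = %.4g nN/nm%s\n",
              x$direction, x$n, min(x$z), max(x$z), x$k_c,
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' Instrument and algorithm configuration
#'
#' Bundles the instrument constants and the tunable parameters shared by all
#' curves of a force-volume image.  Defaults correspond to a soft silicon
#' nitride cantilever (conical tip) operated in a dilute 1:1 electrolyte at
#' room temperature.
#'
#' @param k_c cantilever spring constant, nN/nm.
#' @param alpha tip semi-top angle, degrees.
#' @param nu Poisson coefficient of the sample (0.5 = incompressible).
#' @param temperature temperature, K.
#' @param c_inf bulk 1:1 electrolyte concentration, mol/L.
#' @param eps_r relative permittivity of the medium.
#' @param A_max upper bound on the electrostatic prefactor, nN, or `NULL`
#'   for the automatic choice (twice the maximum force in the electrostatic
#'   window).
#' @param baseline_n number of far-from-contact points used for the affine
#'   baseline fit.
#' @param skip_nm initial retraction span past the contact point excluded
#'   from FJC fitting, nm.
#' @param min_region_pts minimum number of samples for an FJC region.
#' @param tau onset threshold for the electrostatic region, nN, or `NULL`
#'   for the automatic choice (three noise standard deviations).
#' @param kappa_bounds allowed range for the inverse Debye length, nm^-1.
#' @param lk_bounds allowed range for the Kuhn length, nm.
#' @param lk_init initial Kuhn length for the FJC fit, nm (kept small so the
#'   search starts inside the steep, convex part of the cost valley).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(k_c = 0.0104, alpha = 35, nu = 0.5,
                              temperature = 298.15, c_inf = 1e-3,
                              eps_r = 78.5, A_max = NULL,
                              baseline_n = 500L, skip_nm = 100,
                              min_region_pts = 5L, tau = NULL,
                              kappa_bounds = c(1 / 200, 2),
                              lk_bounds = c(1e-3, 5), lk_init = 0.01) {
  stopifnot(k_c > 0, temperature > 0, c_inf > 0, eps_r > 0,
            baseline_n >= 4, skip_nm >= 0, min_region_pts >= 2,
            length(kappa_bounds) == 2, all(kappa_bounds > 0),
            kappa_bounds[1] < kappa_bounds[2],
            length(lk_bounds) == 2, all(lk_bounds > 0),
            lk_bounds[1] < lk_bounds[2], lk_init > 0)
  if (alpha <= 0 || alpha >= 90)
    stop("alpha must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (nu < 0 || nu >= 0.5 + 1e-9)
    stop("nu must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(A_max) && A_max <= 0)
    stop("A_max must be positive (nN) or NULL", call. = FALSE)
  structure(
    list(k_c = k_c, alpha = alpha, nu = nu, temperature = temperature,
         c_inf = c_inf, eps_r = eps_r, A_max = A_max,
         baseline_n = as.integer(baseline_n), skip_nm = skip_nm,
         min_region_pts = as.integer(min_region_pts), tau = tau,
         kappa_bounds = kappa_bounds, lk_bounds = lk_bounds,
         lk_init = lk_init),
    class = "instrument_config")
}

#' Read a two-column force-curve text file
#'
#' Files are plain text with two numeric columns separated by commas and/or
#' whitespace; lines starting with `#` (and blank lines) are ignored.
#' Column 1 is the piezo position in nm.  Column 2 is either the force in nN
#' (`dialect = "z_force"`) or the cantilever deflection in nm
#' (`dialect = "z_deflection"`), which is converted to force through Hooke's
#' law `F = k_c * d`.
#'
#' @param path file path.
#' @param dialect meaning of the second column, see above.
#' @param k_c cantilever spring constant, nN/nm; required for the
#'   deflection dialect.
#' @param direction `"approach"` or `"retract"`.
#' @return A raw (unpreprocessed) [force_curve()].
#' @export
parse_curve_file <- function(path, dialect = c("z_force", "z_deflection"),
                             k_c = 0.0104,
                             direction = c("approach", "retract")) {
  dialect <- match.arg(dialect)
  direction <- match.arg(direction)
  if (!file.exists(path))
    stop("curve file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  n <- length(idx)
  if (n < 10L)
    stop("curve file ", path, " has only ", n,
         " data rows (at least 10 required)", call. = FALSE)
  z <- numeric(n)
  v <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[idx[i]]), "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L)
      stop("parse error in ", path, " at line ", idx[i],
           ": expected two numeric columns", call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals))
      stop("parse error in ", path, " at line ", idx[i],
           ": non-numeric field", call. = FALSE)
    if (!all(is.finite(vals)))
      stop("non-finite value in ", path, " at line ", idx[i], call. = FALSE)
    z[i] <- vals[1]
    v[i] <- vals[2]
  }
  F <- if (dialect == "z_deflection") k_c * v else v
  force_curve(z, F, direction = direction, k_c = k_c)
}

#' Pre-process a raw force curve
#'
#' Sorts the samples by increasing `z` (stable sort; exact duplicate `z`
#' values are averaged so the result is strictly increasing) and subtracts
#' an affine baseline fitted by ordinary least squares to the far-from-contact
#' end of the curve: the first `baseline_n` sorted points for an approach
#' curve, the last `baseline_n` for a retraction curve (whose contact lies at
#' the smallest `z`).
#'
#' @param curve a [force_curve()].
#' @param config an [instrument_config()]; only `baseline_n` is used.
#' @return A new, preprocessed `force_curve`; the input is not modified.
#' @export
preprocess_curve <- function(curve, config = instrument_config()) {
  stopifnot(inherits(curve, "force_curve"))
  ord <- order(curve$z)              # radix sort: stable
  z <- curve$z[ord]
  F <- curve$F[ord]
  if (anyDuplicated(z)) {
    F <- as.numeric(tapply(F, match(z, z), mean))
    z <- unique(z)
  }
  n <- length(z)
  m <- config$baseline_n
  if (n <= m) {
    m <- max(4L, n %/% 4L)
    warning("baseline window shrunk to ", m, " points (curve has only ",
            n, " samples)", call. = FALSE)
  }
  # never let the baseline window reach beyond the far third of the curve:
  # on short records a fixed 500-point window would swallow signal
  m <- min(m, max(4L, n %/% 3L))
  win <- if (curve$direction == "approach") seq_len(m) else (n - m + 1L):n
  fit <- stats::lm.fit(cbind(1, z[win] - mean(z[win])), F[win])
  F <- F - (fit$coefficients[1] + fit$coefficients[2] * (z - mean(z[win])))
  force_curve(z, F, direction = curve$direction, k_c = curve$k_c,
              pixel = curve$pixel, preprocessed = TRUE)
}

#' Empirical noise variance of a force curve
#'
#' Unbiased sample variance of the force over the flat, non-contact end of a
#' preprocessed curve (the low-`z` end for approach, the high-`z` end for
#' retraction).  Used as the default stopping threshold for segmentation.
#'
#' @param curve a preprocessed [force_curve()].
#' @param flat_fraction fraction of the samples taken from the flat end.
#' @return Noise variance, nN^2.
#' @export
estimate_noise_variance <- function(curve, flat_fraction = 0.25) {
  stopifnot(inherits(curve, "force_curve"),
            flat_fraction > 0, flat_fraction <= 1)
  n <- curve$n
  w <- floor(flat_fraction * n)
  if (w < 10L)
    stop("flat window has fewer than 10 points", call. = FALSE)
  win <- if (curve$direction == "approach") seq_len(w) else (n - w + 1L):n
  stats::var(curve$F[win])
}

#' Load a force-volume image from a JSON manifest
#'
#' The manifest is a JSON object
#' `{width, height, pixel_size_nm, config{...}, pixels:[{row, col, approach,
#' retract}]}` whose `approach`/`retract` entries are curve-file paths
#' relative to the manifest location.  Pixels may be omitted (they are
#' masked); `row`/`col` are 0-based, row-major.  Optional manifest fields
#' `dialect` (default `"z_force"`) and any [instrument_config()] argument
#' under `config` are honoured.
#'
#' @param manifest_path path to the JSON manifest.
#' @param preprocess apply [preprocess_curve()] to every curve (default).
#' @return An object of class `fv_image` with fields `width`, `height`,
#'   `pixel_size`, `config`, and row-major lists `approach` and `retract`
#'   of curves (`NULL` where missing).
#' @export
read_fvi <- function(manifest_path, preprocess = TRUE) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  for (f in c("width", "height", "pixel_size_nm", "pixels"))
    if (is.null(man[[f]]))
      stop("manifest is missing required field '", f, "'", call. = FALSE)
  W <- as.integer(man$width)
  H <- as.integer(man$height)
  if (is.na(W) || is.na(H) || W < 1 || H < 1)
    stop("manifest width/height must be positive integers", call. = FALSE)
  cfg_args <- if (is.null(man$config)) list() else man$config
  config <- do.call(instrument_config, cfg_args)
  dialect <- if (is.null(man$dialect)) "z_force" else man$dialect
  base <- dirname(manifest_path)
  approach <- vector("list", W * H)
  retract <- vector("list", W * H)
  seen <- logical(W * H)
  for (px in man$pixels) {
    if (is.null(px$row) || is.null(px$col))
      stop("manifest pixel entry lacks row/col", call. = FALSE)
    r <- as.integer(px$row)
    co <- as.integer(px$col)
    if (is.na(r) || is.na(co) || r < 0 || r >= H || co < 0 || co >= W)
      stop("manifest pixel (", px$row, ", ", px$col,
           ") outside the ", H, "x", W, " grid", call. = FALSE)
    k <- r * W + co + 1L
    if (seen[k])
      stop("duplicate manifest entry for pixel (", r, ", ", co, ")",
           call. = FALSE)
    seen[k] <- TRUE
    for (dir in c("approach", "retract")) {
      rel <- px[[dir]]
      if (is.null(rel)) next
      fp <- file.path(base, rel)
      if (!file.exists(fp))
        stop("curve file for pixel (", r, ", ", co, ") missing: ", fp,
             call. = FALSE)
      cv <- parse_curve_file(fp, dialect = dialect, k_c = config$k_c,
                             direction = dir)
      cv$pixel <- c(r, co)
      if (preprocess) cv <- preprocess_curve(cv, config)
      if (dir == "approach") approach[[k]] <- cv else retract[[k]] <- cv
    }
  }
  structure(
    list(width = W, height = H, pixel_size = as.numeric(man$pixel_size_nm),
         config = config, approach = approach, retract = retract),
    class = "fv_image")
}

#' @export
print.fv_image <- function(x, ...) {
  na <- sum(!vapply(x$approach, is.null, logical(1)))
  nr <- sum(!vapply(x$retract, is.null, logical(1)))
  cat(sprintf("<fv_image> %dx%d grid, pixel size %.3g nm, %d approach / %d retract curves\n",
              x$height, x$width, x$pixel_size, na, nr))
  invisible(x)
}

#' Write a numeric matrix as TSV
#'
#' One line per row, tab-separated, 17 significant digits (lossless for
#' doubles); masked cells are written as the literal token `NaN`.
#'
#' @param mat numeric matrix (may contain `NaN`/`NA`).
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  mat <- as.matrix(mat)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    s <- ifelse(is.finite(v), sprintf("%.17g", v), "NaN")
    writeLines(paste(s, collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  mat <- do.call(rbind, lapply(rows, as.numeric))
  mat
}
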