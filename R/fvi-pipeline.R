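# Whole-image orchestration: per-pixel fitting, parameter maps, pooled
# histograms, result tables and the command-line entry point.  Pixels are
# processed sequentially and independently; no state crosses pixels, so a
# sub-grid yields identical results to the full grid.

#' Construct a parameter map
#'
#' @param name parameter identifier.
#' @param values H x W numeric matrix; masked cells must be `NaN`.
#' @param mask H x W logical matrix, `TRUE` = valid.
#' @param units unit string.
#' @return object of class `parameter_map`.
#' @export
parameter_map <- function(name, values, mask = is.finite(values),
                          units = "") {
  values <- as.matrix(values)
  mask <- as.matrix(mask)
  stopifnot(all(dim(values) == dim(mask)))
  values[!mask] <- NaN
  structure(list(name = name, values = values, mask = mask, units = units),
            class = "parameter_map")
}

# Freedman-Diaconis histogram (falls back to Sturges for tiny/degenerate
# samples); returns NULL when no valid values exist.
.make_histogram <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NULL)
  nb <- tryCatch(max(1L, grDevices::nclass.FD(v)),
                 error = function(e) grDevices::nclass.Sturges(v))
  if (!is.finite(nb) || nb < 1L) nb <- 1L
  h <- graphics::hist(v, breaks = nb, plot = FALSE)
  list(edges = h$breaks, counts = h$counts, n = length(v))
}

#' Process every approach curve of a force-volume image
#'
#' Applies [process_approach()] to each pixel with one shared
#' configuration, then assembles parameter maps (topography, `A`,
#' `kappa_inv`, `E`, `k_cell`), pooled histograms and a per-pixel table.
#' The topography is `max(Z1) - Z1`, the image maximum defining zero
#' height.  Pixels whose fit failed (or with no curve) are masked.
#'
#' @param fvi an `fv_image` (from [read_fvi()] or [simulate_fvi()]).
#' @param config shared configuration (default: the image's).
#' @param ... passed to [process_approach()].
#' @return list of class `fvi_result` with `mode`, `maps` (named
#'   [parameter_map()]s), `histograms`, `per_pixel` (data frame) and
#'   `results` (per-pixel fit objects).
#' @export
process_fvi_approach <- function(fvi, config = fvi$config, ...) {
  stopifnot(inherits(fvi, "fv_image"))
  H <- fvi$height
  W <- fvi$width
  get <- function(res, f) if (is.null(res)) NA_real_ else res[[f]]
  results <- vector("list", H * W)
  for (k in seq_len(H * W)) {
    cv <- fvi$approach[[k]]
    if (is.null(cv)) next
    results[[k]] <- process_approach(cv, config, ...)
  }
  field_mat <- function(f) {
    matrix(vapply(results, function(res) {
      v <- get(res, f)
      if (!is.null(res) && res$status != "ok") NA_real_ else v
    }, numeric(1)), H, W, byrow = TRUE)
  }
  Z1 <- field_mat("Z1")
  topo <- if (all(!is.finite(Z1))) Z1 else max(Z1, na.rm = TRUE) - Z1
  maps <- list(
    topography = parameter_map("topography", topo, units = "nm"),
    A = parameter_map("A", field_mat("A"), units = "nN"),
    kappa_inv = parameter_map("kappa_inv", field_mat("kappa_inv"),
                              units = "nm"),
    E = parameter_map("E", field_mat("E"), units = "Pa"),
    k_cell = parameter_map("k_cell", field_mat("k_cell"), units = "N/m"))
  histograms <- lapply(maps[c("A", "kappa_inv", "E", "k_cell")],
                       function(m) .make_histogram(m$values))
  rowcol <- expand.grid(col = 0:(W - 1), row = 0:(H - 1))[, c("row", "col")]
  per_pixel <- data.frame(
    rowcol,
    status = vapply(results, function(res)
      if (is.null(res)) "missing" else res$status, character(1)),
    Z1 = as.vector(t(Z1)),
    A = as.vector(t(maps$A$values)),
    kappa_inv = as.vector(t(maps$kappa_inv$values)),
    E = as.vector(t(maps$E$values)),
    k_cell = as.vector(t(maps$k_cell$values)))
  structure(list(mode = "approach", maps = maps, histograms = histograms,
                 per_pixel = per_pixel, results = results,
                 shape = c(H, W)),
            class = "fvi_result")
}

#' Process every retraction curve of a force-volume image
#'
#' Applies [process_retract()] per pixel (taking the contact point from the
#' paired approach fit's `Z1` when an approach curve exists, else from the
#' zero-crossing rule), pools `Lc`, `lk`, `N`, `deltaL`, rupture-count and
#' adhesion histograms over all pixels, and builds the last-adhesion-force
#' and last-rupture-distance maps.  Pixels with no detected region
#' contribute zero adhesion (polymer absent or not detectable); their
#' rupture distance is masked.
#'
#' @param fvi an `fv_image`.
#' @param config shared configuration (default: the image's).
#' @param ... passed to [process_retract()].
#' @return an `fvi_result` (see [process_fvi_approach()]).
#' @export
process_fvi_retract <- function(fvi, config = fvi$config, ...) {
  stopifnot(inherits(fvi, "fv_image"))
  H <- fvi$height
  W <- fvi$width
  results <- vector("list", H * W)
  for (k in seq_len(H * W)) {
    cv <- fvi$retract[[k]]
    if (is.null(cv)) next
    Zc <- NULL
    if (!is.null(fvi$approach[[k]])) {
      af <- process_approach(fvi$approach[[k]], config)
      if (af$status == "ok") Zc <- af$Z1
    }
    results[[k]] <- process_retract(cv, Zc = Zc, config = config, ...)
  }
  adh <- matrix(NA_real_, H, W)
  dist <- matrix(NA_real_, H, W)
  nrup <- matrix(NA_real_, H, W)
  pool <- list(Lc = numeric(0), lk = numeric(0), N = numeric(0),
               deltaL = numeric(0), last_adhesion_force = numeric(0),
               n_ruptures = numeric(0))
  for (k in seq_len(H * W)) {
    res <- results[[k]]
    if (is.null(res)) next
    i <- (k - 1L) %/% W + 1L
    j <- (k - 1L) %% W + 1L
    if (res$status == "ok") {
      adh[i, j] <- res$last_adhesion_force
      dist[i, j] <- res$last_rupture_distance
      nrup[i, j] <- res$n_ruptures
      pool$Lc <- c(pool$Lc, vapply(res$regions, `[[`, numeric(1), "Lc"))
      pool$lk <- c(pool$lk, vapply(res$regions, `[[`, numeric(1), "lk"))
      pool$N <- c(pool$N, vapply(res$regions, `[[`, numeric(1), "N"))
      pool$deltaL <- c(pool$deltaL, res$deltaL)
      pool$last_adhesion_force <- c(pool$last_adhesion_force,
                                    res$last_adhesion_force)
      pool$n_ruptures <- c(pool$n_ruptures, res$n_ruptures)
    } else {
      adh[i, j] <- 0            # absent or not detectable
      nrup[i, j] <- 0
    }
  }
  maps <- list(
    last_adhesion_force = parameter_map("last_adhesion_force", adh,
                                        units = "nN"),
    last_rupture_distance = parameter_map("last_rupture_distance", dist,
                                          units = "nm"),
    n_ruptures = parameter_map("n_ruptures", nrup, units = "count"))
  histograms <- lapply(pool, .make_histogram)
  rowcol <- expand.grid(col = 0:(W - 1), row = 0:(H - 1))[, c("row", "col")]
  per_pixel <- data.frame(
    rowcol,
    status = vapply(results, function(res)
      if (is.null(res)) "missing" else res$status, character(1)),
    n_regions = vapply(results, function(res)
      if (is.null(res)) NA_integer_ else length(res$regions), integer(1)),
    n_ruptures = as.vector(t(nrup)),
    last_adhesion_force = as.vector(t(adh)),
    last_rupture_distance = as.vector(t(dist)))
  structure(list(mode = "retract", maps = maps, histograms = histograms,
                 per_pixel = per_pixel, results = results,
                 shape = c(H, W)),
            class = "fvi_result")
}

#' @export
print.fvi_result <- function(x, ...) {
  cat(sprintf("<fvi_result> mode %s, %dx%d grid, %d valid pixel(s)\n",
              x$mode, x$shape[1], x$shape[2], sum(x$per_pixel$status == "ok")))
  invisible(x)
}

#' Write an FVI result bundle to a directory
#'
#' Emits one TSV matrix per parameter map, one TSV (edges/counts) per
#' histogram, the per-pixel table and a JSON run-metadata file.
#'
#' @param bundle an `fvi_result`.
#' @param dir output directory (created if needed).
#' @param metadata optional named list merged into the metadata JSON.
#' @return `dir`, invisibly.
#' @export
write_fvi_bundle <- function(bundle, dir, metadata = list()) {
  stopifnot(inherits(bundle, "fvi_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$maps))
    write_matrix_tsv(bundle$maps[[nm]]$values,
                     file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(bundle$histograms)) {
    h <- bundle$histograms[[nm]]
    if (is.null(h)) next
    df <- data.frame(bin_left = h$edges[-length(h$edges)],
                     bin_right = h$edges[-1], count = h$counts)
    utils::write.table(df, file.path(dir, paste0("hist_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  pp <- bundle$per_pixel
  num <- vapply(pp, is.numeric, logical(1))
  pp[num] <- lapply(pp[num], function(v) sprintf("%.17g", v))
  utils::write.table(pp, file.path(dir, "per_pixel.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- c(list(mode = bundle$mode, shape = bundle$shape,
                 package_version = as.character(utils::packageVersion("forcemap")),
                 r_version = R.version.string),
            metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.cli_usage <- function() {
  paste(
    "usage: forcemap <command> [options]",
    "",
    "commands:",
    "  simulate     --preset NAME --seed S --out DIR [--shape HxW]",
    "               [--noise-sd X] [--n N]",
    "  process-fvi  MANIFEST --mode approach|retract|both --out DIR",
    "  fit-approach CURVE [--kc X] [--json OUT]",
    "  fit-retract  CURVE [--zc X] [--json OUT]",
    sep = "\n")
}

# Tiny deterministic flag parser: --key value pairs plus positionals.
.cli_parse <- function(args, flags) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (!key %in% flags)
        stop("unknown option --", key, call. = FALSE)
      if (i == length(args))
        stop("option --", key, " needs a value", call. = FALSE)
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `process-fvi`, `fit-approach` and
#' `fit-retract` subcommands (see `inst/cli/forcemap.R` for the Rscript
#' wrapper).  Exit codes: 0 success, 2 usage/configuration error, 1
#' runtime failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg, code) {
    message(msg)
    invisible(code)
  }
  if (length(args) == 0L) return(fail(.cli_usage(), 2L))
  cmd <- args[1]
  rest <- args[-1]
  res <- tryCatch({
    switch(
      cmd,
      "simulate" = {
        o <- .cli_parse(rest, c("preset", "seed", "out", "shape",
                                "noise-sd", "n"))
        if (is.null(o$preset) || is.null(o$out))
          stop("simulate needs --preset and --out", call. = FALSE)
        shape <- if (is.null(o$shape)) c(8, 8)
                 else as.integer(strsplit(o$shape, "x")[[1]])
        simulate_fvi(preset = o$preset, shape = shape,
                     seed = if (is.null(o$seed)) 1L else as.integer(o$seed),
                     dir = o$out,
                     noise_sd = if (is.null(o[["noise-sd"]])) NULL
                                else as.numeric(o[["noise-sd"]]),
                     n = if (is.null(o$n)) NULL else as.integer(o$n))
        0L
      },
      "process-fvi" = {
        o <- .cli_parse(rest, c("mode", "out", "seed"))
        if (length(o$positional) != 1L || is.null(o$out))
          stop("process-fvi needs a MANIFEST argument and --out",
               call. = FALSE)
        mode <- if (is.null(o$mode)) "both" else o$mode
        if (!mode %in% c("approach", "retract", "both"))
          stop("--mode must be approach, retract or both", call. = FALSE)
        fvi <- read_fvi(o$positional)
        meta <- list(manifest = o$positional,
                     seed = if (is.null(o$seed)) NA else as.integer(o$seed))
        if (mode %in% c("approach", "both")) {
          has <- any(!vapply(fvi$approach, is.null, logical(1)))
          if (has)
            write_fvi_bundle(process_fvi_approach(fvi),
                             file.path(o$out, "approach"), meta)
        }
        if (mode %in% c("retract", "both")) {
          has <- any(!vapply(fvi$retract, is.null, logical(1)))
          if (has)
            write_fvi_bundle(process_fvi_retract(fvi),
                             file.path(o$out, "retract"), meta)
        }
        0L
      },
      "fit-approach" = {
        o <- .cli_parse(rest, c("kc", "json"))
        if (length(o$positional) != 1L)
          stop("fit-approach needs a CURVE argument", call. = FALSE)
        cfg <- if (is.null(o$kc)) instrument_config()
               else instrument_config(k_c = as.numeric(o$kc))
        cv <- parse_curve_file(o$positional, k_c = cfg$k_c,
                               direction = "approach")
        ft <- process_approach(cv, cfg)
        out <- ft[c("Z0", "Z1", "A", "kappa", "kappa_inv", "delta0",
                    "Delta1", "E", "k_cell", "sse_elec", "sse_contact",
                    "status")]
        if (!is.null(o$json))
          jsonlite::write_json(out, o$json, auto_unbox = TRUE, digits = NA)
        else print(ft)
        0L
      },
      "fit-retract" = {
        o <- .cli_parse(rest, c("zc", "json"))
        if (length(o$positional) != 1L)
          stop("fit-retract needs a CURVE argument", call. = FALSE)
        cfg <- instrument_config()
        cv <- parse_curve_file(o$positional, k_c = cfg$k_c,
                               direction = "retract")
        ft <- process_retract(cv, Zc = if (is.null(o$zc)) NULL
                                       else as.numeric(o$zc), config = cfg)
        if (!is.null(o$json)) {
          out <- list(Zc = ft$Zc, status = ft$status,
                      n_ruptures = ft$n_ruptures, deltaL = ft$deltaL,
                      last_adhesion_force = ft$last_adhesion_force,
                      last_rupture_distance = ft$last_rupture_distance,
                      regions = lapply(ft$regions, function(rg)
                        rg[c("z_a", "z_b", "Lc", "lk", "N", "F_rupture")]))
          jsonlite::write_json(out, o$json, auto_unbox = TRUE, digits = NA)
        } else print(ft)
        0L
      },
      stop("unknown command '", cmd, "'\n", .cli_usage(), call. = FALSE))
  },
  error = function(e) {
    message("forcemap: ", conditionMessage(e))
    msg <- conditionMessage(e)
    if (grepl("unknown|usage|needs|must be|not found|missing|schema",
              msg)) 2L else 1L
  })
  invisible(as.integer(res))
}
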