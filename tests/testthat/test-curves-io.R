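test_that("curve files read back identically in both dialects", {
  z <- 0:11
  v <- seq(0, 5.5, by = 0.5)
  p <- write_curve_file(curve_lines(z, v))
  cv <- parse_curve_file(p, "z_force")
  expect_equal(cv$z, as.numeric(z))
  expect_equal(cv$F, v)
  expect_equal(cv$n, 12L)

  # deflection dialect applies Hooke's law F = k_c * d
  p2 <- write_curve_file(curve_lines(z, z, sep = " "))
  cv2 <- parse_curve_file(p2, "z_deflection", k_c = 0.0104)
  expect_equal(cv2$F, 0.0104 * z)

  # '#' comments and blank lines are ignored
  p3 <- write_curve_file(c("# header", "", curve_lines(z, v)))
  expect_equal(parse_curve_file(p3, "z_force")$F, v)
})

test_that("malformed curve files fail with informative errors", {
  lines <- curve_lines(0:11, 0:11)
  lines[3] <- "2,abc"
  expect_error(parse_curve_file(write_curve_file(lines), "z_force"),
               "line 3")
  expect_error(parse_curve_file(write_curve_file(curve_lines(0:5, 0:5)),
                                "z_force"),
               "at least 10")
  lines <- curve_lines(0:11, 0:11)
  lines[5] <- "4,Inf"
  expect_error(parse_curve_file(write_curve_file(lines), "z_force"),
               "line 5")
  expect_error(force_curve(0:11, c(0:10, NaN)), "non-finite")
})

test_that("preprocessing sorts, averages duplicates and removes the baseline", {
  cv <- force_curve(c(2, 0, 1, 3:11), c(30, 10, 20, 40:48),
                    direction = "approach")
  out <- preprocess_curve(cv, instrument_config(baseline_n = 4))
  expect_true(all(diff(out$z) > 0))

  # exact affine signal becomes identically zero
  z <- seq(0, 100, length.out = 50)
  F <- 0.1 + 0.001 * z
  out <- preprocess_curve(force_curve(z, F, "approach"),
                          instrument_config(baseline_n = 16))
  expect_lt(max(abs(out$F)), 1e-12)

  # duplicate z values are averaged into one strictly increasing sample
  cv <- force_curve(c(0, 1, 1, 2:10), c(0, 2, 4, rep(1, 9)), "approach")
  out <- suppressWarnings(preprocess_curve(cv, instrument_config(baseline_n = 4)))
  expect_equal(out$n, 11L)
  expect_true(all(diff(out$z) > 0))

  # baseline window shrinks with a warning on short curves
  expect_warning(preprocess_curve(force_curve(1:20, rnorm(20), "approach"),
                                  instrument_config(baseline_n = 500)),
                 "shrunk")
})

test_that("preprocessing is idempotent and the input is untouched", {
  set.seed(1)
  sim <- simulate_approach_curve(ref_truth(0.01), seed = 1)
  before <- sim$curve$F
  once <- preprocess_curve(sim$curve)
  twice <- preprocess_curve(once)
  expect_identical(sim$curve$F, before)
  expect_lt(max(abs(twice$F - once$F)), 1e-12)
})

test_that("baseline-subtracted far field is centred on zero", {
  cfg <- instrument_config()
  sim <- simulate_approach_curve(ref_truth(0.01), seed = 42)
  cv <- preprocess_curve(sim$curve, cfg)
  far <- cv$F[seq_len(cfg$baseline_n)]
  expect_lt(abs(mean(far)), 3 * 0.01 / sqrt(cfg$baseline_n))
})

test_that("noise variance estimation is windowed and calibrated", {
  cv <- force_curve(1:100, rep(2, 100), "approach", preprocessed = TRUE)
  expect_equal(estimate_noise_variance(cv), 0)

  set.seed(7)
  n <- 2000
  cv <- force_curve(seq_len(n), rnorm(n, 0, 0.01), "approach",
                    preprocessed = TRUE)
  expect_lt(rel_err(estimate_noise_variance(cv), 1e-4), 0.15)

  # a contact ramp outside the flat window does not leak in
  F <- c(rnorm(500, 0, 0.01), seq(0, 50, length.out = 1500))
  set.seed(8)
  cv <- force_curve(seq_len(2000), F, "approach", preprocessed = TRUE)
  expect_lt(estimate_noise_variance(cv), 3e-4)

  expect_error(estimate_noise_variance(
    force_curve(1:20, rnorm(20), "approach", preprocessed = TRUE)),
    "fewer than 10")
})

test_that("noise variance estimator is unbiased to 2% over replicates", {
  set.seed(11)
  est <- replicate(200, {
    cv <- force_curve(1:400, rnorm(400, 0, 0.02), "approach",
                      preprocessed = TRUE)
    estimate_noise_variance(cv)
  })
  expect_lt(abs(mean(est) - 4e-4) / 4e-4, 0.02)
})

test_that("FVI manifests load, mask missing pixels and reject bad grids", {
  dir <- tempfile()
  fvi <- simulate_fvi("retract-annulus", shape = c(3, 3), seed = 3,
                      dir = dir, n = 400)
  man <- file.path(dir, "manifest.json")
  got <- read_fvi(man, preprocess = FALSE)
  expect_equal(got$width, 3L)
  expect_equal(got$height, 3L)
  expect_equal(sum(!vapply(got$retract, is.null, logical(1))), 9L)
  # raw values survive the text round trip
  expect_equal(got$retract[[1]]$F, fvi$retract[[1]]$F, tolerance = 1e-12)

  # dropping one pixel entry leaves it masked, others load
  m <- jsonlite::read_json(man, simplifyVector = FALSE)
  m$pixels <- Filter(function(p) !(p$row == 1 && p$col == 1), m$pixels)
  man2 <- file.path(dir, "manifest2.json")
  jsonlite::write_json(m, man2, auto_unbox = TRUE)
  got2 <- read_fvi(man2, preprocess = FALSE)
  expect_null(got2$retract[[1 * 3 + 1 + 1]])
  expect_equal(sum(!vapply(got2$retract, is.null, logical(1))), 8L)

  # pixel outside the declared grid is a schema error
  m$pixels[[1]]$row <- 7
  man3 <- file.path(dir, "manifest3.json")
  jsonlite::write_json(m, man3, auto_unbox = TRUE)
  expect_error(read_fvi(man3), "outside")

  # referenced curve file missing names the pixel
  m <- jsonlite::read_json(man, simplifyVector = FALSE)
  m$pixels[[2]]$retract <- "does_not_exist.csv"
  man4 <- file.path(dir, "manifest4.json")
  jsonlite::write_json(m, man4, auto_unbox = TRUE)
  expect_error(suppressWarnings(read_fvi(man4)), "pixel")
})

test_that("matrix TSV writing is lossless and marks masked cells as NaN", {
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(matrix(0.5, 1, 1), p)
  expect_equal(readLines(p), "0.5")

  m <- matrix(c(1.25, NaN, -3, 7), 2, 2)
  write_matrix_tsv(m, p)
  expect_true(grepl("NaN", paste(readLines(p), collapse = "\n")))

  set.seed(5)
  m <- matrix(rnorm(64), 8, 8)
  m[3, 4] <- NaN
  write_matrix_tsv(m, p)
  expect_identical(read_matrix_tsv(p), m)
})
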