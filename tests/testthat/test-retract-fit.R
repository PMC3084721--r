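kBT298 <- 1.380649e-5 * 298.15

test_that("FJC extension has the correct limits and reference value", {
  # saturation: at enormous force the chain is fully extended
  expect_lt(abs(fjc_extension(1e6, 312, 0.27) - 312), 1e-6 * 312)
  expect_gt(fjc_extension(1e3, 312, 0.27), 0.999 * 312)

  # small-force Langevin series x/Lc -> u/3
  u <- 1e-5
  F <- u * kBT298 / 0.27
  expect_lt(abs(fjc_extension(F, 312, 0.27) / 312 - u / 3), 1e-8)

  # 100 pN on the modal chain (Lc = 312 nm, lk = 0.27 nm): u ~ 6.56,
  # x ~ 264.4 nm (direct evaluation of the Langevin expression)
  u <- 0.1 * 0.27 / kBT298
  ref <- 312 * ((exp(u) + exp(-u)) / (exp(u) - exp(-u)) - 1 / u)
  x <- fjc_extension(0.1, 312, 0.27)
  expect_lt(abs(x - ref), 1e-9)
  expect_lt(abs(x - 264.5), 0.2)

  expect_error(fjc_extension(-0.1, 312, 0.27), "positive")
  expect_error(fjc_extension(0, 312, 0.27), "positive")
})

test_that("FJC extension is strictly increasing in force and below Lc", {
  set.seed(31)
  for (i in 1:20) {
    Lc <- runif(1, 50, 1000)
    lk <- runif(1, 0.05, 2)
    F <- sort(runif(50, 1e-4, 2))
    x <- fjc_extension(F, Lc, lk)
    expect_true(all(diff(x) > 0))
    expect_true(all(x > 0 & x < Lc))
  }
})

test_that("decreasing regions are detected with skip and sign rules", {
  # noise-free sawtooth of three affine pulls separated by upward jumps
  z <- seq(0, 500, length.out = 1000)
  F <- numeric(1000)
  pulls <- list(c(110, 190), c(200, 290), c(300, 420))
  for (p in pulls) {
    sel <- z >= p[1] & z <= p[2]
    F[sel] <- -0.02 - 0.25 * (z[sel] - p[1]) / (p[2] - p[1])
  }
  cv <- force_curve(z, F, "retract", preprocessed = TRUE)
  seg <- segment_curve(cv, r = 1L, k_max = 20L, eps = 0)
  rg <- detect_regions(cv, seg, 0, noise_sd = 0)
  expect_equal(length(rg), 3L)
  for (j in 1:3) {
    expect_lt(abs(cv$z[rg[[j]][1]] - pulls[[j]][1]), 3)
    expect_lt(abs(cv$z[rg[[j]][2]] - pulls[[j]][2]), 3)
  }

  # a pull entirely inside the first 100 nm is skipped
  F2 <- numeric(1000)
  sel <- z >= 20 & z <= 90
  F2[sel] <- -0.02 - 0.2 * (z[sel] - 20) / 70
  cv2 <- force_curve(z, F2, "retract", preprocessed = TRUE)
  seg2 <- segment_curve(cv2, r = 1L, k_max = 20L, eps = 0)
  expect_equal(length(detect_regions(cv2, seg2, 0, noise_sd = 0)), 0L)

  # a decreasing region whose interior still has non-negative force is
  # inconsistent with adhesive stretching and is dropped whole
  F3 <- numeric(1000)
  sel <- z >= 150 & z <= 300
  F3[sel] <- 0.1 - 0.2 * (z[sel] - 150) / 150   # positive over half its span
  cv3 <- force_curve(z, F3, "retract", preprocessed = TRUE)
  seg3 <- segment_curve(cv3, r = 1L, k_max = 20L, eps = 0)
  rg3 <- detect_regions(cv3, seg3, 0, noise_sd = 0)
  expect_equal(length(rg3), 0L)
  expect_gte(attr(rg3, "n_sign_excluded"), 1L)
})

test_that("FJC region fits are exact without noise and report N = Lc/lk", {
  tr <- retract_truth(Zc = 0, noise_sd = 0)
  sim <- simulate_retract_curve(tr, seed = 1)
  cv <- preprocess_curve(sim$curve)
  zb <- tr$pulls[[1]]$rupture_z
  sel <- cv$z >= 100 & cv$z <= zb & cv$F < 0
  ft <- fit_fjc_region(cv$z[sel], cv$F[sel], 0, z_b = max(cv$z[sel]))
  expect_lt(rel_err(ft$Lc, 312), 0.005)
  expect_lt(rel_err(ft$lk, 0.27), 0.005)
  expect_equal(ft$N, ft$Lc / ft$lk)
  expect_error(fit_fjc_region(c(1, 2, 3), c(-1, 0.1, -1), 0),
               "negative")
})

test_that("FJC recovery holds under force noise (seeded replicates)", {
  errs <- t(sapply(1:30, function(s) {
    tr <- retract_truth(Zc = 0, noise_sd = 0.01)
    sim <- simulate_retract_curve(tr, seed = 500 + s)
    ft <- process_retract(sim$curve, Zc = 0)
    if (ft$status != "ok") return(c(NA, NA))
    last <- ft$regions[[length(ft$regions)]]
    c(rel_err(last$Lc, 312), rel_err(last$lk, 0.27))
  }))
  expect_gt(mean(!is.na(errs[, 1])), 0.85)
  expect_lt(median(errs[, 1], na.rm = TRUE), 0.03)
  expect_lt(median(errs[, 2], na.rm = TRUE), 0.15)
})

test_that("fit residual at the optimum never exceeds residual at truth", {
  tr <- retract_truth(Zc = 0, noise_sd = 0.01)
  sim <- simulate_retract_curve(tr, seed = 71)
  cv <- preprocess_curve(sim$curve)
  zb <- tr$pulls[[1]]$rupture_z
  sel <- cv$z >= 100 & cv$z <= zb - 1 & cv$F < 0
  ft <- fit_fjc_region(cv$z[sel], cv$F[sel], 0, z_b = max(cv$z[sel]),
                       reweight = FALSE)
  x <- cv$z[sel]
  g_true <- fjc_extension(-cv$F[sel], 312, 0.27) / 312
  sse_truth <- sum((x - 312 * g_true)^2)
  expect_lte(ft$sse, sse_truth + 1e-9)
})

test_that("recovery is invariant to rigid z-translation with Zc", {
  tr <- retract_truth(Zc = 0, noise_sd = 0.005)
  sim <- simulate_retract_curve(tr, seed = 72)
  cv <- preprocess_curve(sim$curve)
  ft1 <- process_retract(cv, Zc = 0)
  cv2 <- force_curve(cv$z + 777, cv$F, "retract", preprocessed = TRUE)
  ft2 <- process_retract(cv2, Zc = 777)
  expect_equal(length(ft1$regions), length(ft2$regions))
  expect_lt(abs(ft1$regions[[1]]$Lc - ft2$regions[[1]]$Lc), 1e-6)
  expect_lt(abs(ft1$regions[[1]]$lk - ft2$regions[[1]]$lk), 1e-6)
})

test_that("a three-pull sawtooth yields three fits and the planted deltaL", {
  mk_pull <- function(Lc, lk, x_target, attach) {
    f <- uniroot(function(F) fjc_extension(F, Lc, lk) - x_target,
                 c(1e-6, 1e4), tol = 1e-12)$root
    list(Lc = Lc, lk = lk, rupture_force = f, attach_z = attach)
  }
  # rupture positions 150 / 215 / 300 nm: deltaL = 65, 85 nm
  pulls <- list(mk_pull(180, 0.27, 150, 0), mk_pull(250, 0.30, 215, 0),
                mk_pull(340, 0.25, 300, 0))
  tr <- retract_truth(Zc = 0, pulls = pulls, noise_sd = 0.005)
  sim <- simulate_retract_curve(tr, seed = 73)
  ft <- process_retract(sim$curve, Zc = 0)
  expect_equal(ft$status, "ok")
  expect_equal(length(ft$regions), 3L)
  expect_equal(ft$n_ruptures, 4L)
  st <- rupture_statistics(ft)
  expect_equal(st$deltaL, c(65, 85), tolerance = 0.05)
  expect_lt(abs(st$last_rupture_distance - 300), 3)
  expect_lt(rel_err(st$last_adhesion_force,
                    pulls[[3]]$rupture_force), 0.15)
})

test_that("flat noise and single pulls give the degenerate statistics", {
  set.seed(74)
  tr <- retract_truth(Zc = 0, pulls = list(), noise_sd = 0.01)
  sim <- simulate_retract_curve(tr, seed = 74)
  ft <- process_retract(sim$curve, Zc = 0)
  expect_true(ft$status %in% c("no_regions", "excluded"))
  expect_equal(ft$n_ruptures, 0L)
  expect_equal(ft$deltaL, numeric(0))

  tr1 <- retract_truth(Zc = 0, noise_sd = 0.005)
  sim1 <- simulate_retract_curve(tr1, seed = 75)
  ft1 <- process_retract(sim1$curve, Zc = 0)
  expect_equal(ft1$status, "ok")
  expect_equal(length(ft1$deltaL), length(ft1$regions) - 1L)
  expect_equal(ft1$last_adhesion_force,
               ft1$regions[[length(ft1$regions)]]$F_rupture)
})

test_that("the zero-crossing contact-point estimate lands near contact", {
  tr <- retract_truth(Zc = 50, noise_sd = 0.005)
  sim <- simulate_retract_curve(tr, seed = 76)
  ft <- process_retract(sim$curve)
  expect_lt(abs(ft$Zc - 50), 5)
})

test_that("two planted Kuhn-length populations are resolved bimodally", {
  lks <- rep(c(0.07, 0.27), each = 12)
  fits <- sapply(seq_along(lks), function(i) {
    tr <- retract_truth(Zc = 0,
                        pulls = list(list(Lc = 312, lk = lks[i],
                                          rupture_force = 0.3,
                                          attach_z = 0)),
                        noise_sd = 0.005)
    sim <- simulate_retract_curve(tr, seed = 600 + i)
    ft <- process_retract(sim$curve, Zc = 0)
    if (ft$status != "ok") return(NA_real_)
    ft$regions[[length(ft$regions)]]$lk
  })
  fits <- fits[!is.na(fits)]
  h <- hist(fits, breaks = seq(0, 0.55, by = 0.05), plot = FALSE)
  top2 <- order(h$counts, decreasing = TRUE)[1:2]
  mids <- sort(h$mids[top2])
  expect_lt(abs(mids[1] - 0.07), 0.05 + 1e-9)
  expect_lt(abs(mids[2] - 0.27), 0.05 + 1e-9)
})
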