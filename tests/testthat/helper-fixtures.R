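# Shared fixture builders: everything is generated in code at test time.

write_curve_file <- function(lines) {
  tmp <- tempfile(fileext = ".csv")
  writeLines(lines, tmp)
  tmp
}

# simple two-column z,value rows
curve_lines <- function(z, v, sep = ",") {
  paste(format(z, digits = 17), format(v, digits = 17), sep = sep)
}

# step signal with a single jump at 1-based index `at`
step_curve <- function(n = 100, at = 51, lo = 0, hi = 1) {
  force_curve(seq_len(n) - 1, ifelse(seq_len(n) < at, lo, hi),
              direction = "approach", preprocessed = TRUE)
}

# piecewise-affine signal with jump discontinuities at the given 1-based
# indices (jumps are large so greedy finds them one by one)
jump_curve <- function(n = 200, at = c(51, 101, 151),
                       levels = c(0, 5, -3, 2), slopes = c(0.02, -0.01, 0.03, 0)) {
  z <- seq_len(n) - 1
  F <- numeric(n)
  bounds <- c(1, at, n + 1)
  for (j in seq_len(length(bounds) - 1)) {
    idx <- bounds[j]:(bounds[j + 1] - 1)
    F[idx] <- levels[j] + slopes[j] * (z[idx] - z[idx[1]])
  }
  force_curve(z, F, direction = "approach", preprocessed = TRUE)
}

# random two-level noisy signal for oracle comparisons
noisy_shift_curve <- function(seed, n = 150) {
  set.seed(seed)
  cut <- sample(seq(n %/% 4, 3 * n %/% 4), 1)
  F <- c(stats::rnorm(cut, 0, 1), stats::rnorm(n - cut, 1.5, 1))
  force_curve(seq_len(n), F, direction = "approach", preprocessed = TRUE)
}

# truth values shared by the approach recovery tests (the package's
# reference study conditions)
ref_truth <- function(noise_sd = 0.01) {
  approach_truth(Z1 = 0, A = 0.05, kappa = 0.1, E = 1e6, k_cell = 0.1,
                 delta0 = 0, Delta1 = 50, noise_sd = noise_sd)
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
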