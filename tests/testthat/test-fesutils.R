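# FES post-processing: entropic correction, zero shift, reweighting,
# binding extraction, profile comparison, fes.dat I/O

kbt300 <- 8.3145e-3 * 300

test_that("entropic correction applies (n-1) R T ln r and guards double
           application", {
  ax <- grid_axis("dist", 0.5, 2.0, n = 16)
  fes <- fes_grid(list(ax), rep(0, 16))
  out <- entropic_correction(fes, n_dims = 3, temperature = 300)
  # r = 1 nm -> zero correction; r = 2 nm -> 2 RT ln 2 = 3.458 kJ/mol
  expect_equal(fes_at(out, 1), 0, tolerance = 1e-9)
  expect_equal(fes_at(out, 2), 2 * 8.3145e-3 * 300 * log(2),
               tolerance = 1e-9)
  expect_equal(fes_at(out, 2), 3.458, tolerance = 1e-3)
  expect_error(entropic_correction(out), "already applied")
  # n = 1: identically zero correction
  f1 <- entropic_correction(fes_grid(list(ax), rep(1.5, 16)), n_dims = 1)
  expect_equal(as.numeric(f1$values), rep(1.5, 16))
})

test_that("entropic correction NAs out nonpositive distances with a warning", {
  ax <- grid_axis("dist", 0, 1, n = 11)
  fes <- fes_grid(list(ax), rep(0, 11))
  expect_warning(out <- entropic_correction(fes), "r <= 0")
  expect_true(is.na(out$values[1]))
  expect_false(anyNA(out$values[-1]))
})

test_that("zero shift is idempotent, gauge invariant, and zeroes the tail", {
  ax <- grid_axis("dist", 0.3, 2.0, n = 35)
  v <- -3 * exp(-(ax$nodes - 0.55)^2 / (2 * 0.08^2)) + 4.2
  fes <- fes_grid(list(ax), v)
  s1 <- zero_shift(fes)
  sel <- ax$nodes >= 1.6 & ax$nodes <= 1.8
  expect_lt(abs(mean(s1$values[sel])), 1e-9)
  expect_true(s1$zero_shifted)
  # idempotence
  s2 <- zero_shift(s1)
  expect_equal(s2$values, s1$values, tolerance = 1e-12)
  # gauge invariance: adding any constant changes nothing after the shift
  s3 <- zero_shift(fes_grid(list(ax), v + 123.4))
  expect_equal(s3$values, s1$values, tolerance = 1e-9)
  # window outside the grid
  expect_error(zero_shift(fes, window = c(5, 6)), "outside")
})

test_that("reweighting with zero bias equals the plain histogram exactly", {
  set.seed(12)
  n <- 5000
  fr <- data.frame(time = 1:n, s = rnorm(n, 0, 0.3), bias = 0)
  traj <- cv_traj(fr, "s", temperature = 300)
  ax <- grid_axis("s", -1.5, 1.5, n = 61)
  fes <- reweight_to_cv(traj, list(ax))
  # independent plain histogram on the same node-centred bins
  idx <- round((fr$s - ax$min) / ax$spacing)
  idx <- idx[idx >= 0 & idx <= ax$n - 1]
  counts <- tabulate(idx + 1, nbins = ax$n)
  ref <- -kbt300 * log(counts / n)
  ref[counts == 0] <- NA
  expect_identical(as.numeric(fes$values), ref)
})

test_that("frozen-bias reweighting recovers the harmonic free energy", {
  # sample U + V with a static Gaussian bump bias, then reweight it away
  k <- 100
  pot <- make_harmonic(k, bounds = c(-0.8, 0.8))
  g <- bias_grid(list(grid_axis("s", -0.85, 0.85, n = 171)), sigmas = 0.1)
  g$values <- g$values + 5 * exp(-g$axes[[1]]$nodes^2 / (2 * 0.3^2))
  traj <- langevin_cv_sample(pot, n_steps = 4e5, seed = 13, x0 = 0,
                             dt = 1e-3, bias = g, record_stride = 2L)
  ax <- grid_axis("s", -0.8, 0.8, n = 81)
  fes <- reweight_to_cv(traj, list(ax))
  sig <- sqrt(kbt300 / k)
  sel <- abs(ax$nodes) <= 2 * sig
  ref <- 0.5 * k * ax$nodes^2
  d <- fes$values[sel] - ref[sel]
  expect_lt(max(abs(d - mean(d))), 0.5)
})

test_that("all-zero weights are reported as a bias/trajectory mismatch", {
  fr <- data.frame(time = 1:10, s = rnorm(10), bias = -1e6)
  traj <- cv_traj(fr, "s")
  expect_error(reweight_weights(traj), NA)  # large negative bias still works
  fr$bias <- NaN
  expect_error(cv_traj(fr, "s"), "finite")
})

test_that("binding extraction locates shell minima and labels modes", {
  # single T-shaped dip: depth -5 at (0.55 nm, 90 deg)
  fes <- make_dip_fes(list(list(center = c(0.55, pi / 2),
                                width = c(0.05, 0.15), depth = -5)))
  b <- extract_binding(fes)
  expect_equal(b$first_shell$dist, 0.55, tolerance = 0.026)
  expect_equal(b$first_shell$angle_deg, 90, tolerance = 2.6)
  expect_equal(b$first_shell$depth, -5, tolerance = 0.05)
  expect_equal(b$mode, "T-shaped")

  # stacked dip at 10 deg
  fes2 <- make_dip_fes(list(list(center = c(0.5, 10 * pi / 180),
                                 width = c(0.05, 0.15), depth = -4)))
  expect_equal(extract_binding(fes2)$mode, "stacked")

  # two dips, deeper one in the second shell: first shell reports its own
  fes3 <- make_dip_fes(list(
    list(center = c(0.55, pi / 2), width = c(0.05, 0.15), depth = -3),
    list(center = c(0.95, pi / 2), width = c(0.05, 0.15), depth = -7)))
  b3 <- extract_binding(fes3)
  expect_equal(b3$first_shell$depth, -3, tolerance = 0.1)
  expect_equal(b3$second_shell$depth, -7, tolerance = 0.1)
  expect_equal(b3$second_shell$dist, 0.95, tolerance = 0.026)

  # flat zeroed grid: depth 0, mode mixed by convention, with a warning
  flat <- make_dip_fes(list())
  expect_warning(bf <- extract_binding(flat), "flat")
  expect_equal(bf$first_shell$depth, 0)
  expect_equal(bf$mode, "mixed")

  # preconditions: flags must be set
  raw <- fes_grid(flat$axes, flat$values)
  expect_error(extract_binding(raw), "zero-shift")
})

test_that("profile comparison flags pairs differing by more than kBT", {
  mk <- function(depth) make_dip_fes(list(list(
    center = c(0.55, pi / 2), width = c(0.05, 0.15), depth = depth)))
  # identical grids: zero differences, nothing flagged
  cmp0 <- compare_profiles(list(a = mk(-5), b = mk(-5)))
  expect_equal(cmp0$pairs$diff, 0)
  expect_false(any(cmp0$pairs$exceeds_kbt))
  expect_equal(cmp0$kbt, 2.494, tolerance = 1e-3)
  # 5 kJ/mol apart: flagged (> kBT); 1 kJ/mol apart: not flagged
  cmp1 <- compare_profiles(list(a = mk(-3), b = mk(-8), c = mk(-4)))
  expect_equal(nrow(cmp1$table), 3)
  expect_equal(nrow(cmp1$pairs), 3)
  ab <- cmp1$pairs$label_a == "a" & cmp1$pairs$label_b == "b"
  ac <- cmp1$pairs$label_a == "a" & cmp1$pairs$label_b == "c"
  expect_true(cmp1$pairs$exceeds_kbt[ab])
  expect_false(cmp1$pairs$exceeds_kbt[ac])
  # mismatched axes are refused
  other <- make_dip_fes(list(list(center = c(0.55, pi / 2),
                                  width = c(0.05, 0.15), depth = -5)),
                        dist_axis = grid_axis("dist", 0.25, 2.0,
                                              spacing = 0.025))
  expect_error(compare_profiles(list(a = mk(-5), b = other)), "mismatched")
})

test_that("fes.dat files round-trip values, errors, axes and flags", {
  fes <- make_dip_fes(list(list(center = c(0.6, 0.3), width = c(0.07, 0.2),
                                depth = -4)), stderr = 0.25)
  path <- withr::local_tempfile(fileext = ".dat")
  write_fes(fes, path)
  back <- read_fes(path)
  expect_equal(back$values, fes$values, tolerance = 1e-9)
  expect_equal(back$stderr, fes$stderr, tolerance = 1e-9)
  expect_true(back$entropic_corrected)
  expect_true(back$zero_shifted)
  expect_equal(back$axes[[1]]$nodes, fes$axes[[1]]$nodes, tolerance = 1e-9)
  # 1-D grids round-trip too
  ax <- grid_axis("s", -1, 1, n = 21)
  f1 <- fes_grid(list(ax), sin(ax$nodes))
  write_fes(f1, path)
  b1 <- read_fes(path)
  expect_equal(as.numeric(b1$values), sin(ax$nodes), tolerance = 1e-9)
})

test_that("ideal-gas MC with corrections gives a flat radial profile and the
           uncorrected profile shows the -2RT ln r shape", {
  sys <- make_ideal_gas_dimer()
  traj <- mc_sample(sys$tmpl_a, sys$tmpl_b, n_steps = 3e5, seed = 14,
                    max_trans = 0.5, tune_steps = 1000L)
  ax <- grid_axis("dist", 0.1, 2.2, spacing = 0.06)
  raw <- reweight_to_cv(traj, list(ax))
  sel <- ax$nodes >= 0.4 & ax$nodes <= 1.7
  # uncorrected: F(r) ~ -2RT ln r + const
  ref <- -2 * kbt300 * log(ax$nodes)
  d <- raw$values[sel] - ref[sel]
  expect_lt(max(abs(d - mean(d))), 0.5)
  fes <- zero_shift(entropic_correction(raw))
  expect_lt(max(abs(fes$values[sel])), 0.5)
})
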