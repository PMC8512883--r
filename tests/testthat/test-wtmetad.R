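# Well-tempered bias engine: deposition law, grid interpolation vs explicit
# hill summation, bias-to-FES relation, HILLS I/O

kbt300 <- 8.3145e-3 * 300

test_that("hill heights follow the well-tempered decay law", {
  g <- bias_grid(list(grid_axis("s", -2, 2, n = 201)), sigmas = 0.1,
                 bias_factor = 5, height0 = 1.0)
  # first hill on an empty grid: height exactly w0 = 1.0 kJ/mol
  d1 <- deposit_hill(g, 0)
  expect_identical(d1$hill$height, 1.0)
  # bias V = (gamma-1) kT at the deposition point: height w0/e
  g2 <- bias_grid(list(grid_axis("s", -2, 2, n = 201)), sigmas = 0.1)
  g2$values[] <- (5 - 1) * kbt300
  d2 <- deposit_hill(g2, 0.3)
  expect_equal(d2$hill$height, exp(-1), tolerance = 1e-12)
  # very large bias: height tends to zero
  g3 <- bias_grid(list(grid_axis("s", -2, 2, n = 201)), sigmas = 0.1)
  g3$values[] <- 1e4
  expect_lt(deposit_hill(g3, 0)$hill$height, 1e-10)
})

test_that("heights are non-increasing when revisiting the same point and
           bias values never decrease", {
  g <- bias_grid(list(grid_axis("s", -2, 2, n = 201)), sigmas = 0.1)
  hs <- numeric(20)
  prev <- g$values
  for (i in 1:20) {
    d <- deposit_hill(g, 0.5, time = i)
    g <- d$grid
    hs[i] <- d$hill$height
    expect_true(all(g$values >= prev - 1e-12))
    prev <- g$values
  }
  expect_true(all(diff(hs) < 0))
})

test_that("gamma <= 1 is rejected as a configuration error", {
  expect_error(bias_grid(list(grid_axis("s", -2, 2, n = 201)),
                         bias_factor = 1), "bias_factor")
})

hill_sum_oracle <- function(hills, pts) {
  # direct summation over the hill list (wrapped torsion displacement)
  direct <- rep(0, nrow(pts))
  for (i in seq_len(nrow(hills))) {
    h <- hills[i, ]
    dd <- pts[, 1] - h$dist
    dt <- pts[, 2] - h$torsion
    dt <- dt - 2 * pi * round(dt / (2 * pi))
    direct <- direct + h$height *
      exp(-dd^2 / (2 * h$sigma_dist^2)) * exp(-dt^2 / (2 * h$sigma_torsion^2))
  }
  direct
}

test_that("grid bias equals explicit hill summation", {
  set.seed(9)
  g <- bias_grid()  # default dist x torsion axes
  centers <- cbind(runif(60, 0.3, 2.0), runif(60, -pi, pi))
  for (i in seq_len(nrow(centers)))
    g <- deposit_hill(g, centers[i, ], time = i)$grid
  # at grid nodes the stored bias is the exact hill sum (only the 6-sigma
  # truncation differs, < 1e-8 of a hill height)
  nodes <- cbind(sample(g$axes[[1]]$nodes, 1000, replace = TRUE),
                 sample(g$axes[[2]]$nodes, 1000, replace = TRUE))
  expect_lt(max(abs(bias_at(g, nodes) - hill_sum_oracle(g$hills, nodes))),
            1e-3)
  # between nodes, bilinear interpolation is accurate to O(dx^2/sigma^2) of
  # the local bias (about 1% at the default resolution)
  pts <- cbind(runif(1000, 0.05, 2.15), runif(1000, -pi, pi))
  expect_lt(max(abs(bias_at(g, pts) - hill_sum_oracle(g$hills, pts))), 0.05)
})

test_that("empty grid is zero everywhere and a single hill peaks at its own
           height", {
  g <- bias_grid()
  pts <- cbind(runif(50, 0, 2.2), runif(50, -pi, pi))
  expect_equal(bias_at(g, pts), rep(0, 50))
  g <- deposit_hill(g, c(0.8, 0.5))$grid
  expect_equal(bias_at(g, c(0.8, 0.5)), 1.0, tolerance = 1e-3)
})

test_that("fes_from_bias applies the -gamma/(gamma-1) prefactor", {
  g <- bias_grid(list(grid_axis("s", -2, 2, n = 41)), sigmas = 0.1,
                 bias_factor = 5)
  f0 <- fes_from_bias(g)
  expect_true(all(f0$values == 0))  # flat bias -> flat FES
  g$values[21] <- 4
  f1 <- fes_from_bias(g)
  expect_equal(f1$values[21] - f1$values[1], -5)  # -1.25 * 4
  g$values <- 2 * g$values
  f2 <- fes_from_bias(g)
  expect_equal(f2$values[21] - f2$values[1], -10)  # linearity
})

test_that("HILLS files round-trip and reject malformed headers", {
  g <- bias_grid()
  set.seed(10)
  for (i in 1:100)
    g <- deposit_hill(g, c(runif(1, 0.3, 2), runif(1, -pi, pi)),
                      time = i)$grid
  path <- withr::local_tempfile(fileext = ".hills")
  write_hills(g$hills, path)
  back <- read_hills(path)
  expect_equal(back, g$hills, tolerance = 1e-9)

  # PLUMED-formatted fixture with 3 hills: parsed heights match the text
  fixture <- c("#! FIELDS time dist torsion sigma_dist sigma_torsion height biasf",
               "500 0.52 1.1 0.05 0.2 1.0 5",
               "1000 0.61 -0.4 0.05 0.2 0.93 5",
               "1500 0.55 2.9 0.05 0.2 0.871 5")
  writeLines(fixture, path)
  fx <- read_hills(path)
  expect_equal(fx$height, c(1.0, 0.93, 0.871))
  expect_equal(fx$dist, c(0.52, 0.61, 0.55))

  # empty hill list -> header-only file -> empty list
  write_hills(g$hills[0, ], path)
  expect_equal(nrow(read_hills(path)), 0)

  writeLines(c("#! FIELDS time x height", "1 2 3"), path)
  expect_error(read_hills(path), "expected columns")
})

test_that("grid_from_hills reproduces the deposited bias", {
  g <- bias_grid()
  set.seed(11)
  for (i in 1:50)
    g <- deposit_hill(g, c(runif(1, 0.3, 2), runif(1, -pi, pi)),
                      time = i)$grid
  empty <- bias_grid()
  rebuilt <- grid_from_hills(g$hills, empty)
  expect_equal(rebuilt$values, g$values, tolerance = 1e-12)
})

test_that("well-tempered run recovers the double-well FES within 1 kJ/mol", {
  traj <- dw_run(11)
  fes <- fes_from_bias(traj$final_grid)
  f <- function(x) fes_at(fes, x)
  # degenerate minima: true dF = 0; barrier height = h = 10 exactly, and the
  # quadrature oracle agrees (F(s) = U(s) + const in 1D)
  kt <- kbt300
  z <- integrate(function(x) exp(-10 * (x^2 - 1)^2 / kt), -1.7, 1.7,
                 rel.tol = 1e-10)$value
  fq <- function(s) 10 * (s^2 - 1)^2 + kt * log(z)
  barrier_true <- fq(0) - (fq(-1) + fq(1)) / 2
  expect_equal(barrier_true, 10, tolerance = 1e-9)
  expect_lt(abs(f(-1) - f(1)), 1.0)
  expect_lt(abs(f(0) - (f(-1) + f(1)) / 2 - barrier_true), 1.0)
})
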