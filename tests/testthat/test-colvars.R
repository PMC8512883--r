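# COG distance, inter-ring torsion, plane-normal angle, COLVAR I/O

t1 <- make_ring_template(1)

test_that("cog distance handles trivial and random cases", {
  st <- dimer_state(c(2, 2, 2), c(2.55, 2, 2))
  expect_equal(cog_distance(st, t1, t1), 0.55, tolerance = 1e-12)
  # minimum image: 4.8 nm apart in a 5 nm box is 0.2 nm
  st2 <- dimer_state(c(0.1, 2, 2), c(4.9, 2, 2))
  expect_equal(cog_distance(st2, t1, t1), 0.2, tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:20) {
    ta <- random_template(); tb <- random_template()
    st <- random_state()
    # independent computation from raw rotated coordinates
    rotm <- function(q) {
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
               2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
               2 * (x * z - w * y), 2 * (y * z + w * x),
               1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
    }
    cog <- function(tm, pos, q) {
      X <- as.matrix(tm$atoms[tm$ring, c("x", "y", "z")])
      colMeans(t(rotm(q) %*% t(X)) + matrix(pos, nrow(X), 3, byrow = TRUE))
    }
    d <- cog(tb, st$pos_b, st$quat_b) - cog(ta, st$pos_a, st$quat_a)
    d <- d - st$box * round(d / st$box)
    expect_equal(cog_distance(st, ta, tb), sqrt(sum(d^2)), tolerance = 1e-9)
  }
})

test_that("ring torsion reproduces cis/trans and the independent dihedral", {
  # anchor of the hexagon sits at +x in the body frame; coincident
  # orientations give a cis (0) arrangement along the COG axis
  st_cis <- dimer_state(c(2, 2, 2), c(2, 2, 2.6))
  expect_equal(ring_torsion(st_cis, t1, t1), 0, tolerance = 1e-9)
  # rotate molecule B by pi about the COG-COG axis (z): trans arrangement
  qz <- c(cos(pi / 2), 0, 0, sin(pi / 2))
  st_trans <- dimer_state(c(2, 2, 2), c(2, 2, 2.6), c(1, 0, 0, 0), qz)
  expect_equal(abs(ring_torsion(st_trans, t1, t1)), pi, tolerance = 1e-9)
  set.seed(4)
  for (rep in 1:20) {
    ta <- random_template(); tb <- random_template()
    st <- random_state()
    rotm <- function(q) {
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
               2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
               2 * (x * z - w * y), 2 * (y * z + w * x),
               1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
    }
    world <- function(tm, pos, q, idx) {
      X <- as.matrix(tm$atoms[idx, c("x", "y", "z"), drop = FALSE])
      t(rotm(q) %*% t(X))[1, ] + pos
    }
    ca <- colMeans(t(vapply(ta$ring, function(i)
      world(ta, st$pos_a, st$quat_a, i), numeric(3))))
    cb <- colMeans(t(vapply(tb$ring, function(i)
      world(tb, st$pos_b, st$quat_b, i), numeric(3))))
    shift <- (cb - ca) - st$box * round((cb - ca) / st$box) - (cb - ca)
    expect_equal(ring_torsion(st, ta, tb),
                 dihedral_oracle(world(ta, st$pos_a, st$quat_a, ta$anchor),
                                 ca, cb + shift,
                                 world(tb, st$pos_b, st$quat_b,
                                       tb$anchor) + shift),
                 tolerance = 1e-9)
  }
  # coincident COGs leave the torsion undefined
  st0 <- dimer_state(c(2, 2, 2), c(2, 2, 2))
  expect_error(ring_torsion(st0, t1, t1), "undefined")
})

test_that("normal angle is 0 for stacked, pi/2 for T-shaped, and matches the
           cross-product oracle on planar rings", {
  st_par <- dimer_state(c(2, 2, 2), c(2, 2, 2.4))
  expect_equal(normal_angle(st_par, t1, t1), 0, tolerance = 1e-9)
  qx <- c(cos(pi / 4), sin(pi / 4), 0, 0)  # rotate B by 90 deg about x
  st_perp <- dimer_state(c(2, 2, 2), c(2, 2, 2.5), c(1, 0, 0, 0), qx)
  expect_equal(normal_angle(st_perp, t1, t1), pi / 2, tolerance = 1e-9)
  set.seed(5)
  for (rep in 1:20) {
    st <- random_state()
    rotm <- function(q) {
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
               2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
               2 * (x * z - w * y), 2 * (y * z + w * x),
               1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
    }
    ring_world <- function(tm, pos, q) {
      X <- as.matrix(tm$atoms[tm$ring, c("x", "y", "z")])
      t(rotm(q) %*% t(X)) + matrix(pos, nrow(X), 3, byrow = TRUE)
    }
    n1 <- cross_normal_oracle(ring_world(t1, st$pos_a, st$quat_a))
    n2 <- cross_normal_oracle(ring_world(t1, st$pos_b, st$quat_b))
    expect_equal(normal_angle(st, t1, t1),
                 acos(min(1, abs(sum(n1 * n2)))), tolerance = 1e-9)
  }
})

test_that("CVs are invariant under global transforms, label exchange, and
           normal flips", {
  set.seed(6)
  for (rep in 1:10) {
    ta <- random_template(); tb <- random_template()
    st <- random_state()
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    st2 <- transform_state(st, q, runif(3, -2, 2))
    expect_equal(cog_distance(st2, ta, tb), cog_distance(st, ta, tb),
                 tolerance = 1e-9)
    expect_equal(ring_torsion(st2, ta, tb), ring_torsion(st, ta, tb),
                 tolerance = 1e-9)
    expect_equal(normal_angle(st2, ta, tb), normal_angle(st, ta, tb),
                 tolerance = 1e-9)
    # exchanging the molecule labels flips the torsion sign only
    sw <- dimer_state(st$pos_b, st$pos_a, st$quat_b, st$quat_a, st$box)
    expect_equal(cog_distance(sw, tb, ta), cog_distance(st, ta, tb),
                 tolerance = 1e-9)
    tor <- ring_torsion(st, ta, tb)
    tor_sw <- ring_torsion(sw, tb, ta)
    expect_equal(abs(tor_sw), abs(tor), tolerance = 1e-9)
    expect_equal(normal_angle(sw, tb, ta), normal_angle(st, ta, tb),
                 tolerance = 1e-9)
    # fold invariance is built in: the angle never exceeds pi/2
    expect_lte(normal_angle(st, ta, tb), pi / 2 + 1e-12)
  }
})

test_that("COLVAR files round-trip with header-declared CV names", {
  fr <- data.frame(time = 1:5, dist = runif(5, 0.3, 2),
                   torsion = runif(5, -pi, pi), nangle = runif(5, 0, pi / 2),
                   bias = runif(5, 0, 3))
  traj <- cv_traj(fr, c("dist", "torsion", "nangle"), temperature = 300,
                  bias_factor = 5)
  path <- withr::local_tempfile(fileext = ".colvar")
  write_colvar(traj, path)
  back <- read_colvar(path)
  expect_equal(back$cv_names, c("dist", "torsion", "nangle"))
  expect_equal(back$frames, traj$frames, tolerance = 1e-9)
  expect_equal(back$temperature, 300)
  expect_equal(back$bias_factor, 5)
  writeLines(c("1 2 3"), path)
  expect_error(read_colvar(path), "FIELDS")
})

test_that("cv_traj enforces monotone time and finite bias", {
  fr <- data.frame(time = c(1, 1), s = c(0, 1), bias = 0)
  expect_error(cv_traj(fr, "s"), "increasing")
  fr2 <- data.frame(time = 1:2, s = c(0, 1), bias = c(0, Inf))
  expect_error(cv_traj(fr2, "s"), "finite")
})
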