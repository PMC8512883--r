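# Independent oracles and fixture builders for the test suite. These are
# deliberately naive re-implementations sharing no kernels with the package.

R_KJ <- 8.3145e-3  # kJ mol^-1 K^-1

# naive double-loop dimer energy: scalar LJ + shifted reaction-field Coulomb
naive_dimer_energy <- function(state, tmpl_a, tmpl_b, cfg) {
  rot <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  Ra <- rot(state$quat_a); Rb <- rot(state$quat_b)
  box <- state$box
  rc <- cfg$cutoff
  krf <- (cfg$epsilon_rf - 1) / ((2 * cfg$epsilon_rf + 1) * rc^3)
  crf <- 1 / rc + krf * rc^2
  e <- 0
  for (i in seq_len(nrow(tmpl_a$atoms))) {
    ai <- tmpl_a$atoms[i, ]
    pi_ <- as.numeric(Ra %*% c(ai$x, ai$y, ai$z)) + state$pos_a
    for (j in seq_len(nrow(tmpl_b$atoms))) {
      bj <- tmpl_b$atoms[j, ]
      pj <- as.numeric(Rb %*% c(bj$x, bj$y, bj$z)) + state$pos_b
      d <- pi_ - pj
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r > rc) next
      sig <- if (cfg$combination_rule == "geometric")
        sqrt(ai$sigma * bj$sigma) else (ai$sigma + bj$sigma) / 2
      eps <- sqrt(ai$epsilon * bj$epsilon)
      e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      e <- e + cfg$coulomb_constant * ai$charge * bj$charge *
        (1 / r + krf * r^2 - crf)
    }
  }
  e
}

# textbook dihedral via projection onto the plane normal to the central bond
# (acos magnitude + triple-product sign); independent of the atan2 route
dihedral_oracle <- function(p1, p2, p3, p4) {
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(max(-1, min(1, sum(n1 * n2))))
  # IUPAC sign: positive when n1 x n2 points against the central bond
  if (sum(xp(n1, n2) * b2) > 0) ang <- -ang
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

# cross-product plane normal from the first three ring atoms (exact for
# perfectly planar rings)
cross_normal_oracle <- function(coords) {
  v1 <- coords[2, ] - coords[1, ]
  v2 <- coords[3, ] - coords[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  n / sqrt(sum(n^2))
}

# random valid molecule template: planar ring of m atoms (ring COG at the
# origin) plus optional off-plane extra atoms
random_template <- function(m_ring = sample(3:8, 1), extra = sample(0:2, 1)) {
  ang <- sort(stats::runif(m_ring, 0, 2 * pi))
  rad <- stats::runif(m_ring, 0.08, 0.25)
  pts <- cbind(rad * cos(ang), rad * sin(ang), 0)
  pts <- sweep(pts, 2, colMeans(pts))
  if (extra > 0) {
    pts <- rbind(pts, matrix(stats::runif(3 * extra, -0.3, 0.3),
                             ncol = 3))
  }
  n <- nrow(pts)
  atoms <- data.frame(
    name = paste0("A", seq_len(n)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    sigma = stats::runif(n, 0.2, 0.5),
    epsilon = stats::runif(n, 0, 1),
    charge = round(stats::runif(n, -0.3, 0.3), 4),
    stringsAsFactors = FALSE)
  molecule_template(atoms, ring = seq_len(m_ring),
                    anchor = sample(seq_len(n), 1),
                    name = paste0("rnd", m_ring))
}

# random dimer pose with COG separation roughly in [0.3, 2.2] nm
random_state <- function(box = 5) {
  pa <- stats::runif(3, 1, box - 1)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  pb <- pa + dir * stats::runif(1, 0.3, 2.2)
  qa <- stats::rnorm(4); qa <- qa / sqrt(sum(qa^2))
  qb <- stats::rnorm(4); qb <- qb / sqrt(sum(qb^2))
  dimer_state(pa, pb %% box, qa, qb, box = box)
}

# apply a global rigid rotation + translation to a dimer state
transform_state <- function(state, quat, shift) {
  qmul <- function(a, b)
    c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
      a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
      a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
      a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  rot <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  R <- rot(quat)
  dimer_state(as.numeric(R %*% state$pos_a) + shift,
              as.numeric(R %*% state$pos_b) + shift,
              qmul(quat, state$quat_a), qmul(quat, state$quat_b),
              box = 1e6)  # huge box: transformed poses must stay equivalent
}

# double-well metadynamics run used by several tests (memoised per seed)
.dw_cache <- new.env(parent = emptyenv())
dw_run <- function(seed, n_steps = 6e5) {
  key <- paste0("s", seed, "_", n_steps)
  if (!is.null(.dw_cache[[key]])) return(.dw_cache[[key]])
  pot <- make_double_well(10)
  g <- bias_grid(list(grid_axis("s", -1.75, 1.75, n = 141)),
                 sigmas = 0.1, stride = 500L)
  traj <- langevin_cv_sample(pot, n_steps = n_steps, seed = seed, x0 = -1,
                             metad = g)
  .dw_cache[[key]] <- traj
  traj
}
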