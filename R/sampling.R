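# Desk-scale biased samplers standing in for explicit-solvent MD:
# rigid-body Metropolis Monte Carlo for molecular dimers, a 1-D Metropolis
# chain in CV space, and an overdamped Langevin integrator on analytic
# CV-space potentials. All are fully seeded and bit-reproducible.

#' Rigid-body Metropolis Monte Carlo for a dimer, optionally with
#' well-tempered metadynamics
#'
#' Samples the Boltzmann distribution of
#' \eqn{U = E_{dimer} + E_{wall}(r) + V_{bias}(dist, torsion)} at the
#' configured temperature. Moves cycle through translation/rotation of each
#' molecule in turn; move sizes are auto-tuned during a discarded burn-in to
#' a 30-50\% acceptance window and then frozen (continued tuning would break
#' detailed balance). When \code{metad} is given, hills are deposited on the
#' (dist, torsion) grid every \code{metad$stride} steps and the bias is held
#' fixed between depositions.
#'
#' The initial state stacks the molecules 1 nm apart along z with random
#' orientations drawn from the seed.
#'
#' @param tmpl_a,tmpl_b \code{molecule_template}s.
#' @param n_steps number of MC moves.
#' @param seed RNG seed (mandatory: no silent default entropy).
#' @param nonbonded a \code{\link{nonbonded_config}}.
#' @param wall a \code{\link{wall_config}}.
#' @param metad a \code{\link{bias_grid}} to run well-tempered metadynamics
#'   on (dist, torsion), or \code{NULL} for unbiased sampling.
#' @param bias a static \code{bias_grid} evaluated but never updated
#'   (frozen-bias runs; ignored when \code{metad} is given).
#' @param box cubic box edge, nm.
#' @param record_stride record CVs every this many moves; must divide the
#'   deposition stride.
#' @param max_trans,max_rot initial maximum move sizes (nm, rad).
#' @param tune_steps burn-in length for move-size tuning (0 disables).
#' @return a \code{\link{cv_traj}} with columns dist, torsion, nangle and
#'   bias; for metadynamics runs \code{$hills} and \code{$grid} hold the
#'   deposited hills and final bias. \code{$log} carries acceptance
#'   statistics.
#' @export
mc_sample <- function(tmpl_a, tmpl_b, n_steps, seed,
                      nonbonded = nonbonded_config(), wall = wall_config(),
                      metad = NULL, bias = NULL, box = 5,
                      record_stride = 1L, max_trans = 0.15, max_rot = 0.3,
                      tune_steps = 5000L) {
  stopifnot(n_steps > 0, !missing(seed))
  record_stride <- as.integer(record_stride)
  if (!is.null(metad)) {
    stopifnot(inherits(metad, "bias_grid"), length(metad$axes) == 2)
    if (metad$stride %% record_stride != 0)
      stop("record_stride must divide the deposition stride")
  }
  kt <- .kt(nonbonded$temperature)
  tables <- .pair_tables(tmpl_a, tmpl_b, nonbonded)
  xa_body <- template_coords(tmpl_a)
  xb_body <- template_coords(tmpl_b)
  anchor_a <- xa_body[tmpl_a$anchor, ]
  anchor_b <- xb_body[tmpl_b$anchor, ]
  # rigid-body plane normals: rotate the body-frame best-fit normal
  na_body <- plane_normal(xa_body[tmpl_a$ring, , drop = FALSE])
  nb_body <- plane_normal(xb_body[tmpl_b$ring, , drop = FALSE])

  # hoisted constants for the hot loop
  SIG <- tables$SIG; EPS4 <- 4 * tables$EPS; QQ <- tables$QQ
  has_nb <- tables$has_lj || tables$has_q
  has_lj <- tables$has_lj; has_q <- tables$has_q
  rfc <- .rf_constants(nonbonded)
  krf <- rfc$krf; crf <- rfc$crf; cutoff <- nonbonded$cutoff
  wall_r0 <- wall$r0; wall_k <- wall$k

  with_seed(seed, {
    pos_a <- rep(box / 2, 3)
    pos_b <- pos_a + c(0, 0, 1.0)
    qa <- random_quat(); qb <- random_quat()
    Ra <- quat_to_mat(qa); Rb <- quat_to_mat(qb)
    Xa <- sweep(xa_body %*% t(Ra), 2, pos_a, "+")
    Xb <- sweep(xb_body %*% t(Rb), 2, pos_b, "+")

    grid <- if (!is.null(metad)) metad else bias
    biased <- !is.null(grid)
    bias_2d <- biased && length(grid$axes) == 2
    need_tor <- bias_2d
    if (biased) {
      ax1 <- grid$axes[[1]]
      g1min <- ax1$min; g1dx <- ax1$spacing; g1n <- ax1$n
      if (bias_2d) {
        ax2 <- grid$axes[[2]]
        g2min <- ax2$min; g2dx <- ax2$spacing; g2n <- ax2$n
        g2per <- ax2$periodic
      }
      gv <- grid$values
    }
    # scalar (bi)linear interpolation on the cached bias values; same
    # arithmetic as bias_at, inlined for the per-move hot path
    bias_fast <- function(dist, tor) {
      u <- (dist - g1min) / g1dx
      if (u < 0) u <- 0 else if (u > g1n - 1) u <- g1n - 1
      i0 <- floor(u); if (i0 > g1n - 2) i0 <- g1n - 2
      f1 <- u - i0
      if (!bias_2d)
        return((1 - f1) * gv[i0 + 1] + f1 * gv[i0 + 2])
      u2 <- (tor - g2min) / g2dx
      if (g2per) {
        u2 <- u2 %% g2n
        j0 <- floor(u2); f2 <- u2 - j0
        j0 <- j0 %% g2n; j1 <- (j0 + 1) %% g2n
      } else {
        if (u2 < 0) u2 <- 0 else if (u2 > g2n - 1) u2 <- g2n - 1
        j0 <- floor(u2); if (j0 > g2n - 2) j0 <- g2n - 2
        f2 <- u2 - j0; j1 <- j0 + 1
      }
      (1 - f1) * ((1 - f2) * gv[i0 + 1, j0 + 1] + f2 * gv[i0 + 1, j1 + 1]) +
        f1 * ((1 - f2) * gv[i0 + 2, j0 + 1] + f2 * gv[i0 + 2, j1 + 1])
    }

    torsion_of <- function(pos_a, Ra, pos_b, Rb, dvec) {
      ca <- pos_a; cb <- pos_a + dvec
      pa <- ca + as.numeric(Ra %*% anchor_a)
      pb <- cb + as.numeric(Rb %*% anchor_b)
      dihedral_angle(pa, ca, cb, pb)
    }

    energy_of <- function(Xa, Xb, dist, tor) {
      e <- 0
      if (has_nb) {
        dxm <- outer(Xa[, 1], Xb[, 1], "-")
        dym <- outer(Xa[, 2], Xb[, 2], "-")
        dzm <- outer(Xa[, 3], Xb[, 3], "-")
        dxm <- dxm - box * round(dxm / box)
        dym <- dym - box * round(dym / box)
        dzm <- dzm - box * round(dzm / box)
        r2 <- dxm * dxm + dym * dym + dzm * dzm
        if (any(r2 < 1e-12)) return(Inf)
        r <- sqrt(r2)
        inr <- r <= cutoff
        if (has_lj) {
          sr6 <- (SIG[inr] / r[inr])^6
          e <- e + sum(EPS4[inr] * (sr6 * sr6 - sr6))
        }
        if (has_q)
          e <- e + sum(QQ[inr] * (1 / r[inr] + krf * r[inr]^2 - crf))
      }
      if (dist > wall_r0) e <- e + 0.5 * wall_k * (dist - wall_r0)^2
      if (biased) e <- e + bias_fast(dist, tor)
      e
    }

    dvec <- min_image(pos_b - pos_a, box)
    dist <- sqrt(sum(dvec * dvec))
    tor <- if (need_tor) torsion_of(pos_a, Ra, pos_b, Rb, dvec) else NA_real_
    cv <- c(dist, tor)
    e_cur <- energy_of(Xa, Xb, cv[1], cv[2])
    if (!is.finite(e_cur)) stop("initial state has non-finite energy")

    n_rec <- n_steps %/% record_stride
    rec <- matrix(NA_real_, nrow = n_rec, ncol = 5)
    colnames(rec) <- c("time", "dist", "torsion", "nangle", "bias")
    irec <- 0L

    acc <- 0L; tried <- 0L
    acc_window <- 0L; tried_window <- 0L
    warned_zero <- FALSE
    tuning <- tune_steps > 0
    total <- n_steps + (if (tuning) as.integer(tune_steps) else 0L)
    step0 <- if (tuning) -as.integer(tune_steps) else 0L

    for (raw in seq_len(total)) {
      step <- step0 + raw - 1L + 1L  # steps run 1..n_steps after burn-in
      move <- (raw - 1L) %% 4L       # transA, rotA, transB, rotB
      nqa <- qa; nqb <- qb; nRa <- Ra; nRb <- Rb
      npos_a <- pos_a; npos_b <- pos_b
      if (move == 0L || move == 2L) {
        dpos <- stats::runif(3, -max_trans, max_trans)
        if (move == 0L) {
          npos_a <- (pos_a + dpos) %% box
          sh <- npos_a - pos_a
          nXa <- Xa; nXa[, 1] <- nXa[, 1] + sh[1]
          nXa[, 2] <- nXa[, 2] + sh[2]; nXa[, 3] <- nXa[, 3] + sh[3]
          nXb <- Xb
        } else {
          npos_b <- (pos_b + dpos) %% box
          sh <- npos_b - pos_b
          nXb <- Xb; nXb[, 1] <- nXb[, 1] + sh[1]
          nXb[, 2] <- nXb[, 2] + sh[2]; nXb[, 3] <- nXb[, 3] + sh[3]
          nXa <- Xa
        }
      } else {
        dq <- random_rotation_quat(max_rot)
        if (move == 1L) {
          nqa <- quat_normalize(quat_multiply(dq, qa))
          nRa <- quat_to_mat(nqa)
          nXa <- xa_body %*% t(nRa)
          nXa[, 1] <- nXa[, 1] + pos_a[1]; nXa[, 2] <- nXa[, 2] + pos_a[2]
          nXa[, 3] <- nXa[, 3] + pos_a[3]
          nXb <- Xb
        } else {
          nqb <- quat_normalize(quat_multiply(dq, qb))
          nRb <- quat_to_mat(nqb)
          nXb <- xb_body %*% t(nRb)
          nXb[, 1] <- nXb[, 1] + pos_b[1]; nXb[, 2] <- nXb[, 2] + pos_b[2]
          nXb[, 3] <- nXb[, 3] + pos_b[3]
          nXa <- Xa
        }
      }
      ndvec <- npos_b - npos_a
      ndvec <- ndvec - box * round(ndvec / box)
      ndist <- sqrt(sum(ndvec * ndvec))
      ntor <- if (need_tor) torsion_of(npos_a, nRa, npos_b, nRb, ndvec)
              else NA_real_
      e_new <- energy_of(nXa, nXb, ndist, ntor)
      tried <- tried + 1L; tried_window <- tried_window + 1L
      if (is.finite(e_new) &&
          (e_new <= e_cur || stats::runif(1) < exp(-(e_new - e_cur) / kt))) {
        pos_a <- npos_a; pos_b <- npos_b; qa <- nqa; qb <- nqb
        Ra <- nRa; Rb <- nRb; Xa <- nXa; Xb <- nXb
        cv <- c(ndist, ntor); e_cur <- e_new
        acc <- acc + 1L; acc_window <- acc_window + 1L
      }
      if (tuning && raw <= tune_steps) {
        if (raw %% 200L == 0L) {
          rate <- acc_window / tried_window
          f <- if (rate > 0.5) 1.15 else if (rate < 0.3) 0.85 else 1
          max_trans <- min(max_trans * f, box / 4)
          max_rot <- min(max_rot * f, pi)
          acc_window <- 0L; tried_window <- 0L
        }
        if (raw == tune_steps) { acc <- 0L; tried <- 0L
                                 acc_window <- 0L; tried_window <- 0L }
        next
      }
      if (tried_window >= 1000L) {
        if (acc_window == 0L && !warned_zero) {
          warning("zero acceptance over ", tried_window, " moves; ",
                  "move sizes may be too large")
          warned_zero <- TRUE
        }
        acc_window <- 0L; tried_window <- 0L
      }
      if (!is.null(metad) && step %% grid$stride == 0L) {
        grid <- deposit_hill(grid, cv, time = step)$grid
        gv <- grid$values
        # bias changed under the current state: refresh cached energy
        e_cur <- energy_of(Xa, Xb, cv[1], cv[2])
      }
      if (step %% record_stride == 0L) {
        irec <- irec + 1L
        tor <- if (need_tor) cv[2]
               else torsion_of(pos_a, Ra, pos_b, Rb,
                               min_image(pos_b - pos_a, box))
        nang <- acos(min(1, abs(sum((Ra %*% na_body) * (Rb %*% nb_body)))))
        vb <- if (biased) bias_fast(cv[1], cv[2]) else 0
        rec[irec, ] <- c(step, cv[1], tor, nang, vb)
      }
    }
    frames <- as.data.frame(rec[seq_len(irec), , drop = FALSE])
    traj <- cv_traj(frames, c("dist", "torsion", "nangle"),
                    temperature = nonbonded$temperature,
                    bias_factor = if (!is.null(metad)) grid$bias_factor
                                  else NA,
                    seed = seed,
                    hills = if (!is.null(metad)) grid$hills else NULL,
                    grid = if (!is.null(metad)) {
                      g <- grid; g$values[] <- 0; g$hills <- .empty_hills(g$axes)
                      g
                    } else NULL)
    traj$final_grid <- if (!is.null(metad)) grid else NULL
    traj$log <- list(acceptance = acc / max(tried, 1L),
                     max_trans = max_trans, max_rot = max_rot)
    traj
  })
}

#' Metropolis Monte Carlo on a 1-D CV-space potential
#'
#' Validation channel: samples \eqn{p(s) \propto e^{-U(s)/k_B T}} on an
#' interval with symmetric uniform proposals (rejected outside the bounds).
#'
#' @param potential a list with \code{U = function(s)} (kJ/mol), e.g. from
#'   \code{\link{make_double_well}}; or a plain function.
#' @param n_steps chain length.
#' @param seed RNG seed.
#' @param x0 initial point.
#' @param bounds length-2 interval.
#' @param step_size maximum proposal displacement.
#' @param temperature K.
#' @param record_stride record every this many steps.
#' @return a \code{cv_traj} with CV column \code{s} (bias is zero).
#' @export
mc_sample_cv <- function(potential, n_steps, seed, x0 = 0,
                         bounds = c(-2, 2), step_size = 0.2,
                         temperature = 300, record_stride = 1L) {
  U <- if (is.function(potential)) potential else potential$U
  kt <- .kt(temperature)
  with_seed(seed, {
    x <- x0
    u <- U(x)
    n_rec <- n_steps %/% record_stride
    s_rec <- numeric(n_rec); t_rec <- numeric(n_rec)
    irec <- 0L
    for (step in seq_len(n_steps)) {
      xn <- x + stats::runif(1, -step_size, step_size)
      if (xn >= bounds[1] && xn <= bounds[2]) {
        un <- U(xn)
        if (un <= u || stats::runif(1) < exp(-(un - u) / kt)) {
          x <- xn; u <- un
        }
      }
      if (step %% record_stride == 0L) {
        irec <- irec + 1L
        s_rec[irec] <- x; t_rec[irec] <- step
      }
    }
    cv_traj(data.frame(time = t_rec, s = s_rec, bias = 0), "s",
            temperature = temperature, seed = seed)
  })
}

#' Overdamped Langevin dynamics on a CV-space potential, optionally with
#' well-tempered metadynamics
#'
#' Euler-Maruyama integration of
#' \eqn{dx = -\mu \nabla(U + V_{bias}) dt + \sqrt{2 k_B T \mu \, dt}\,\xi}
#' with mobility \eqn{\mu = 1/\gamma_f} (friction \eqn{\gamma_f}), whose
#' stationary density is \eqn{\propto e^{-\beta U}}. Bounds are reflective.
#' Works in any CV dimension matching \code{x0}; the bias force is the cell
#' slope of the (multi)linear bias interpolant.
#'
#' @param potential list with \code{U} and optionally \code{grad} (numerical
#'   gradient is used when absent), e.g. from \code{\link{make_double_well}}.
#' @param n_steps integration steps.
#' @param seed RNG seed.
#' @param x0 initial CV value(s).
#' @param bounds 2-vector (1-D) or 2-row matrix (one column per CV) of
#'   reflective bounds; defaults to \code{potential$bounds}.
#' @param dt time step (CV units).
#' @param friction inverse-time friction coefficient.
#' @param temperature K.
#' @param metad a \code{bias_grid} over the same CVs for well-tempered
#'   deposition every \code{metad$stride} steps, or \code{NULL}.
#' @param bias static \code{bias_grid}, evaluated but never updated.
#' @param record_stride record every this many steps.
#' @param cv_names names for the CV columns (default from the bias axes, or
#'   \code{"s"}).
#' @return a \code{cv_traj}; metadynamics runs carry \code{$hills},
#'   \code{$grid} (empty template) and \code{$final_grid}.
#' @export
langevin_cv_sample <- function(potential, n_steps, seed, x0 = 0,
                               bounds = NULL, dt = 5e-4, friction = 1,
                               temperature = 300, metad = NULL, bias = NULL,
                               record_stride = 1L, cv_names = NULL) {
  U <- potential$U
  gradf <- potential$grad
  d <- length(x0)
  if (is.null(bounds)) bounds <- potential$bounds
  if (is.null(bounds)) stop("bounds required")
  bounds <- if (is.null(dim(bounds))) matrix(bounds, nrow = 2) else bounds
  stopifnot(ncol(bounds) == d)
  if (is.null(gradf)) {
    h <- 1e-6
    gradf <- function(x) vapply(seq_len(d), function(k) {
      e <- numeric(d); e[k] <- h
      (U(x + e) - U(x - e)) / (2 * h)
    }, 0)
  }
  grid <- if (!is.null(metad)) metad else bias
  biased <- !is.null(grid)
  if (biased) stopifnot(length(grid$axes) == d)
  if (is.null(cv_names))
    cv_names <- if (biased) vapply(grid$axes, function(a) a$name, "")
                else if (d == 1) "s" else paste0("cv", seq_len(d))
  kt <- .kt(temperature)
  eta <- dt / friction
  noise_sd <- sqrt(2 * kt * eta)
  record_stride <- as.integer(record_stride)
  if (!is.null(metad) && metad$stride %% record_stride != 0)
    stop("record_stride must divide the deposition stride")

  # bias force: finite difference with half-cell spacing (the interpolant is
  # piecewise linear, so this reads the local slope)
  bias_force <- function(x) {
    vapply(seq_len(d), function(k) {
      hh <- grid$axes[[k]]$spacing / 2
      lo <- x; hi <- x
      lo[k] <- max(x[k] - hh, grid$axes[[k]]$min)
      hi[k] <- min(x[k] + hh, if (grid$axes[[k]]$periodic) Inf
                   else grid$axes[[k]]$max)
      -(bias_at(grid, hi) - bias_at(grid, lo)) / (hi[k] - lo[k])
    }, 0)
  }

  with_seed(seed, {
    x <- as.numeric(x0)
    n_rec <- n_steps %/% record_stride
    rec <- matrix(NA_real_, nrow = n_rec, ncol = 2 + d)
    irec <- 0L
    if (d == 1) {
      # specialized scalar loop: the bias interpolation and its cell slope
      # are inlined (identical arithmetic to bias_at on a 1-D grid)
      lo <- bounds[1, 1]; hi <- bounds[2, 1]
      if (biased) {
        axn <- grid$axes[[1]]
        gmin <- axn$min; gdx <- axn$spacing; gn <- axn$n
        v <- as.numeric(grid$values)
      }
      deposit_every <- if (!is.null(metad)) grid$stride else 0L
      x1 <- x[1]
      noise <- noise_sd * stats::rnorm(n_steps)
      for (step in seq_len(n_steps)) {
        f <- -gradf(x1)
        vb <- 0
        if (biased) {
          u <- (x1 - gmin) / gdx
          if (u < 0) u <- 0 else if (u > gn - 1) u <- gn - 1
          i0 <- floor(u); if (i0 > gn - 2) i0 <- gn - 2
          slope <- (v[i0 + 2] - v[i0 + 1]) / gdx
          vb <- v[i0 + 1] + (u - i0) * gdx * slope
          f <- f - slope
        }
        x1 <- x1 + eta * f + noise[step]
        if (x1 < lo) x1 <- 2 * lo - x1
        if (x1 > hi) x1 <- 2 * hi - x1
        if (x1 < lo || x1 > hi || !is.finite(x1))
          stop("Langevin integration diverged; use a smaller dt")
        if (deposit_every && step %% deposit_every == 0L) {
          grid <- deposit_hill(grid, x1, time = step)$grid
          v <- as.numeric(grid$values)
        }
        if (step %% record_stride == 0L) {
          irec <- irec + 1L
          if (biased) {
            u <- (x1 - gmin) / gdx
            if (u < 0) u <- 0 else if (u > gn - 1) u <- gn - 1
            i0 <- floor(u); if (i0 > gn - 2) i0 <- gn - 2
            vb <- v[i0 + 1] + (u - i0) * (v[i0 + 2] - v[i0 + 1])
          } else vb <- 0
          rec[irec, ] <- c(step, x1, vb)
        }
      }
      x <- x1
    } else {
    for (step in seq_len(n_steps)) {
      f <- -gradf(x)
      if (biased) f <- f + bias_force(x)
      x <- x + eta * f + noise_sd * stats::rnorm(d)
      # reflective bounds
      for (k in seq_len(d)) {
        if (x[k] < bounds[1, k]) x[k] <- 2 * bounds[1, k] - x[k]
        if (x[k] > bounds[2, k]) x[k] <- 2 * bounds[2, k] - x[k]
        # a huge kick can overshoot both reflections
        if (x[k] < bounds[1, k] || x[k] > bounds[2, k] || !is.finite(x[k]))
          stop("Langevin integration diverged (|s| outside bounds after ",
               "reflection); use a smaller dt")
      }
      if (abs(max(abs(x))) > 1e8)
        stop("Langevin integration diverged; use a smaller dt")
      if (!is.null(metad) && step %% grid$stride == 0L) {
        grid <- deposit_hill(grid, x, time = step)$grid
      }
      if (step %% record_stride == 0L) {
        irec <- irec + 1L
        rec[irec, ] <- c(step, x, if (biased) bias_at(grid, x) else 0)
      }
    }
    }
    frames <- as.data.frame(rec[seq_len(irec), , drop = FALSE])
    names(frames) <- c("time", cv_names, "bias")
    traj <- cv_traj(frames, cv_names, temperature = temperature,
                    bias_factor = if (!is.null(metad)) grid$bias_factor
                                  else NA,
                    seed = seed,
                    hills = if (!is.null(metad)) grid$hills else NULL,
                    grid = if (!is.null(metad)) {
                      g <- grid; g$values[] <- 0
                      g$hills <- .empty_hills(g$axes)
                      g
                    } else NULL)
    traj$final_grid <- if (!is.null(metad)) grid else NULL
    traj
  })
}
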