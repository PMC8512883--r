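# Synthetic fixtures and independent oracles: analytic CV-space potentials
# with quadrature free energies, non-interacting (ideal-gas) dimers, AR(1)
# series, and constructed FES grids with known minima. The evaluators here
# deliberately use naive quadrature/closed forms independent of the main
# numerical kernels, so they can serve as genuine cross-checks.

#' Analytic double-well potential
#'
#' \eqn{U(s) = h (s^2 - 1)^2}: minima at s = +/-1 (degenerate, so the true
#' free-energy difference between them is exactly 0) and a barrier of height
#' h at s = 0.
#'
#' @param h barrier height, kJ/mol (default 10).
#' @param bounds sampling interval (default [-1.7, 1.7]).
#' @return an analytic potential: list with \code{U}, \code{grad},
#'   \code{bounds}, and \code{fes(s, temperature)} returning
#'   \eqn{-k_B T \ln p(s)} for the quadrature-normalized Boltzmann density.
#' @export
make_double_well <- function(h = 10, bounds = c(-1.7, 1.7)) {
  U <- function(s) h * (s^2 - 1)^2
  obj <- list(
    name = "double_well", h = h,
    U = U,
    grad = function(s) 4 * h * s * (s^2 - 1),
    bounds = bounds,
    fes = function(s, temperature = 300)
      .quadrature_fes(U, s, bounds, temperature))
  class(obj) <- "analytic_potential"
  obj
}

#' Analytic harmonic potential \eqn{U(s) = k s^2 / 2}
#'
#' The Boltzmann variance is \eqn{k_B T / k} (0.02494 nm^2 for
#' k = 100 kJ mol^-1 nm^-2 at 300 K).
#'
#' @param k force constant, kJ mol^-1 (CV unit)^-2.
#' @param bounds sampling interval.
#' @export
make_harmonic <- function(k = 100, bounds = c(-1, 1)) {
  U <- function(s) 0.5 * k * s^2
  obj <- list(name = "harmonic", k = k, U = U,
              grad = function(s) k * s, bounds = bounds,
              fes = function(s, temperature = 300)
                .quadrature_fes(U, s, bounds, temperature))
  class(obj) <- "analytic_potential"
  obj
}

#' Flat potential (U = 0) on an interval
#' @param bounds sampling interval.
#' @export
make_flat <- function(bounds = c(0, 1)) {
  U <- function(s) 0 * s
  obj <- list(name = "flat", U = U, grad = function(s) 0 * s,
              bounds = bounds,
              fes = function(s, temperature = 300)
                .quadrature_fes(U, s, bounds, temperature))
  class(obj) <- "analytic_potential"
  obj
}

# -kT ln of the quadrature-normalized Boltzmann density (naive oracle)
.quadrature_fes <- function(U, s, bounds, temperature) {
  kt <- R_GAS * temperature
  z <- stats::integrate(function(x) exp(-U(x) / kt), bounds[1], bounds[2],
                        rel.tol = 1e-10, subdivisions = 500L)$value
  U(s) + kt * log(z)
}

#' Non-interacting (ideal-gas) dimer system
#'
#' Two rigid ring templates with all epsilon = 0 and charge = 0: the
#' intermolecular energy is identically zero and only the distance wall
#' acts, so the exact radial distribution is proportional to \eqn{r^2}
#' (times the wall's Boltzmann factor) and the entropic-corrected,
#' zero-shifted radial FES is flat. This is the ground-truth fixture for the
#' Jacobian correction.
#'
#' @param n_fused_rings ring count per molecule (default 1).
#' @param bond_length nm.
#' @return list with \code{tmpl_a}, \code{tmpl_b}.
#' @export
make_ideal_gas_dimer <- function(n_fused_rings = 1, bond_length = 0.14) {
  style <- list(sigma = 0.355, epsilon = 0, charge = 0)
  t1 <- make_ring_template(n_fused_rings, bond_length, param_style = style)
  t1$name <- paste0(t1$name, "_ideal")
  list(tmpl_a = t1, tmpl_b = t1)
}

#' Stationary AR(1) time series
#'
#' \eqn{x_t = \phi x_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0, sd^2)},
#' initialized from the stationary distribution
#' \eqn{N(0, sd^2/(1-\phi^2))}. phi = 0 gives white noise; the correlation
#' time is about \eqn{1/(1-\phi)} samples.
#'
#' @param phi autoregression coefficient in [0, 1).
#' @param n length.
#' @param seed RNG seed.
#' @param sd innovation standard deviation.
#' @return numeric vector.
#' @export
make_ar1_series <- function(phi, n, seed, sd = 1) {
  stopifnot(phi >= 0, phi < 1, n >= 1)
  with_seed(seed, {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
    if (n > 1) {
      eps <- stats::rnorm(n - 1, 0, sd)
      for (t in 2:n) x[t] <- phi * x[t - 1] + eps[t - 1]
    }
    x
  })
}

#' Constructed FES grid with Gaussian dips
#'
#' Builds a dist x angle \code{fes_grid} that is zero everywhere except for
#' the requested Gaussian wells — a ground-truth fixture for binding-mode
#' extraction and profile comparison. The grid is marked corrected and
#' shifted (it is constructed in its final gauge).
#'
#' @param dips list of dips, each \code{list(center = c(dist, angle_rad),
#'   width = c(sd_dist, sd_angle), depth = <negative kJ/mol>)}.
#' @param dist_axis,angle_axis \code{\link{grid_axis}} definitions.
#' @param stderr optional constant per-node standard error.
#' @return a \code{fes_grid}
#' @export
make_dip_fes <- function(dips,
                         dist_axis = grid_axis("dist", 0.25, 2.2,
                                               spacing = 0.025),
                         angle_axis = grid_axis("nangle", 0, pi / 2,
                                                n = 37L),
                         stderr = NULL) {
  v <- matrix(0, nrow = dist_axis$n, ncol = angle_axis$n)
  for (dp in dips) {
    gd <- exp(-(dist_axis$nodes - dp$center[1])^2 / (2 * dp$width[1]^2))
    ga <- exp(-(angle_axis$nodes - dp$center[2])^2 / (2 * dp$width[2]^2))
    v <- v + dp$depth * (gd %o% ga)
  }
  se <- if (!is.null(stderr)) array(stderr, dim = dim(v)) else NULL
  fes_grid(list(dist_axis, angle_axis), v, stderr = se,
           entropic_corrected = TRUE, zero_shifted = TRUE)
}
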