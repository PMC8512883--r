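# Nonbonded energetics of a rigid dimer: truncated Lennard-Jones plus
# Coulomb with a constant-shifted reaction field, and the harmonic upper
# wall restraining the COG distance.

#' Nonbonded interaction settings
#'
#' Defaults follow the common "general setup" for small-molecule simulations:
#' 1.4 nm cutoff for both LJ and electrostatics, reaction-field electrostatics
#' with a water-like effective dielectric of 54, 300 K.
#'
#' @param cutoff LJ and Coulomb cutoff, nm.
#' @param epsilon_rf reaction-field dielectric (> 1).
#' @param coulomb_constant f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
#' @param combination_rule \code{"lorentz_berthelot"} (arithmetic sigma,
#'   geometric epsilon) or \code{"geometric"} (OPLS-style, geometric both).
#' @param temperature K.
#' @return object of class \code{nonbonded_config}
#' @export
nonbonded_config <- function(cutoff = 1.4, epsilon_rf = 54,
                             coulomb_constant = 138.935458,
                             combination_rule = c("lorentz_berthelot",
                                                  "geometric"),
                             temperature = 300) {
  combination_rule <- match.arg(combination_rule)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (epsilon_rf <= 1) stop("epsilon_rf must be > 1")
  obj <- list(cutoff = cutoff, epsilon_rf = epsilon_rf,
              coulomb_constant = coulomb_constant,
              combination_rule = combination_rule,
              temperature = temperature)
  class(obj) <- "nonbonded_config"
  obj
}

#' Harmonic upper-wall settings
#'
#' One-sided harmonic restraint on the COG distance keeping the dimer within
#' the sampled range: zero below the onset, 0.5 k (r - r0)^2 beyond it.
#'
#' @param r0 onset distance, nm (default 2).
#' @param k force constant, kJ mol^-1 nm^-2 (default 200).
#' @export
wall_config <- function(r0 = 2, k = 200) {
  if (r0 <= 0) stop("r0 must be > 0")
  if (k < 0) stop("k must be >= 0")
  obj <- list(r0 = r0, k = k)
  class(obj) <- "wall_config"
  obj
}

#' Lennard-Jones pair energy (plain truncation)
#'
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} for \eqn{r \le cutoff},
#' zero beyond. Vectorized over \code{r}.
#'
#' @param r distance(s), nm; must be > 0.
#' @param sigma_ij combined LJ diameter, nm.
#' @param epsilon_ij combined LJ well depth, kJ/mol.
#' @param cutoff truncation distance, nm.
#' @return energy, kJ/mol
#' @export
lj_pair <- function(r, sigma_ij, epsilon_ij, cutoff = 1.4) {
  if (any(r <= 0)) stop("lj_pair: r must be > 0")
  sr6 <- (sigma_ij / r)^6
  e <- 4 * epsilon_ij * (sr6 * sr6 - sr6)
  e[r > cutoff] <- 0
  e
}

# reaction-field constants for a config
.rf_constants <- function(cfg) {
  rc <- cfg$cutoff
  krf <- (cfg$epsilon_rf - 1) / ((2 * cfg$epsilon_rf + 1) * rc^3)
  crf <- 1 / rc + krf * rc^2
  list(krf = krf, crf = crf)
}

#' Coulomb pair energy with constant-shifted reaction field
#'
#' \eqn{f q_i q_j [1/r + k_{rf} r^2 - c_{rf}]} for \eqn{r \le cutoff}, zero
#' beyond, with \eqn{k_{rf} = (\epsilon_{rf}-1)/((2\epsilon_{rf}+1) r_c^3)}
#' and \eqn{c_{rf} = 1/r_c + k_{rf} r_c^2} so the potential is continuous
#' (zero) at the cutoff. Vectorized over \code{r} (and \code{qi*qj} of
#' matching shape).
#'
#' @param r distance(s), nm; must be > 0.
#' @param qi,qj partial charges, e.
#' @param cfg a \code{\link{nonbonded_config}}.
#' @return energy, kJ/mol
#' @export
coulomb_rf_pair <- function(r, qi, qj, cfg = nonbonded_config()) {
  if (any(r <= 0)) stop("coulomb_rf_pair: r must be > 0")
  k <- .rf_constants(cfg)
  e <- cfg$coulomb_constant * qi * qj * (1 / r + k$krf * r^2 - k$crf)
  e[r > cfg$cutoff] <- 0
  e
}

#' Harmonic upper-wall energy
#'
#' @param r distance(s), nm (>= 0).
#' @param wall a \code{\link{wall_config}}.
#' @return 0 for r <= r0, else 0.5 k (r - r0)^2, kJ/mol.
#' @export
wall_energy <- function(r, wall = wall_config()) {
  if (any(r < 0)) stop("wall_energy: r must be >= 0")
  d <- pmax(r - wall$r0, 0)
  0.5 * wall$k * d^2
}

# combined pair parameter matrices for two templates (na x nb)
.pair_tables <- function(tmpl_a, tmpl_b, cfg) {
  sa <- tmpl_a$atoms$sigma; sb <- tmpl_b$atoms$sigma
  ea <- tmpl_a$atoms$epsilon; eb <- tmpl_b$atoms$epsilon
  qa <- tmpl_a$atoms$charge; qb <- tmpl_b$atoms$charge
  SIG <- if (cfg$combination_rule == "geometric")
    sqrt(outer(sa, sb)) else outer(sa, sb, function(x, y) (x + y) / 2)
  EPS <- sqrt(outer(ea, eb))
  QQ <- cfg$coulomb_constant * outer(qa, qb)
  list(SIG = SIG, EPS = EPS, QQ = QQ,
       has_lj = any(EPS > 0), has_q = any(QQ != 0))
}

# intermolecular energy from world coordinates; returns +Inf on atom overlap
# (r < overlap_tol) so samplers can reject; `tables` from .pair_tables.
.intermolecular_energy <- function(xa, xb, box, cfg, tables,
                                   overlap_tol = 1e-6) {
  if (!tables$has_lj && !tables$has_q) return(0)
  dx <- min_image(outer(xa[, 1], xb[, 1], "-"), box)
  dy <- min_image(outer(xa[, 2], xb[, 2], "-"), box)
  dz <- min_image(outer(xa[, 3], xb[, 3], "-"), box)
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < overlap_tol^2)) return(Inf)
  r <- sqrt(r2)
  k <- .rf_constants(cfg)
  inr <- r <= cfg$cutoff
  e <- 0
  if (tables$has_lj) {
    sr6 <- (tables$SIG[inr] / r[inr])^6
    e <- e + sum(4 * tables$EPS[inr] * (sr6 * sr6 - sr6))
  }
  if (tables$has_q)
    e <- e + sum(tables$QQ[inr] * (1 / r[inr] + k$krf * r[inr]^2 - k$crf))
  e
}

#' Total intermolecular nonbonded energy of a rigid dimer
#'
#' Sum of LJ and reaction-field Coulomb terms over all intermolecular atom
#' pairs (intramolecular pairs excluded; the molecules are rigid) under the
#' minimum-image convention in the cubic box. Atom pairs closer than 1e-6 nm
#' are rejected as overlapping.
#'
#' @param state a \code{\link{dimer_state}}.
#' @param tmpl_a,tmpl_b \code{molecule_template}s.
#' @param cfg a \code{\link{nonbonded_config}}.
#' @return energy, kJ/mol
#' @export
dimer_energy <- function(state, tmpl_a, tmpl_b, cfg = nonbonded_config()) {
  xa <- template_world(template_coords(tmpl_a), state$pos_a, state$quat_a)
  xb <- template_world(template_coords(tmpl_b), state$pos_b, state$quat_b)
  dx <- min_image(outer(xa[, 1], xb[, 1], "-"), state$box)
  dy <- min_image(outer(xa[, 2], xb[, 2], "-"), state$box)
  dz <- min_image(outer(xa[, 3], xb[, 3], "-"), state$box)
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < 1e-12)) {
    ij <- which(r2 == min(r2), arr.ind = TRUE)[1, ]
    stop(sprintf("overlapping atoms: %s[%d] and %s[%d] at r = %.2e nm",
                 tmpl_a$name, ij[1], tmpl_b$name, ij[2], sqrt(min(r2))))
  }
  tables <- .pair_tables(tmpl_a, tmpl_b, cfg)
  if (!tables$has_lj && !tables$has_q) return(0)
  r <- sqrt(r2)
  k <- .rf_constants(cfg)
  inr <- r <= cfg$cutoff
  e <- 0
  if (tables$has_lj) {
    sr6 <- (tables$SIG[inr] / r[inr])^6
    e <- e + sum(4 * tables$EPS[inr] * (sr6 * sr6 - sr6))
  }
  if (tables$has_q)
    e <- e + sum(tables$QQ[inr] * (1 / r[inr] + k$krf * r[inr]^2 - k$crf))
  e
}
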