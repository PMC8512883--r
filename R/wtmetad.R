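# Well-tempered metadynamics bias: grid-based Gaussian deposition with the
# tempered height-decay law, multilinear bias interpolation, the bias-to-FES
# relation, and PLUMED-style HILLS file I/O.

#' Define one grid axis for a bias or FES grid
#'
#' Non-periodic axes place \code{n} nodes from \code{min} to \code{max}
#' inclusive; periodic axes place \code{n} nodes from \code{min} with spacing
#' \code{(max - min)/n} (the upper edge is identified with the lower).
#'
#' @param name axis/CV name (e.g. \code{"dist"}, \code{"torsion"}).
#' @param min,max axis range.
#' @param n number of nodes (give either \code{n} or \code{spacing}).
#' @param spacing node spacing (alternative to \code{n}).
#' @param periodic logical.
#' @return object of class \code{grid_axis}
#' @export
grid_axis <- function(name, min, max, n = NULL, spacing = NULL,
                      periodic = FALSE) {
  stopifnot(max > min)
  if (is.null(n)) {
    if (is.null(spacing)) stop("give either n or spacing")
    n <- if (periodic) round((max - min) / spacing)
         else round((max - min) / spacing) + 1L
  }
  n <- as.integer(n)
  if (n < 2) stop("axis needs at least 2 nodes")
  d <- if (periodic) (max - min) / n else (max - min) / (n - 1)
  obj <- list(name = name, min = min, max = max, n = n, spacing = d,
              periodic = periodic, nodes = min + (seq_len(n) - 1) * d)
  class(obj) <- "grid_axis"
  obj
}

#' Default bias-grid axes for dimer metadynamics
#'
#' Distance over [0, 2.2] nm (0.01 nm resolution, non-periodic; the upper
#' wall guards the top edge) and torsion over (-pi, pi] (about 0.05 rad,
#' periodic).
#' @return list of two \code{grid_axis}
#' @export
default_bias_axes <- function() {
  list(grid_axis("dist", 0, 2.2, spacing = 0.01),
       grid_axis("torsion", -pi, pi, n = 126L, periodic = TRUE))
}

#' Well-tempered metadynamics bias grid
#'
#' Holds the accumulated bias on a 1- or 2-D node grid along with the
#' deposition parameters: initial hill height, hill widths, deposition
#' stride, bias factor and temperature.
#'
#' @param axes list of \code{\link{grid_axis}} (1 or 2).
#' @param bias_factor tempering parameter gamma (> 1; default 5).
#' @param height0 initial Gaussian height w0, kJ/mol (default 1.0).
#' @param sigmas Gaussian widths per axis (defaults 0.05 nm and 0.2 rad for a
#'   distance/torsion pair; a single 0.1 for 1-D grids).
#' @param stride deposition stride in sampler steps (default 500).
#' @param temperature K (default 300).
#' @return object of class \code{bias_grid} with zero initial bias and an
#'   empty hill list.
#' @export
bias_grid <- function(axes = default_bias_axes(), bias_factor = 5,
                      height0 = 1.0, sigmas = NULL, stride = 500L,
                      temperature = 300) {
  if (inherits(axes, "grid_axis")) axes <- list(axes)
  stopifnot(length(axes) %in% 1:2,
            all(vapply(axes, inherits, TRUE, "grid_axis")))
  if (bias_factor <= 1)
    stop("configuration error: bias_factor must be > 1 (well-tempered ",
         "metadynamics is undefined for gamma <= 1)")
  if (height0 <= 0) stop("height0 must be > 0")
  if (is.null(sigmas))
    sigmas <- if (length(axes) == 2) c(0.05, 0.2) else 0.1
  if (length(sigmas) != length(axes) || any(sigmas <= 0))
    stop("sigmas must be positive, one per axis")
  dims <- vapply(axes, function(a) a$n, 1L)
  values <- array(0, dim = dims)
  hills <- .empty_hills(axes)
  obj <- list(axes = axes, values = values, bias_factor = bias_factor,
              height0 = height0, sigmas = sigmas, stride = as.integer(stride),
              temperature = temperature, hills = hills)
  class(obj) <- "bias_grid"
  obj
}

.empty_hills <- function(axes) {
  nm <- vapply(axes, function(a) a$name, "")
  cols <- c("time", nm, paste0("sigma_", nm), "height", "biasf")
  df <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
  names(df) <- cols
  df
}

#' @export
print.bias_grid <- function(x, ...) {
  cat("bias_grid over [", paste(vapply(x$axes, function(a) a$name, ""),
                                collapse = " x "),
      "], gamma = ", x$bias_factor, ", w0 = ", x$height0, " kJ/mol, ",
      nrow(x$hills), " hills, max bias ",
      format(max(x$values), digits = 4), " kJ/mol\n", sep = "")
  invisible(x)
}

# per-axis fractional position: list(i0, i1, frac) with 0-based node indices
.axis_locate <- function(axis, x, warn_clamp = TRUE) {
  u <- (x - axis$min) / axis$spacing
  if (axis$periodic) {
    u <- u %% axis$n
    i0 <- floor(u)
    list(i0 = i0 %% axis$n, i1 = (i0 + 1) %% axis$n, frac = u - i0)
  } else {
    out <- x < axis$min - 1e-9 | x > axis$max + 1e-9
    if (any(out) && warn_clamp)
      warning("value(s) outside the '", axis$name,
              "' axis range; clamping to the grid edge")
    u <- pmin(pmax(u, 0), axis$n - 1)
    i0 <- pmin(floor(u), axis$n - 2)
    list(i0 = i0, i1 = i0 + 1, frac = u - i0)
  }
}

#' Evaluate the bias by multilinear interpolation
#'
#' Linear (1-D) or bilinear (2-D) interpolation between grid nodes; periodic
#' axes wrap. Points outside a non-periodic axis range are clamped to the
#' edge with a warning.
#'
#' @param grid a \code{bias_grid}
#' @param s a numeric vector (one point) or matrix (one point per row)
#' @return bias value(s), kJ/mol
#' @export
bias_at <- function(grid, s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  d <- length(grid$axes)
  stopifnot(ncol(s) == d)
  if (d == 1) {
    lo <- .axis_locate(grid$axes[[1]], s[, 1])
    v <- grid$values
    (1 - lo$frac) * v[lo$i0 + 1] + lo$frac * v[lo$i1 + 1]
  } else {
    l1 <- .axis_locate(grid$axes[[1]], s[, 1])
    l2 <- .axis_locate(grid$axes[[2]], s[, 2])
    v <- grid$values
    v00 <- v[cbind(l1$i0 + 1, l2$i0 + 1)]
    v10 <- v[cbind(l1$i1 + 1, l2$i0 + 1)]
    v01 <- v[cbind(l1$i0 + 1, l2$i1 + 1)]
    v11 <- v[cbind(l1$i1 + 1, l2$i1 + 1)]
    (1 - l1$frac) * ((1 - l2$frac) * v00 + l2$frac * v01) +
      l1$frac * ((1 - l2$frac) * v10 + l2$frac * v11)
  }
}

# add one Gaussian of given height to a values array; truncated at 6 sigma
# per axis; periodic axes wrap displacements. Shared by deposition and by
# grid reconstruction from HILLS files.
.hill_update <- function(values, axes, center, sigmas, height) {
  d <- length(axes)
  parts <- vector("list", d)
  idx <- vector("list", d)
  for (k in seq_len(d)) {
    ax <- axes[[k]]
    disp <- ax$nodes - center[k]
    if (ax$periodic) {
      span <- ax$max - ax$min
      disp <- disp - span * round(disp / span)
    }
    keep <- which(abs(disp) <= 6 * sigmas[k])
    idx[[k]] <- keep
    parts[[k]] <- exp(-disp[keep]^2 / (2 * sigmas[k]^2))
  }
  if (any(vapply(idx, length, 1L) == 0)) return(values)
  if (d == 1) {
    values[idx[[1]]] <- values[idx[[1]]] + height * parts[[1]]
  } else {
    values[idx[[1]], idx[[2]]] <- values[idx[[1]], idx[[2]]] +
      height * (parts[[1]] %o% parts[[2]])
  }
  values
}

#' Deposit one well-tempered hill
#'
#' The hill height follows the tempering law
#' \eqn{w = w_0 \exp(-V(s)/((\gamma - 1) k_B T))} with \eqn{V(s)} the current
#' bias at the deposition point; the Gaussian (truncated at 6 sigma per axis)
#' is added to the grid.
#'
#' @param grid a \code{bias_grid}
#' @param s_now CV value(s) at the deposition point (length = number of axes)
#' @param time step index recorded with the hill
#' @return list with the updated \code{grid} and the deposited \code{hill}
#'   (one-row data.frame)
#' @export
deposit_hill <- function(grid, s_now, time = nrow(grid$hills) + 1) {
  stopifnot(inherits(grid, "bias_grid"), length(s_now) == length(grid$axes))
  v <- bias_at(grid, s_now)
  w <- grid$height0 *
    exp(-v / ((grid$bias_factor - 1) * .kt(grid$temperature)))
  grid$values <- .hill_update(grid$values, grid$axes, s_now, grid$sigmas, w)
  nm <- vapply(grid$axes, function(a) a$name, "")
  hill <- as.data.frame(as.list(c(time, s_now, grid$sigmas, w,
                                  grid$bias_factor)))
  names(hill) <- c("time", nm, paste0("sigma_", nm), "height", "biasf")
  grid$hills <- rbind(grid$hills, hill)
  list(grid = grid, hill = hill)
}

#' Rebuild a bias grid from a hill list
#'
#' Re-applies the recorded Gaussians (with their recorded heights, no
#' re-tempering) onto an empty grid — the grid equivalent of PLUMED's
#' sum_hills.
#'
#' @param hills data.frame as produced by \code{deposit_hill} /
#'   \code{\link{read_hills}}
#' @param grid an empty (or template) \code{bias_grid} defining axes and
#'   parameters
#' @return a \code{bias_grid} with the summed bias
#' @export
grid_from_hills <- function(hills, grid) {
  nm <- vapply(grid$axes, function(a) a$name, "")
  stopifnot(all(c(nm, paste0("sigma_", nm), "height") %in% names(hills)))
  grid$values[] <- 0
  for (i in seq_len(nrow(hills))) {
    grid$values <- .hill_update(grid$values, grid$axes,
                                as.numeric(hills[i, nm]),
                                as.numeric(hills[i, paste0("sigma_", nm)]),
                                hills$height[i])
  }
  grid$hills <- hills
  grid
}

#' FES estimate from the accumulated well-tempered bias
#'
#' \eqn{F(s) = -\gamma/(\gamma - 1) \, V(s) + C}; the constant is fixed later
#' by \code{\link{zero_shift}}. For gamma = 5 the prefactor is -1.25.
#'
#' @param grid a \code{bias_grid}
#' @return a \code{\link{fes_grid}} over the same axes
#' @export
fes_from_bias <- function(grid) {
  stopifnot(inherits(grid, "bias_grid"))
  g <- grid$bias_factor
  fes_grid(grid$axes, -g / (g - 1) * grid$values)
}

#' Write hills to a PLUMED-style HILLS file
#'
#' Header \code{#! FIELDS time <cvs...> sigma_<cv>... height biasf}.
#'
#' @param hills data.frame of hills
#' @param path output file
#' @param extra_header optional comment lines
#' @export
write_hills <- function(hills, path, extra_header = character(0)) {
  hdr <- c(paste("#! FIELDS", paste(names(hills), collapse = " ")),
           extra_header)
  body <- if (nrow(hills))
    do.call(sprintf, c(list(paste(rep("%.12g", ncol(hills)),
                                  collapse = " ")), unname(hills)))
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a HILLS file
#'
#' @param path input file; the FIELDS header must be
#'   \code{time <cvs...> sigma_<cv>... height biasf}, otherwise an error
#'   listing the expected columns is raised.
#' @return data.frame of hills (possibly 0 rows)
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("HILLS file not found: ", path)
  lines <- readLines(path)
  fl <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(fl) == 0) stop("HILLS file has no '#! FIELDS' header: ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fl[1])), "\\s+")[[1]]
  k <- length(fields)
  ncv <- (k - 3) / 2
  ok <- k >= 5 && ncv == round(ncv) && fields[1] == "time" &&
    fields[k - 1] == "height" && fields[k] == "biasf" &&
    all(fields[(2 + ncv):(1 + 2 * ncv)] == paste0("sigma_",
                                                  fields[2:(1 + ncv)]))
  if (!ok)
    stop("unknown HILLS FIELDS header; expected columns: time <cv...> ",
         "sigma_<cv>... height biasf, got: ", paste(fields, collapse = " "))
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(data_lines)) {
    df <- as.data.frame(matrix(numeric(0), ncol = k))
    names(df) <- fields
    return(df)
  }
  utils::read.table(text = data_lines, col.names = fields)
}

#' Uncertainty of the bias-derived FES from late-run checkpoints
#'
#' The instantaneous well-tempered estimate \eqn{-\gamma/(\gamma-1) V(s,t)}
#' keeps oscillating around the converged profile with an amplitude set by
#' the (decaying) hill height. This function rebuilds the cumulative bias at
#' several checkpoints over the tail of the hill sequence, aligns each FES
#' estimate (removes its mean over the probed nodes) and returns the
#' per-node standard deviation across checkpoints — an error bar for
#' \code{\link{fes_from_bias}}.
#'
#' @param hills hill list of the run.
#' @param grid an empty \code{bias_grid} defining axes and parameters.
#' @param from fraction of the hill sequence after which checkpoints start
#'   (default 0.5).
#' @param n_checkpoints number of checkpoints (default 10).
#' @return list with \code{stderr} (per-node array), \code{mean} (aligned
#'   mean FES estimate), \code{checkpoints} (hill counts used).
#' @export
fes_bias_error <- function(hills, grid, from = 0.5, n_checkpoints = 10) {
  n <- nrow(hills)
  if (n < n_checkpoints + 1) stop("too few hills for checkpoint analysis")
  cps <- unique(round(seq(from * n, n, length.out = n_checkpoints)))
  nm <- vapply(grid$axes, function(a) a$name, "")
  g <- grid$bias_factor
  gtmp <- grid
  gtmp$values[] <- 0
  est <- matrix(NA_real_, nrow = length(cps), ncol = length(gtmp$values))
  k <- 1L
  for (i in seq_len(n)) {
    gtmp$values <- .hill_update(gtmp$values, gtmp$axes,
                                as.numeric(hills[i, nm]),
                                as.numeric(hills[i, paste0("sigma_", nm)]),
                                hills$height[i])
    if (k <= length(cps) && i == cps[k]) {
      f <- -g / (g - 1) * as.numeric(gtmp$values)
      est[k, ] <- f - mean(f)
      k <- k + 1L
    }
  }
  dims <- vapply(grid$axes, function(a) a$n, 1L)
  list(stderr = array(apply(est, 2, stats::sd), dim = dims),
       mean = array(colMeans(est), dim = dims),
       checkpoints = cps)
}
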