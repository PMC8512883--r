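# FES post-processing: the fes_grid container, entropic (Jacobian)
# correction, zero-shifting at the flat tail, reweighting of biased
# trajectories onto arbitrary CV axes, binding-mode extraction and
# profile comparison, plus fes.dat-style text I/O.

#' Free-energy surface on a node grid
#'
#' @param axes list of \code{\link{grid_axis}} (1 or 2).
#' @param values free energy per node, kJ/mol (vector or matrix matching the
#'   axes; NA marks unsampled nodes).
#' @param stderr per-node standard errors (optional, filled by
#'   \code{\link{block_fes_error}}).
#' @param entropic_corrected,zero_shifted state flags.
#' @param shift_window distance interval used by \code{\link{zero_shift}}
#'   (default [1.6, 1.8] nm, operationalizing the nearly flat region around
#'   1.7 nm).
#' @return object of class \code{fes_grid}
#' @export
fes_grid <- function(axes, values, stderr = NULL,
                     entropic_corrected = FALSE, zero_shifted = FALSE,
                     shift_window = c(1.6, 1.8)) {
  if (inherits(axes, "grid_axis")) axes <- list(axes)
  dims <- vapply(axes, function(a) a$n, 1L)
  values <- array(as.numeric(values), dim = dims)
  if (!is.null(stderr)) stderr <- array(as.numeric(stderr), dim = dims)
  obj <- list(axes = axes, values = values, stderr = stderr,
              entropic_corrected = entropic_corrected,
              zero_shifted = zero_shifted, shift_window = shift_window)
  class(obj) <- "fes_grid"
  obj
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("fes_grid over [", paste(vapply(x$axes, function(a) a$name, ""),
                               collapse = " x "), "], ",
      sum(is.finite(x$values)), "/", length(x$values), " finite nodes",
      if (x$entropic_corrected) ", entropic-corrected" else "",
      if (x$zero_shifted) ", zero-shifted" else "", "\n", sep = "")
  invisible(x)
}

# index of the axis named `name` (default: the distance axis)
.fes_axis_index <- function(fes, name = "dist") {
  nm <- vapply(fes$axes, function(a) a$name, "")
  i <- match(name, nm)
  if (is.na(i))
    stop("FES grid has no axis named '", name, "' (axes: ",
         paste(nm, collapse = ", "), ")")
  i
}

#' Interpolate a FES at arbitrary points
#'
#' @param fes a \code{fes_grid}
#' @param s point (vector) or points (matrix, one per row)
#' @return interpolated free energy, kJ/mol
#' @export
fes_at <- function(fes, s) {
  tmp <- list(axes = fes$axes, values = fes$values)
  class(tmp) <- "bias_grid"
  bias_at(tmp, s)
}

#' Entropic (Jacobian) correction of a radial FES
#'
#' In n spatial dimensions the volume available to the second molecule grows
#' as \eqn{r^{n-1}}, so the raw radial free energy acquires a spurious
#' \eqn{-(n-1) R T \ln r} slope. This adds \eqn{(n-1) R T \ln r} at every
#' node at distance r, removing it.
#'
#' @param fes a \code{fes_grid} with a distance axis.
#' @param n_dims spatial dimensionality (default 3).
#' @param temperature K.
#' @param dist_axis name of the distance axis (default \code{"dist"}).
#' @return corrected \code{fes_grid} (flag set; double application is
#'   rejected). Nodes at r <= 0, where the correction is undefined, are set
#'   to NA with a warning.
#' @export
entropic_correction <- function(fes, n_dims = 3, temperature = 300,
                                dist_axis = "dist") {
  stopifnot(inherits(fes, "fes_grid"))
  if (fes$entropic_corrected)
    stop("entropic correction already applied (entropic_corrected flag is ",
         "set); refusing double application")
  i <- .fes_axis_index(fes, dist_axis)
  r <- fes$axes[[i]]$nodes
  corr <- rep(NA_real_, length(r))
  pos <- r > 0
  corr[pos] <- (n_dims - 1) * R_GAS * temperature * log(r[pos])
  if (any(!pos))
    warning("distance axis has nodes at r <= 0; correction undefined there, ",
            "setting those nodes to NA")
  if (length(fes$axes) == 1) {
    fes$values <- fes$values + corr
  } else if (i == 1) {
    fes$values <- fes$values + corr          # recycles down columns
  } else {
    fes$values <- sweep(fes$values, 2, corr, "+")
  }
  fes$entropic_corrected <- TRUE
  fes
}

#' Zero-shift a FES at its flat tail
#'
#' Subtracts the mean free energy over the shift window on the distance axis
#' (averaged over any second axis), anchoring F = 0 where the profile is
#' nearly flat. Gauge-invariant and idempotent.
#'
#' @param fes a \code{fes_grid}
#' @param window distance interval, nm (default the grid's
#'   \code{shift_window})
#' @param dist_axis name of the axis carrying the window (default
#'   \code{"dist"}; pass another name for non-radial grids)
#' @return shifted \code{fes_grid} with \code{zero_shifted = TRUE}
#' @export
zero_shift <- function(fes, window = NULL, dist_axis = "dist") {
  stopifnot(inherits(fes, "fes_grid"))
  if (is.null(window)) window <- fes$shift_window
  i <- .fes_axis_index(fes, dist_axis)
  r <- fes$axes[[i]]$nodes
  sel <- r >= window[1] & r <= window[2]
  if (!any(sel))
    stop("shift window [", window[1], ", ", window[2],
         "] lies outside the '", dist_axis, "' axis range")
  vals <- if (length(fes$axes) == 1) fes$values[sel]
          else if (i == 1) fes$values[sel, , drop = FALSE]
          else fes$values[, sel, drop = FALSE]
  m <- mean(vals[is.finite(vals)])
  if (!is.finite(m))
    stop("shift window contains no finite free-energy values")
  fes$values <- fes$values - m
  fes$zero_shifted <- TRUE
  fes$shift_window <- window
  fes
}

# node-centred bin index (flat) for points on a set of axes; NA outside
.node_bin <- function(axes, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(axes))
  idx <- rep(1L, nrow(X))
  mult <- 1L
  ok <- rep(TRUE, nrow(X))
  for (k in seq_along(axes)) {
    ax <- axes[[k]]
    i <- round((X[, k] - ax$min) / ax$spacing)
    if (ax$periodic) {
      i <- i %% ax$n
    } else {
      bad <- i < 0 | i > ax$n - 1
      ok <- ok & !bad
      i[bad] <- 0
    }
    idx <- idx + as.integer(i) * mult
    mult <- mult * ax$n
  }
  idx[!ok] <- NA_integer_
  idx
}

# weighted histogram -> free energy on node-centred bins
.weighted_fes <- function(X, w, axes, kt) {
  idx <- .node_bin(axes, X)
  keep <- !is.na(idx)
  n_nodes <- prod(vapply(axes, function(a) a$n, 1L))
  wsum <- numeric(n_nodes)
  if (any(keep)) {
    rs <- rowsum(w[keep], idx[keep])
    wsum[as.integer(rownames(rs))] <- rs[, 1]
  }
  f <- -kt * log(wsum / sum(w))
  f[wsum <= 0] <- NA_real_
  f
}

#' Frame weights for reweighting a metadynamics trajectory
#'
#' Time-dependent-offset variant (default): \eqn{w_t \propto
#' \exp(\beta [V(s_t, t) - c(t)])} with \eqn{V(s_t, t)} the instantaneous
#' bias recorded with the frame and
#' \eqn{c(t) = \beta^{-1} \ln [\sum_s e^{\beta\gamma V/(\gamma-1)} /
#' \sum_s e^{\beta V/(\gamma-1)}]} evaluated on the bias grid rebuilt at the
#' frame's deposition epoch. Final-bias variant: \eqn{w_t \propto
#' \exp(\beta V_{final}(s_t))} with the bias summed from all hills and
#' evaluated at the frame's biased CVs.
#'
#' @param traj a \code{cv_traj} whose frames carry the instantaneous bias.
#' @param hills hill list of the run (default \code{traj$hills}).
#' @param grid an empty \code{bias_grid} defining the biased-CV axes and
#'   tempering parameters (default \code{traj$grid}, required when hills are
#'   present).
#' @param variant \code{"time_offset"} or \code{"final_bias"}.
#' @return numeric weights, normalized to mean 1.
#' @export
reweight_weights <- function(traj, hills = traj$hills, grid = traj$grid,
                             variant = c("time_offset", "final_bias")) {
  variant <- match.arg(variant)
  stopifnot(inherits(traj, "cv_traj"))
  kt <- .kt(traj$temperature)
  beta <- 1 / kt
  n <- nrow(traj$frames)
  if (is.null(hills) || nrow(hills) == 0) {
    w <- exp(beta * (traj$frames$bias - max(traj$frames$bias)))
  } else {
    if (is.null(grid)) stop("reweighting with hills requires the bias grid ",
                            "definition (grid argument)")
    g <- grid$bias_factor
    if (variant == "final_bias") {
      full <- grid_from_hills(hills, grid)
      nm <- vapply(grid$axes, function(a) a$name, "")
      V <- bias_at(full, as.matrix(traj$frames[, nm]))
      w <- exp(beta * (V - max(V)))
    } else {
      # c(t) after each deposition epoch
      nm <- vapply(grid$axes, function(a) a$name, "")
      gtmp <- grid
      gtmp$values[] <- 0
      cs <- numeric(nrow(hills))
      for (i in seq_len(nrow(hills))) {
        gtmp$values <- .hill_update(gtmp$values, gtmp$axes,
                                    as.numeric(hills[i, nm]),
                                    as.numeric(hills[i, paste0("sigma_", nm)]),
                                    hills$height[i])
        v <- as.numeric(gtmp$values)
        vm <- max(v)
        num <- vm * g / (g - 1) * beta +
          log(mean(exp(beta * g / (g - 1) * (v - vm))))
        den <- vm / (g - 1) * beta +
          log(mean(exp(beta / (g - 1) * (v - vm))))
        cs[i] <- kt * (num - den)
      }
      epoch <- findInterval(traj$frames$time, hills$time)
      ct <- c(0, cs)[epoch + 1]
      arg <- beta * (traj$frames$bias - ct)
      w <- exp(arg - max(arg))
    }
  }
  if (!any(w > 0) || !all(is.finite(w)))
    stop("all-zero or non-finite reweighting weights: bias/trajectory ",
         "mismatch")
  w / mean(w)
}

#' Reweight a biased trajectory onto target CV axes
#'
#' Builds the weighted histogram of the trajectory on node-centred bins of
#' \code{target_axes} and returns \eqn{F = -k_B T \ln(\text{weighted
#' density})} (normalization constant absorbed by \code{\link{zero_shift}}).
#' With zero bias throughout, the weights are uniform and the result is
#' exactly the plain histogram estimate.
#'
#' @param traj a \code{cv_traj}; its frames must carry columns matching the
#'   target axis names.
#' @param target_axes list of \code{\link{grid_axis}} (1 or 2) to project on.
#' @param hills,grid,variant passed to \code{\link{reweight_weights}}.
#' @param weights optional precomputed frame weights (overrides the above).
#' @return a \code{\link{fes_grid}} (unshifted, uncorrected)
#' @export
reweight_to_cv <- function(traj, target_axes, hills = traj$hills,
                           grid = traj$grid,
                           variant = c("time_offset", "final_bias"),
                           weights = NULL) {
  if (inherits(target_axes, "grid_axis")) target_axes <- list(target_axes)
  nm <- vapply(target_axes, function(a) a$name, "")
  if (!all(nm %in% names(traj$frames)))
    stop("trajectory lacks CV column(s): ",
         paste(setdiff(nm, names(traj$frames)), collapse = ", "))
  if (is.null(weights))
    weights <- reweight_weights(traj, hills, grid, variant)
  X <- as.matrix(traj$frames[, nm])
  f <- .weighted_fes(X, weights, target_axes, .kt(traj$temperature))
  fes_grid(target_axes, f)
}

#' Extract binding minima and stacking mode from a corrected FES
#'
#' Finds the global free-energy minimum within the first (0.4-0.7 nm) and
#' second (0.8-1.1 nm) interaction shells of a zero-shifted,
#' entropic-corrected distance x angle FES, and labels the binding mode from
#' the angle at the first-shell minimum: >= 60 degrees T-shaped, <= 30
#' degrees stacked, otherwise mixed. The mode label is meaningful for
#' plane-normal-angle grids; for other second axes it is reported as-is.
#'
#' @param fes a corrected, zero-shifted \code{fes_grid} with a distance axis.
#' @param first_shell,second_shell distance windows, nm.
#' @param stacked_max,tshaped_min mode thresholds, degrees.
#' @param dist_axis name of the distance axis.
#' @return object of class \code{binding_summary}: lists
#'   \code{first_shell}/\code{second_shell} with \code{dist} (nm),
#'   \code{angle_deg}, \code{depth} (kJ/mol), and \code{mode}.
#' @export
extract_binding <- function(fes, first_shell = c(0.4, 0.7),
                            second_shell = c(0.8, 1.1),
                            stacked_max = 30, tshaped_min = 60,
                            dist_axis = "dist") {
  stopifnot(inherits(fes, "fes_grid"))
  if (!fes$zero_shifted)
    stop("extract_binding requires a zero-shifted FES (run zero_shift first)")
  if (!fes$entropic_corrected)
    stop("extract_binding requires an entropic-corrected FES ",
         "(run entropic_correction first)")
  i <- .fes_axis_index(fes, dist_axis)
  two_d <- length(fes$axes) == 2
  find_min <- function(win) {
    r <- fes$axes[[i]]$nodes
    sel <- which(r >= win[1] & r <= win[2])
    v <- if (!two_d) fes$values[sel]
         else if (i == 1) fes$values[sel, , drop = FALSE]
         else fes$values[, sel, drop = FALSE]
    if (!any(is.finite(v)))
      stop("shell window [", win[1], ", ", win[2],
           "] contains no finite free-energy values")
    k <- which(v == min(v, na.rm = TRUE), arr.ind = two_d)
    if (two_d) {
      k <- k[1, ]
      di <- if (i == 1) sel[k[1]] else sel[k[2]]
      ai <- if (i == 1) k[2] else k[1]
      other <- fes$axes[[if (i == 1) 2 else 1]]
      list(dist = r[di], angle_deg = other$nodes[ai] * 180 / pi,
           depth = min(v, na.rm = TRUE))
    } else {
      list(dist = r[sel[k[1]]], angle_deg = NA_real_,
           depth = min(v, na.rm = TRUE))
    }
  }
  fs <- find_min(first_shell)
  ss <- find_min(second_shell)
  if (fs$depth > -1e-9) {
    warning("flat first shell (depth ~ 0); mode labelled 'mixed' by ",
            "convention")
    mode <- "mixed"
  } else if (!two_d || !is.finite(fs$angle_deg)) {
    mode <- NA_character_
  } else if (fs$angle_deg >= tshaped_min) {
    mode <- "T-shaped"
  } else if (fs$angle_deg <= stacked_max) {
    mode <- "stacked"
  } else mode <- "mixed"
  obj <- list(first_shell = fs, second_shell = ss, mode = mode,
              windows = list(first = first_shell, second = second_shell))
  class(obj) <- "binding_summary"
  obj
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf(
    "binding summary: first shell min %.3f kJ/mol at %.2f nm%s; second shell min %.3f kJ/mol at %.2f nm; mode: %s\n",
    x$first_shell$depth, x$first_shell$dist,
    if (is.finite(x$first_shell$angle_deg))
      sprintf(" / %.0f deg", x$first_shell$angle_deg) else "",
    x$second_shell$depth, x$second_shell$dist, x$mode))
  invisible(x)
}

#' Compare first-shell well depths across FES profiles
#'
#' Tabulates the first-shell minimum depth (with its standard error where
#' available) for each labelled profile and flags pairs whose depths differ
#' by more than the thermal energy \eqn{k_B T} (2.494 kJ/mol at 300 K) —
#' differences below that are within thermal fluctuations.
#'
#' @param fes_list named list of comparable \code{fes_grid}s (>= 2, same
#'   axes).
#' @param temperature K (sets the \eqn{k_B T} flag threshold).
#' @param ... passed to \code{\link{extract_binding}}.
#' @return object of class \code{fes_comparison}: \code{table} (label, depth,
#'   stderr, dist, angle_deg), \code{pairs} (pairwise absolute differences
#'   and \code{exceeds_kbt} flags), and \code{kbt}.
#' @export
compare_profiles <- function(fes_list, temperature = 300, ...) {
  if (length(fes_list) < 2) stop("need at least 2 profiles to compare")
  labels <- names(fes_list)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- paste0("profile", seq_along(fes_list))
  ref <- fes_list[[1]]
  for (f in fes_list[-1]) {
    same <- length(f$axes) == length(ref$axes) &&
      all(vapply(seq_along(f$axes), function(k)
        f$axes[[k]]$n == ref$axes[[k]]$n &&
          isTRUE(all.equal(f$axes[[k]]$nodes, ref$axes[[k]]$nodes)) &&
          f$axes[[k]]$name == ref$axes[[k]]$name, TRUE))
    if (!same) stop("mismatched axes between profiles")
  }
  rows <- lapply(seq_along(fes_list), function(k) {
    b <- extract_binding(fes_list[[k]], ...)
    se <- NA_real_
    if (!is.null(fes_list[[k]]$stderr)) {
      i <- .node_bin(fes_list[[k]]$axes,
                     if (length(fes_list[[k]]$axes) == 2)
                       c(b$first_shell$dist, b$first_shell$angle_deg * pi / 180)
                     else b$first_shell$dist)
      if (!is.na(i)) se <- as.numeric(fes_list[[k]]$stderr)[i]
    }
    data.frame(label = labels[k], depth = b$first_shell$depth, stderr = se,
               dist = b$first_shell$dist, angle_deg = b$first_shell$angle_deg,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  kbt <- .kt(temperature)
  cmb <- utils::combn(seq_along(fes_list), 2)
  pairs <- data.frame(
    label_a = labels[cmb[1, ]], label_b = labels[cmb[2, ]],
    diff = abs(table$depth[cmb[1, ]] - table$depth[cmb[2, ]]),
    stringsAsFactors = FALSE)
  pairs$exceeds_kbt <- pairs$diff > kbt
  obj <- list(table = table, pairs = pairs, kbt = kbt)
  class(obj) <- "fes_comparison"
  obj
}

#' @export
print.fes_comparison <- function(x, ...) {
  cat("first-shell well depths (kJ/mol), kBT =", format(x$kbt, digits = 4),
      "kJ/mol\n")
  print(x$table, row.names = FALSE)
  if (any(x$pairs$exceeds_kbt)) {
    cat("pairs differing by more than kBT:\n")
    print(x$pairs[x$pairs$exceeds_kbt, ], row.names = FALSE)
  } else cat("no pair differs by more than kBT\n")
  invisible(x)
}

#' Write a FES grid as a PLUMED-style fes.dat file
#'
#' Header \code{#! FIELDS <cv...> free err}; grid-major rows with a blank
#' line between blocks of the first CV (2-D grids). Flags and axis
#' definitions are carried on \code{#! SET} lines so the file round-trips.
#'
#' @param fes a \code{fes_grid}
#' @param path output file
#' @param extra_header optional comment lines
#' @export
write_fes <- function(fes, path, extra_header = character(0)) {
  nm <- vapply(fes$axes, function(a) a$name, "")
  hdr <- c(paste("#! FIELDS", paste(nm, collapse = " "), "free err"),
           unlist(lapply(fes$axes, function(a)
             sprintf("#! SET axis_%s %.12g %.12g %d %d", a$name, a$min,
                     a$max, a$n, as.integer(a$periodic)))),
           sprintf("#! SET entropic_corrected %d",
                   as.integer(fes$entropic_corrected)),
           sprintf("#! SET zero_shifted %d", as.integer(fes$zero_shifted)),
           extra_header)
  err <- if (is.null(fes$stderr)) array(NA_real_, dim = dim(fes$values))
         else fes$stderr
  lines <- hdr
  if (length(fes$axes) == 1) {
    lines <- c(lines, sprintf("%.12g %.12g %.12g", fes$axes[[1]]$nodes,
                              as.numeric(fes$values), as.numeric(err)))
  } else {
    a1 <- fes$axes[[1]]; a2 <- fes$axes[[2]]
    for (i in seq_len(a1$n)) {
      lines <- c(lines,
                 sprintf("%.12g %.12g %.12g %.12g", a1$nodes[i], a2$nodes,
                         fes$values[i, ], err[i, ]),
                 "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a fes.dat file written by \code{\link{write_fes}}
#' @param path input file
#' @return a \code{fes_grid}
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) stop("fes file not found: ", path)
  lines <- readLines(path)
  fl <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(fl) == 0) stop("fes file has no '#! FIELDS' header: ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fl[1])), "\\s+")[[1]]
  ncv <- length(fields) - 2
  if (ncv < 1 || ncv > 2 || fields[ncv + 1] != "free")
    stop("unexpected fes FIELDS header: ", paste(fields, collapse = " "))
  axes <- list()
  ec <- FALSE; zs <- FALSE
  for (sl in grep("^#!\\s*SET", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^#!\\s*SET", "", sl)), "\\s+")[[1]]
    if (startsWith(tok[1], "axis_")) {
      axes[[length(axes) + 1L]] <-
        grid_axis(sub("^axis_", "", tok[1]), as.numeric(tok[2]),
                  as.numeric(tok[3]), n = as.integer(tok[4]),
                  periodic = as.integer(tok[5]) == 1L)
    }
    if (tok[1] == "entropic_corrected") ec <- tok[2] == "1"
    if (tok[1] == "zero_shifted") zs <- tok[2] == "1"
  }
  if (length(axes) != ncv) stop("fes file axis definitions missing")
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  df <- utils::read.table(text = data_lines,
                          col.names = c(fields[seq_len(ncv)], "free", "err"),
                          na.strings = c("NA", "nan", "NaN"))
  dims <- vapply(axes, function(a) a$n, 1L)
  if (nrow(df) != prod(dims)) stop("fes file node count mismatch")
  if (ncv == 1) {
    values <- df$free
    err <- df$err
  } else {
    values <- t(matrix(df$free, nrow = dims[2]))
    err <- t(matrix(df$err, nrow = dims[2]))
  }
  if (all(is.na(err))) err <- NULL
  fes_grid(axes, values, stderr = err, entropic_corrected = ec,
           zero_shifted = zs)
}
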