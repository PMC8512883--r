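# Block-analysis error estimation for (re)weighted FES profiles and the
# flatness-equals-convergence diagnostic.

#' Block-analysis standard errors of a weighted FES
#'
#' Partitions the trajectory into contiguous blocks of \code{block_size}
#' frames (the trailing partial block is discarded), computes the weighted
#' free energy \eqn{F_b = -k_B T \ln(\hat p_b)} per block on node-centred
#' bins of \code{axes}, and returns the weighted standard error of the block
#' estimates per node, blocks weighted by their total weight. The average
#' error is the unweighted mean of per-node errors over nodes populated in
#' every block (others are NA).
#'
#' @param traj a \code{cv_traj} (or data.frame of frames).
#' @param axes list of \code{\link{grid_axis}} (1 or 2) to histogram on.
#' @param block_size frames per block; at least 2 blocks must fit.
#' @param weights per-frame weights (default: uniform; use
#'   \code{\link{reweight_weights}} for metadynamics runs).
#' @param temperature K.
#' @return list with \code{stderr} (per-node array), \code{mean} (per-node
#'   weighted mean F), \code{avg_error}, \code{n_blocks}, \code{block_size}.
#' @export
block_fes_error <- function(traj, axes, block_size, weights = NULL,
                            temperature = 300) {
  frames <- if (inherits(traj, "cv_traj")) traj$frames else traj
  if (inherits(traj, "cv_traj")) temperature <- traj$temperature
  if (inherits(axes, "grid_axis")) axes <- list(axes)
  nm <- vapply(axes, function(a) a$name, "")
  stopifnot(all(nm %in% names(frames)))
  n <- nrow(frames)
  block_size <- as.integer(block_size)
  n_blocks <- n %/% block_size
  if (n_blocks < 2)
    stop("need at least 2 blocks: ", n, " frames / block size ", block_size)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  kt <- .kt(temperature)
  X <- as.matrix(frames[, nm])
  idx <- .node_bin(axes, X)
  n_nodes <- prod(vapply(axes, function(a) a$n, 1L))

  Fb <- matrix(NA_real_, nrow = n_blocks, ncol = n_nodes)
  Wb <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    sel <- ((b - 1L) * block_size + 1L):(b * block_size)
    w <- weights[sel]; ib <- idx[sel]
    keep <- !is.na(ib)
    Wb[b] <- sum(w)
    wsum <- numeric(n_nodes)
    if (any(keep)) {
      rs <- rowsum(w[keep], ib[keep])
      wsum[as.integer(rownames(rs))] <- rs[, 1]
    }
    f <- -kt * log(wsum / Wb[b])
    f[wsum <= 0] <- NA_real_
    Fb[b, ] <- f
  }
  pop_all <- colSums(!is.na(Fb)) == n_blocks
  wtot <- sum(Wb)
  werr <- rep(NA_real_, n_nodes)
  wmean <- rep(NA_real_, n_nodes)
  if (any(pop_all)) {
    wn <- Wb / wtot
    mcol <- colSums(Fb[, pop_all, drop = FALSE] * wn)
    dev2 <- sweep(Fb[, pop_all, drop = FALSE], 2, mcol)^2
    # weighted variance of block means with an n/(n-1) bias correction,
    # scaled by the effective inverse sample size sum(w^2)/(sum w)^2
    s2 <- colSums(dev2 * wn) * n_blocks / (n_blocks - 1)
    werr[pop_all] <- sqrt(s2 * sum(wn^2))
    wmean[pop_all] <- mcol
  }
  dims <- vapply(axes, function(a) a$n, 1L)
  list(stderr = array(werr, dim = dims), mean = array(wmean, dim = dims),
       avg_error = if (any(pop_all)) mean(werr[pop_all]) else NA_real_,
       n_blocks = n_blocks, block_size = block_size)
}

#' Block-error convergence curve
#'
#' Average FES error as a function of block size. For converged (effectively
#' uncorrelated) sampling the curve is flat; residual correlation makes it
#' rise until blocks exceed the correlation time. The verdict fits the slope
#' of average error versus log2(block size) over the three largest sizes:
#' converged when the slope is below \code{tol} kJ/mol per doubling.
#'
#' @inheritParams block_fes_error
#' @param block_sizes strictly increasing block sizes; each must yield at
#'   least 2 blocks.
#' @param tol convergence slope tolerance, kJ/mol per doubling of the block
#'   size (default 0.05).
#' @return object of class \code{block_error_curve}: \code{curve}
#'   (data.frame block_size, avg_error), \code{slope}, \code{converged},
#'   and the largest-block per-node errors in \code{stderr}.
#' @export
convergence_curve <- function(traj, axes, block_sizes, weights = NULL,
                              temperature = 300, tol = 0.05) {
  block_sizes <- as.integer(block_sizes)
  if (any(diff(block_sizes) <= 0))
    stop("block sizes must be strictly increasing")
  res <- lapply(block_sizes, function(bs)
    block_fes_error(traj, axes, bs, weights = weights,
                    temperature = temperature))
  avg <- vapply(res, function(r) r$avg_error, 0)
  k <- length(block_sizes)
  if (k < 3) stop("need at least 3 block sizes for a convergence verdict")
  # smallest correlated blocks may leave no node populated in every block
  # (avg_error NA); the verdict uses the largest three informative sizes
  top <- utils::tail(which(is.finite(avg)), 3)
  if (length(top) < 2) {
    slope <- NA_real_
  } else {
    fit <- stats::lm(avg[top] ~ log2(block_sizes[top]))
    slope <- unname(stats::coef(fit)[2])
  }
  obj <- list(curve = data.frame(block_size = block_sizes, avg_error = avg),
              slope = slope, converged = is.finite(slope) && slope < tol,
              tol = tol, stderr = res[[k]]$stderr)
  class(obj) <- "block_error_curve"
  obj
}

#' @export
print.block_error_curve <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  cat(sprintf("slope over largest blocks: %.4g kJ/mol per doubling -> %s\n",
              x$slope,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Write a convergence curve (or two) as TSV
#'
#' @param biased \code{block_error_curve} of the biased run.
#' @param reweighted optional \code{block_error_curve} of the reweighted
#'   profile (same block sizes).
#' @param path output file.
#' @param extra_header optional comment lines.
#' @export
write_block_curve <- function(biased, path, reweighted = NULL,
                              extra_header = character(0)) {
  df <- data.frame(block_size = biased$curve$block_size,
                   avg_error_biased = biased$curve$avg_error)
  if (!is.null(reweighted))
    df$avg_error_reweighted <- reweighted$curve$avg_error
  lines <- c(extra_header, paste(names(df), collapse = "\t"),
             do.call(sprintf,
                     c(list(paste(rep("%g", ncol(df)), collapse = "\t")),
                       unname(df))))
  writeLines(lines, path)
  invisible(path)
}
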