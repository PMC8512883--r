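# Collective variables for aromatic dimer stacking: COG distance, the
# torsion (anchor_a, COG_a, COG_b, anchor_b), and the angle between the
# best-fit ring-plane normals. COLVAR-style trajectory I/O lives here too.

# world-frame ring COG of one molecule
.ring_cog_world <- function(state, tmpl, which = c("a", "b")) {
  which <- match.arg(which)
  coords <- template_coords(tmpl)[tmpl$ring, , drop = FALSE]
  pos <- if (which == "a") state$pos_a else state$pos_b
  quat <- if (which == "a") state$quat_a else state$quat_b
  colMeans(template_world(coords, pos, quat))
}

#' COG distance between the rings of a dimer
#'
#' Euclidean distance between the ring-atom centres of geometry under the
#' minimum-image convention.
#'
#' @param state a \code{dimer_state}
#' @param tmpl_a,tmpl_b molecule templates
#' @return distance, nm
#' @export
cog_distance <- function(state, tmpl_a, tmpl_b) {
  ca <- .ring_cog_world(state, tmpl_a, "a")
  cb <- .ring_cog_world(state, tmpl_b, "b")
  d <- min_image(cb - ca, state$box)
  sqrt(sum(d * d))
}

#' Inter-ring torsion
#'
#' Signed dihedral over the four points (anchor_a, COG_a, COG_b, anchor_b),
#' in (-pi, pi]. Molecule B is taken at its minimum image relative to A.
#' The sign convention follows the standard atan2 dihedral; swapping the
#' molecule labels flips the sign.
#'
#' @inheritParams cog_distance
#' @return torsion, rad
#' @export
ring_torsion <- function(state, tmpl_a, tmpl_b) {
  ca <- .ring_cog_world(state, tmpl_a, "a")
  cb <- .ring_cog_world(state, tmpl_b, "b")
  shift <- min_image(cb - ca, state$box) - (cb - ca)
  cb <- cb + shift
  if (sum((cb - ca)^2) < 1e-18)
    stop("undefined CV: coincident ring COGs")
  pa <- template_world(template_coords(tmpl_a)[tmpl_a$anchor, , drop = FALSE],
                       state$pos_a, state$quat_a)[1, ]
  pb <- template_world(template_coords(tmpl_b)[tmpl_b$anchor, , drop = FALSE],
                       state$pos_b, state$quat_b)[1, ] + shift
  dihedral_angle(pa, ca, cb, pb)
}

#' Angle between ring-plane normals
#'
#' Each ring plane is the best-fit plane of its ring atoms (smallest principal
#' direction of the centred coordinates). Since plane normals are
#' sign-ambiguous, the angle is folded to [0, pi/2]: 0 for parallel (stacked)
#' rings, pi/2 for perpendicular (T-shaped) rings.
#'
#' @inheritParams cog_distance
#' @return angle, rad in [0, pi/2]
#' @export
normal_angle <- function(state, tmpl_a, tmpl_b) {
  xa <- template_world(template_coords(tmpl_a)[tmpl_a$ring, , drop = FALSE],
                       state$pos_a, state$quat_a)
  xb <- template_world(template_coords(tmpl_b)[tmpl_b$ring, , drop = FALSE],
                       state$pos_b, state$quat_b)
  na_ <- plane_normal(xa)
  nb_ <- plane_normal(xb)
  acos(min(1, abs(sum(na_ * nb_))))
}

#' All three collective variables of a dimer state
#'
#' @inheritParams cog_distance
#' @return named numeric: \code{dist} (nm), \code{torsion} (rad),
#'   \code{nangle} (rad)
#' @export
dimer_cvs <- function(state, tmpl_a, tmpl_b) {
  c(dist = cog_distance(state, tmpl_a, tmpl_b),
    torsion = ring_torsion(state, tmpl_a, tmpl_b),
    nangle = normal_angle(state, tmpl_a, tmpl_b))
}

#' CV trajectory container
#'
#' Time series of collective-variable values plus the instantaneous
#' metadynamics bias at each frame; the in-memory equivalent of a PLUMED
#' COLVAR file.
#'
#' @param frames data.frame with a strictly increasing \code{time} column, one
#'   column per CV, and a finite \code{bias} column (kJ/mol).
#' @param cv_names names of the CV columns, in order.
#' @param temperature K.
#' @param bias_factor well-tempered bias factor of the generating run (NA for
#'   unbiased runs).
#' @param seed RNG seed of the generating run.
#' @param hills data.frame of deposited hills (optional).
#' @param grid final bias grid of the generating run (optional).
#' @return object of class \code{cv_traj}
#' @export
cv_traj <- function(frames, cv_names, temperature = 300, bias_factor = NA,
                    seed = NA, hills = NULL, grid = NULL) {
  stopifnot(is.data.frame(frames), all(c("time", "bias", cv_names) %in%
                                         names(frames)))
  if (nrow(frames) > 1 && any(diff(frames$time) <= 0))
    stop("invariant violated: frame times must be strictly increasing")
  if (!all(is.finite(frames$bias)))
    stop("invariant violated: bias must be finite")
  obj <- list(frames = frames[, c("time", cv_names, "bias")],
              cv_names = cv_names, temperature = temperature,
              bias_factor = bias_factor, seed = seed,
              hills = hills, grid = grid)
  class(obj) <- "cv_traj"
  obj
}

#' @export
print.cv_traj <- function(x, ...) {
  cat("cv_traj: ", nrow(x$frames), " frames, CVs [",
      paste(x$cv_names, collapse = ", "), "], T = ", x$temperature,
      " K, bias factor ", x$bias_factor, "\n", sep = "")
  invisible(x)
}

#' Write a CV trajectory as a PLUMED-style COLVAR file
#'
#' Header \code{#! FIELDS time <cvs...> bias}; one space-separated row per
#' frame. Extra \code{#! SET} lines carry metadata.
#'
#' @param traj a \code{cv_traj}
#' @param path output file
#' @param extra_header optional extra \code{#!} or \code{#} comment lines
#' @export
write_colvar <- function(traj, path, extra_header = character(0)) {
  stopifnot(inherits(traj, "cv_traj"))
  fr <- traj$frames
  hdr <- c(paste("#! FIELDS", paste(names(fr), collapse = " ")),
           sprintf("#! SET temperature %g", traj$temperature),
           sprintf("#! SET bias_factor %g", traj$bias_factor),
           extra_header)
  body <- do.call(sprintf, c(list(paste(rep("%.12g", ncol(fr)),
                                        collapse = " ")), unname(fr)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a COLVAR file written by \code{\link{write_colvar}} (or PLUMED)
#'
#' @param path input file
#' @return a \code{cv_traj}; CV names are taken from the FIELDS header.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("COLVAR file not found: ", path)
  lines <- readLines(path)
  fl <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(fl) == 0) stop("COLVAR file has no '#! FIELDS' header: ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fl[1])), "\\s+")[[1]]
  if (fields[1] != "time" || !"bias" %in% fields)
    stop("COLVAR header must contain 'time' first and a 'bias' column; got: ",
         paste(fields, collapse = " "))
  temperature <- 300; bias_factor <- NA
  for (sl in grep("^#!\\s*SET", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^#!\\s*SET", "", sl)), "\\s+")[[1]]
    if (tok[1] == "temperature") temperature <- as.numeric(tok[2])
    if (tok[1] == "bias_factor") bias_factor <- as.numeric(tok[2])
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fr <- if (length(data_lines)) {
    df <- utils::read.table(text = data_lines, col.names = fields)
    df
  } else {
    df <- as.data.frame(matrix(numeric(0), ncol = length(fields)))
    names(df) <- fields
    df
  }
  cvs <- setdiff(fields, c("time", "bias"))
  cv_traj(fr, cvs, temperature = temperature, bias_factor = bias_factor)
}
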