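# Synthetic rigid planar aromatic molecules and the plain-text geometry /
# topology formats consumed by the rest of the pipeline.
#
# Units package-wide: nm, kJ/mol, radians (degrees only at presentation), K.

#' Construct a rigid planar molecule template
#'
#' A molecule template is the rigid-body description the pipeline works with:
#' atom coordinates in a body frame whose origin is the centre of geometry
#' (COG) of the ring atoms, per-atom Lennard-Jones and charge parameters, the
#' indices of the atoms defining the aromatic plane, and the anchor atom used
#' (together with the COGs) to define the inter-ring torsion.
#'
#' @param atoms data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z} (nm, body frame), \code{sigma} (nm), \code{epsilon} (kJ/mol),
#'   \code{charge} (e).
#' @param ring integer indices (1-based) of the ring atoms defining the plane.
#' @param anchor index (1-based) of the atom anchoring the torsion CV.
#' @param name molecule label.
#' @return object of class \code{molecule_template} with fields \code{atoms},
#'   \code{ring}, \code{anchor}, \code{name}, \code{net_charge}.
#' @export
molecule_template <- function(atoms, ring, anchor = 1L, name = "mol") {
  req <- c("name", "x", "y", "z", "sigma", "epsilon", "charge")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop("atoms must be a data.frame with columns: ", paste(req, collapse = ", "))
  atoms <- atoms[, req]
  n <- nrow(atoms)
  ring <- as.integer(ring)
  anchor <- as.integer(anchor)
  num <- as.matrix(atoms[, c("x", "y", "z", "sigma", "epsilon", "charge")])
  if (!all(is.finite(num)))
    stop("invariant violated: atom fields must be finite")
  if (any(atoms$sigma <= 0))
    stop("invariant violated: sigma must be > 0")
  if (any(atoms$epsilon < 0))
    stop("invariant violated: epsilon must be >= 0")
  if (length(ring) < 3 || any(ring < 1L) || any(ring > n) || anyDuplicated(ring))
    stop("invariant violated: need >= 3 distinct valid ring atom indices")
  if (anchor < 1L || anchor > n)
    stop("invariant violated: anchor index out of range")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  cog <- colMeans(coords[ring, , drop = FALSE])
  if (any(abs(cog) > 1e-9))
    stop("invariant violated: ring-atom COG must be the body-frame origin ",
         "(found |COG| = ", format(max(abs(cog))), " nm)")
  # non-collinearity: plane_normal() errors on collinear rings
  plane_normal(coords[ring, , drop = FALSE])
  obj <- list(name = name, atoms = atoms, ring = ring, anchor = anchor,
              net_charge = sum(atoms$charge))
  class(obj) <- "molecule_template"
  obj
}

#' @export
print.molecule_template <- function(x, ...) {
  cat("molecule_template '", x$name, "': ", nrow(x$atoms), " atoms, ",
      length(x$ring), " ring atoms, anchor ", x$anchor,
      ", net charge ", format(x$net_charge), " e\n", sep = "")
  invisible(x)
}

# body-frame coordinate matrix (n x 3)
template_coords <- function(tmpl) {
  as.matrix(tmpl$atoms[, c("x", "y", "z")])
}

.param_styles <- list(
  # merged carbon-like united ring atom (hydrogens omitted)
  generic = list(sigma = 0.355, epsilon = 0.29, charge = 0)
)

#' Generate a linear fused-ring (acene-like) planar template
#'
#' Builds a benzene-like hexagon for \code{n_fused_rings = 1}; each additional
#' fused ring shares an edge with the previous one and adds 4 atoms, giving the
#' linear acene series (naphthalene-, anthracene-, tetracene-like) with
#' \eqn{4n + 2} ring atoms. All atoms are ring atoms, carry uniform carbon-like
#' nonbonded parameters and zero charge, and lie exactly in the z = 0 plane
#' with the ring COG at the origin.
#'
#' @param n_fused_rings integer in 1..4.
#' @param bond_length C-C bond length, nm (default 0.14, benzene-like; for a
#'   regular hexagon this equals the circumradius).
#' @param param_style either the name of a built-in parameter set
#'   (\code{"generic"}: sigma 0.355 nm, epsilon 0.29 kJ/mol, charge 0) or a
#'   list with elements \code{sigma}, \code{epsilon}, \code{charge}.
#' @return a \code{molecule_template}
#' @export
make_ring_template <- function(n_fused_rings, bond_length = 0.14,
                               param_style = "generic") {
  if (length(n_fused_rings) != 1 || !n_fused_rings %in% 1:4)
    stop("unsupported n_fused_rings: must be one of 1, 2, 3, 4")
  if (bond_length <= 0) stop("bond_length must be > 0")
  if (is.character(param_style)) {
    if (!param_style %in% names(.param_styles))
      stop("unknown param_style '", param_style, "'")
    pp <- .param_styles[[param_style]]
  } else pp <- param_style
  L <- bond_length
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_fused_rings) - 1) {
    cx <- i * sqrt(3) * L
    ang <- (30 + 60 * 0:5) * pi / 180
    vert <- cbind(cx + L * cos(ang), L * sin(ang))
    for (k in seq_len(6)) {
      p <- vert[k, ]
      if (nrow(pts) == 0 ||
          min(colSums((t(pts) - p)^2)) > (1e-6 * L)^2)
        pts <- rbind(pts, p)
    }
  }
  pts <- sweep(pts, 2, colMeans(pts))          # ring COG -> origin
  n <- nrow(pts)
  atoms <- data.frame(
    name = paste0("C", seq_len(n)),
    x = pts[, 1], y = pts[, 2], z = rep(0, n),
    sigma = pp$sigma, epsilon = pp$epsilon, charge = pp$charge,
    stringsAsFactors = FALSE)
  nm <- c("benzene_like", "naphthalene_like", "anthracene_like",
          "tetracene_like")[n_fused_rings]
  molecule_template(atoms, ring = seq_len(n), anchor = 1L, name = nm)
}

#' Pose of a rigid dimer in a cubic periodic box
#'
#' @param pos_a,pos_b translations of molecule A/B, nm.
#' @param quat_a,quat_b orientations as unit quaternions (w, x, y, z);
#'   normalized on construction, rejected if far from unit norm.
#' @param box cubic box edge, nm (default 5, two small molecules in a
#'   5 x 5 x 5 nm box).
#' @return object of class \code{dimer_state}
#' @export
dimer_state <- function(pos_a, pos_b, quat_a = c(1, 0, 0, 0),
                        quat_b = c(1, 0, 0, 0), box = 5) {
  stopifnot(length(pos_a) == 3, length(pos_b) == 3,
            length(quat_a) == 4, length(quat_b) == 4, box > 0)
  for (q in list(quat_a, quat_b))
    if (abs(sqrt(sum(q * q)) - 1) > 1e-6)
      stop("invariant violated: quaternion norm differs from 1 by > 1e-6")
  obj <- list(pos_a = as.numeric(pos_a), pos_b = as.numeric(pos_b),
              quat_a = quat_normalize(quat_a), quat_b = quat_normalize(quat_b),
              box = box)
  class(obj) <- "dimer_state"
  obj
}

#' Write a molecule template to a plain-text topology file
#'
#' Format: header lines \code{molecule <name>}, \code{ring <indices>},
#' \code{anchor <index>} (indices 0-based on disk), then one line per atom:
#' \code{name x y z sigma epsilon charge} (nm, nm, kJ/mol, e).
#'
#' @param template a \code{molecule_template}
#' @param path output file
#' @export
write_topology <- function(template, path) {
  stopifnot(inherits(template, "molecule_template"))
  a <- template$atoms
  lines <- c(
    paste("molecule", template$name),
    paste("ring", paste(template$ring - 1L, collapse = " ")),
    paste("anchor", template$anchor - 1L),
    sprintf("%s %.12g %.12g %.12g %.12g %.12g %.12g",
            a$name, a$x, a$y, a$z, a$sigma, a$epsilon, a$charge))
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule template from a topology file
#'
#' @param path input file (format of \code{\link{write_topology}})
#' @return a \code{molecule_template}; malformed lines are reported with their
#'   line number, violated invariants with the invariant's name.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 4) stop("topology file too short: ", path)
  name <- NULL; ring <- NULL; anchor <- NULL
  atom_rows <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] == "molecule") {
      if (length(tok) != 2) stop("malformed 'molecule' header at line ", i)
      name <- tok[2]
    } else if (tok[1] == "ring") {
      v <- suppressWarnings(as.integer(tok[-1]))
      if (length(v) == 0 || anyNA(v))
        stop("malformed 'ring' header at line ", i)
      ring <- v + 1L
    } else if (tok[1] == "anchor") {
      v <- suppressWarnings(as.integer(tok[2]))
      if (length(tok) != 2 || is.na(v))
        stop("malformed 'anchor' header at line ", i)
      anchor <- v + 1L
    } else {
      if (length(tok) != 7)
        stop("malformed atom line ", i, ": expected 7 fields, got ", length(tok))
      num <- suppressWarnings(as.numeric(tok[2:7]))
      if (anyNA(num))
        stop("parse error at line ", i, ": non-numeric atom field")
      atom_rows[[length(atom_rows) + 1L]] <-
        data.frame(name = tok[1], x = num[1], y = num[2], z = num[3],
                   sigma = num[4], epsilon = num[5], charge = num[6],
                   stringsAsFactors = FALSE)
    }
  }
  if (is.null(name) || is.null(ring) || is.null(anchor))
    stop("topology file missing molecule/ring/anchor header: ", path)
  atoms <- do.call(rbind, atom_rows)
  molecule_template(atoms, ring = ring, anchor = anchor, name = name)
}

#' Read an XYZ trajectory file
#'
#' Standard XYZ dialect: count line, comment line, atom lines. Coordinates are
#' Angstrom on disk and converted to nm. Multiple concatenated frames are
#' supported.
#'
#' @param path input file
#' @return list of frames; each frame is a list with \code{labels} (character)
#'   and \code{coords} (n x 3 matrix, nm) and \code{comment}.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty XYZ file: ", path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("invalid atom count at line ", i, " of ", path)
    if (i + 1L + n > length(lines))
      stop("atom count mismatch: frame at line ", i, " declares ", n,
           " atoms but file ends early")
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    if (any(vapply(tok, length, 1L) < 4))
      stop("malformed atom line in frame at line ", i)
    labels <- vapply(tok, `[[`, "", 1L)
    coords <- t(vapply(tok, function(t)
      suppressWarnings(as.numeric(t[2:4])), numeric(3)))
    if (anyNA(coords)) stop("non-numeric coordinate in frame at line ", i)
    frames[[length(frames) + 1L]] <-
      list(labels = labels, coords = coords / 10, comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write frames to an XYZ file
#'
#' @param frames a single frame (list with \code{labels}, \code{coords} in nm)
#'   or a list of such frames.
#' @param path output file
#' @param comment default comment line
#' @export
write_xyz <- function(frames, path, comment = "generated by dimerfes") {
  if (!is.null(frames$coords)) frames <- list(frames)
  out <- character(0)
  for (fr in frames) {
    n <- nrow(fr$coords)
    cmt <- if (!is.null(fr$comment)) fr$comment else comment
    out <- c(out, as.character(n), cmt,
             sprintf("%s %.9f %.9f %.9f", fr$labels,
                     fr$coords[, 1] * 10, fr$coords[, 2] * 10,
                     fr$coords[, 3] * 10))
  }
  writeLines(out, path)
  invisible(path)
}

#' Snapshot of a dimer state as an XYZ frame
#' @param state a \code{dimer_state}
#' @param tmpl_a,tmpl_b molecule templates
#' @return a frame suitable for \code{\link{write_xyz}}
#' @export
dimer_frame <- function(state, tmpl_a, tmpl_b) {
  xa <- template_world(template_coords(tmpl_a), state$pos_a, state$quat_a)
  xb <- template_world(template_coords(tmpl_b), state$pos_b, state$quat_b)
  list(labels = c(tmpl_a$atoms$name, tmpl_b$atoms$name),
       coords = rbind(xa, xb),
       comment = sprintf("dimer %s + %s box %.4f nm",
                         tmpl_a$name, tmpl_b$name, state$box))
}
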