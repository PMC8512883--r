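# End-to-end pipeline: run configuration (YAML), generate/run/analyze/
# compare steps, provenance (resolved config + hash in output headers).

#' Build a run configuration
#'
#' All knobs of a metadynamics dimer run in one serializable list. Every
#' pipeline run writes the resolved configuration next to its outputs, and
#' every output file carries a short hash of it for provenance.
#'
#' @param molecule list: either \code{n_rings} (1..4) for a generated
#'   template or \code{topology} (path) for a file-defined molecule.
#' @param sampler list: \code{n_steps}, \code{record_stride}, \code{seed},
#'   \code{max_trans}, \code{max_rot}, \code{box}.
#' @param nonbonded list mirroring \code{\link{nonbonded_config}} keys
#'   (\code{cutoff_nm}, \code{epsilon_rf}, \code{combination_rule},
#'   \code{temperature}).
#' @param wall list: \code{wall_r0_nm}, \code{wall_k}.
#' @param metad list: \code{hill_height}, \code{sigma_dist},
#'   \code{sigma_torsion}, \code{stride}, \code{bias_factor},
#'   \code{dist_max}, \code{dist_spacing}, \code{torsion_bins}.
#' @param analysis list: \code{shift_window}, \code{first_shell},
#'   \code{second_shell}, \code{stacked_max_deg}, \code{tshaped_min_deg},
#'   \code{reweight_variant}, \code{nangle_bins}, \code{rew_dist_spacing},
#'   \code{block_sizes}.
#' @param output_dir where run outputs go.
#' @return object of class \code{run_config}
#' @export
run_config <- function(molecule = list(n_rings = 1),
                       sampler = list(),
                       nonbonded = list(),
                       wall = list(),
                       metad = list(),
                       analysis = list(),
                       output_dir = "dimerfes_run") {
  defaults <- list(
    molecule = list(n_rings = 1, topology = NULL),
    sampler = list(n_steps = 200000L, record_stride = 1L, seed = 1L,
                   max_trans = 0.15, max_rot = 0.3, box = 5,
                   tune_steps = 5000L),
    nonbonded = list(cutoff_nm = 1.4, epsilon_rf = 54,
                     combination_rule = "lorentz_berthelot",
                     temperature = 300),
    wall = list(wall_r0_nm = 2, wall_k = 200),
    metad = list(hill_height = 1.0, sigma_dist = 0.05, sigma_torsion = 0.2,
                 stride = 500L, bias_factor = 5, dist_max = 2.2,
                 dist_spacing = 0.01, torsion_bins = 126L),
    analysis = list(shift_window = c(1.6, 1.8), first_shell = c(0.4, 0.7),
                    second_shell = c(0.8, 1.1), stacked_max_deg = 30,
                    tshaped_min_deg = 60, reweight_variant = "time_offset",
                    nangle_bins = 19L, rew_dist_spacing = 0.05,
                    block_sizes = NULL))
  cfg <- defaults
  user <- list(molecule = molecule, sampler = sampler, nonbonded = nonbonded,
               wall = wall, metad = metad, analysis = analysis)
  for (sec in names(user))
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  cfg$output_dir <- output_dir
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @return a \code{run_config}
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw),
                                    c("molecule", "sampler", "nonbonded",
                                      "wall", "metad", "analysis",
                                      "output_dir"))])
}

#' @rdname read_run_config
#' @param config a \code{run_config}
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(.strip_null(unclass(config)), path)
  invisible(path)
}

# drop NULL entries recursively (YAML round trips do not preserve them)
.strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, .strip_null)
}

# short provenance hash of a config, canonicalized through a YAML
# load/dump cycle so the in-memory and re-read configs hash identically
config_hash <- function(config) {
  s <- yaml::as.yaml(.strip_null(unclass(config)))
  s <- yaml::as.yaml(yaml::yaml.load(s))
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.resolve_template <- function(molecule) {
  if (!is.null(molecule$topology)) {
    if (!file.exists(molecule$topology))
      stop("missing topology file: ", molecule$topology)
    read_topology(molecule$topology)
  } else {
    make_ring_template(molecule$n_rings)
  }
}

.bias_grid_from_config <- function(cfg) {
  m <- cfg$metad
  bias_grid(
    axes = list(grid_axis("dist", 0, m$dist_max, spacing = m$dist_spacing),
                grid_axis("torsion", -pi, pi, n = as.integer(m$torsion_bins),
                          periodic = TRUE)),
    bias_factor = m$bias_factor, height0 = m$hill_height,
    sigmas = c(m$sigma_dist, m$sigma_torsion), stride = m$stride,
    temperature = cfg$nonbonded$temperature)
}

#' Generate topology and geometry files for a ring molecule
#'
#' @param n_rings 1..4 fused rings.
#' @param out_dir output directory (created if needed).
#' @param name optional molecule name override.
#' @param bond_length nm.
#' @return invisible list of written paths (\code{topology}, \code{xyz}).
#' @export
pipeline_generate <- function(n_rings, out_dir, name = NULL,
                              bond_length = 0.14) {
  tmpl <- make_ring_template(n_rings, bond_length)
  if (!is.null(name)) tmpl$name <- name
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  top <- file.path(out_dir, paste0(tmpl$name, ".top"))
  xyz <- file.path(out_dir, paste0(tmpl$name, ".xyz"))
  write_topology(tmpl, top)
  write_xyz(list(labels = tmpl$atoms$name, coords = template_coords(tmpl),
                 comment = tmpl$name), xyz)
  invisible(list(topology = top, xyz = xyz))
}

#' Run a well-tempered metadynamics dimer simulation from a configuration
#'
#' Resolves the molecule, runs \code{\link{mc_sample}} with metadynamics on
#' (dist, torsion), and writes COLVAR, HILLS, a log file and the resolved
#' configuration (all stamped with the config hash) into the output
#' directory.
#'
#' @param config a \code{run_config} or path to a YAML config.
#' @param out_dir output directory (default \code{config$output_dir}).
#' @return invisible list: \code{traj}, \code{paths}, \code{config}.
#' @export
pipeline_run <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- .resolve_template(config$molecule)
  nb <- nonbonded_config(cutoff = config$nonbonded$cutoff_nm,
                         epsilon_rf = config$nonbonded$epsilon_rf,
                         combination_rule = config$nonbonded$combination_rule,
                         temperature = config$nonbonded$temperature)
  wl <- wall_config(r0 = config$wall$wall_r0_nm, k = config$wall$wall_k)
  grid <- .bias_grid_from_config(config)
  sc <- config$sampler
  traj <- mc_sample(tmpl, tmpl, n_steps = as.integer(sc$n_steps),
                    seed = as.integer(sc$seed), nonbonded = nb, wall = wl,
                    metad = grid, box = sc$box,
                    record_stride = as.integer(sc$record_stride),
                    max_trans = sc$max_trans, max_rot = sc$max_rot,
                    tune_steps = as.integer(sc$tune_steps))
  hash <- config_hash(config)
  stamp <- sprintf("#! SET config_hash %s", hash)
  paths <- list(colvar = file.path(out_dir, "COLVAR"),
                hills = file.path(out_dir, "HILLS"),
                config = file.path(out_dir, "config_resolved.yaml"),
                log = file.path(out_dir, "run.log"))
  write_colvar(traj, paths$colvar, extra_header = stamp)
  write_hills(traj$hills, paths$hills, extra_header = stamp)
  write_run_config(config, paths$config)
  writeLines(c(sprintf("# config %s", hash),
               sprintf("molecule: %s (%d atoms)", tmpl$name,
                       nrow(tmpl$atoms)),
               sprintf("steps: %d  recorded frames: %d", sc$n_steps,
                       nrow(traj$frames)),
               sprintf("hills deposited: %d  final hill height: %.4g kJ/mol",
                       nrow(traj$hills),
                       if (nrow(traj$hills)) traj$hills$height[
                         nrow(traj$hills)] else NA),
               sprintf("acceptance rate: %.3f", traj$log$acceptance),
               sprintf("tuned move sizes: %.3g nm / %.3g rad",
                       traj$log$max_trans, traj$log$max_rot)),
             paths$log)
  invisible(list(traj = traj, paths = paths, config = config))
}

#' Analyze a completed run directory
#'
#' Reads COLVAR and HILLS, rebuilds the bias, and writes: \code{fes.dat}
#' (biased dist x torsion FES after entropic correction and zero-shift),
#' \code{fes_reweighted.dat} (dist x normal-angle FES via reweighting, same
#' corrections, with block-analysis errors), \code{binding.json} (first/
#' second-shell minima and stacking mode) and \code{blockerror.tsv}
#' (convergence curves for the biased and reweighted profiles).
#'
#' @param run_dir directory produced by \code{\link{pipeline_run}}.
#' @param out_dir where to write analysis outputs (default \code{run_dir}).
#' @return invisible list with the computed objects.
#' @export
pipeline_analyze <- function(run_dir, out_dir = run_dir) {
  colvar_path <- file.path(run_dir, "COLVAR")
  hills_path <- file.path(run_dir, "HILLS")
  config_path <- file.path(run_dir, "config_resolved.yaml")
  for (p in c(colvar_path, hills_path, config_path))
    if (!file.exists(p)) stop("run directory is missing ", basename(p),
                              ": ", p)
  config <- read_run_config(config_path)
  an <- config$analysis
  temperature <- config$nonbonded$temperature
  traj <- read_colvar(colvar_path)
  traj$temperature <- temperature
  hills <- read_hills(hills_path)
  grid <- .bias_grid_from_config(config)
  traj$hills <- hills
  traj$grid <- grid
  traj$bias_factor <- grid$bias_factor
  hash <- config_hash(config)
  stamp <- sprintf("#! SET config_hash %s", hash)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # biased-pair FES: sum hills, tempered bias -> FES, correct, shift
  full <- grid_from_hills(hills, grid)
  fes_biased <- fes_from_bias(full)
  fes_biased$shift_window <- an$shift_window
  fes_biased <- entropic_correction(fes_biased, temperature = temperature)
  fes_biased <- zero_shift(fes_biased)
  write_fes(fes_biased, file.path(out_dir, "fes.dat"),
            extra_header = stamp)

  # reweighted dist x normal-angle FES with block errors
  w <- reweight_weights(traj, hills, grid, variant = an$reweight_variant)
  rew_axes <- list(
    grid_axis("dist", 0.25, config$metad$dist_max,
              spacing = an$rew_dist_spacing),
    grid_axis("nangle", 0, pi / 2, n = as.integer(an$nangle_bins)))
  fes_rew <- reweight_to_cv(traj, rew_axes, weights = w)
  fes_rew$shift_window <- an$shift_window
  fes_rew <- entropic_correction(fes_rew, temperature = temperature)
  fes_rew <- zero_shift(fes_rew)
  n <- nrow(traj$frames)
  block_sizes <- an$block_sizes
  if (is.null(block_sizes))
    block_sizes <- unique(pmax(2L, floor(n / c(50, 20, 10, 5, 3))))
  be_rew <- convergence_curve(traj, rew_axes, block_sizes, weights = w,
                              temperature = temperature)
  be_bias <- convergence_curve(traj, rew_axes, block_sizes,
                               temperature = temperature)
  fes_rew$stderr <- be_rew$stderr
  write_fes(fes_rew, file.path(out_dir, "fes_reweighted.dat"),
            extra_header = stamp)
  write_block_curve(be_bias, file.path(out_dir, "blockerror.tsv"),
                    reweighted = be_rew,
                    extra_header = sprintf("# config %s", hash))

  binding <- extract_binding(fes_rew, first_shell = an$first_shell,
                             second_shell = an$second_shell,
                             stacked_max = an$stacked_max_deg,
                             tshaped_min = an$tshaped_min_deg)
  jsonlite::write_json(
    list(config_hash = hash, molecule = config$molecule,
         first_shell = binding$first_shell,
         second_shell = binding$second_shell, mode = binding$mode,
         converged_biased = be_bias$converged,
         converged_reweighted = be_rew$converged),
    file.path(out_dir, "binding.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(fes_biased = fes_biased, fes_reweighted = fes_rew,
                 binding = binding, curve_biased = be_bias,
                 curve_reweighted = be_rew, config = config))
}

#' Compare analyzed runs (force-field / parameter comparison table)
#'
#' Reads the reweighted FES of each analyzed run directory, tabulates the
#' first-shell well depths and flags pairs differing by more than kBT.
#' Refuses to compare runs of different molecules.
#'
#' @param run_dirs character vector of analyzed run directories (>= 2).
#' @param labels labels for the table (default: directory basenames).
#' @param out_path optional TSV output path.
#' @return a \code{\link{compare_profiles}} result.
#' @export
pipeline_compare <- function(run_dirs, labels = basename(run_dirs),
                             out_path = NULL) {
  stopifnot(length(run_dirs) >= 2)
  mols <- character(length(run_dirs))
  fess <- list()
  temps <- numeric(length(run_dirs))
  for (i in seq_along(run_dirs)) {
    fp <- file.path(run_dirs[i], "fes_reweighted.dat")
    cp <- file.path(run_dirs[i], "config_resolved.yaml")
    if (!file.exists(fp)) stop("not an analyzed run directory (missing ",
                               "fes_reweighted.dat): ", run_dirs[i])
    config <- read_run_config(cp)
    mols[i] <- if (!is.null(config$molecule$topology))
      config$molecule$topology else paste0("rings", config$molecule$n_rings)
    temps[i] <- config$nonbonded$temperature
    fess[[i]] <- read_fes(fp)
  }
  if (length(unique(mols)) != 1)
    stop("mismatched molecules across runs: ",
         paste(unique(mols), collapse = " vs "))
  names(fess) <- labels
  cmp <- compare_profiles(fess, temperature = temps[1])
  if (!is.null(out_path)) {
    lines <- c(paste(names(cmp$table), collapse = "\t"),
               do.call(sprintf, c(list("%s\t%g\t%g\t%g\t%g"),
                                  unname(cmp$table))),
               "",
               paste(names(cmp$pairs), collapse = "\t"),
               sprintf("%s\t%s\t%g\t%s", cmp$pairs$label_a,
                       cmp$pairs$label_b, cmp$pairs$diff,
                       cmp$pairs$exceeds_kbt))
    writeLines(lines, out_path)
  }
  cmp
}
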