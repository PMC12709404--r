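#' Read and write meshes in ASCII OFF format
#'
#' @param mesh A `tri_mesh` (or `tri_soup` for writing).
#' @param path File path.
#' @return `read_mesh_off` returns a `tri_mesh`; the writers return the
#'   path invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  V <- mesh$positions
  F <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(V), nrow(F)), con)
  writeLines(apply(format(V, digits = 17, scientific = TRUE, trim = TRUE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  V <- matrix(as.numeric(unlist(strsplit(lines[3:(2 + nv)], "\\s+"))),
              nv, 3, byrow = TRUE)
  fl <- strsplit(lines[(3 + nv):(2 + nv + nf)], "\\s+")
  F <- t(vapply(fl, function(x) {
    x <- as.integer(x)
    if (x[1] != 3) stop("only triangle faces are supported")
    x[2:4] + 1L
  }, integer(3)))
  tri_mesh(V, F)
}

#' Read and write meshes in ASCII PLY format
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @param vertex_data Optional named list of per-vertex numeric vectors
#'   written as extra vertex properties (e.g. mean curvature).
#' @return `read_mesh_ply` returns a `tri_mesh`; writers return the path.
#' @export
write_mesh_ply <- function(mesh, path, vertex_data = NULL) {
  V <- mesh$positions
  F <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  extra <- if (is.null(vertex_data)) character(0) else
    sprintf("property double %s", names(vertex_data))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               extra,
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  M <- V
  if (!is.null(vertex_data)) M <- cbind(V, do.call(cbind, vertex_data))
  writeLines(apply(format(M, digits = 17, scientific = TRUE, trim = TRUE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- trimws(readLines(path))
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[1:hdr_end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  V <- t(vapply(strsplit(body[1:nv], "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  F <- t(vapply(strsplit(body[(nv + 1):(nv + nf)], "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3) stop("only triangle faces are supported")
    x[2:4] + 1L
  }, integer(3)))
  tri_mesh(V, F)
}

#' Write filament coordinates as XYZ
#'
#' One molecule block per chain (element tag `C<k>`), compatible with
#' standard molecular viewers.
#'
#' @param fil A `filament_system`.
#' @param path File path.
#' @param comment Second-line comment.
#' @return The path, invisibly.
#' @export
write_filaments_xyz <- function(fil, path, comment = "filament beads") {
  X <- fil$positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(X)), con)
  writeLines(comment, con)
  if (nrow(X) > 0) {
    chain <- rep(seq_len(fil$n_f), each = fil$n_bf)
    writeLines(sprintf("C%d %.10g %.10g %.10g", chain, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_filaments_xyz
#' @param n_f,n_bf Chain layout of the stored beads.
#' @export
read_filaments_xyz <- function(path, n_f, n_bf) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (n == 0) return(filament_system(matrix(0, 0, 3), 0, n_bf))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  X <- t(vapply(rows, function(x) as.numeric(x[2:4]), numeric(3)))
  filament_system(X, n_f, n_bf)
}

#' Export a mesh with per-vertex scalar fields as legacy VTK
#'
#' Writes an ASCII VTK PolyData file with the mesh and any per-vertex
#' scalars (mean curvature, mixed area, virial, ...) as point data, for
#' visualization in ParaView-like tools.
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @param point_data Named list of per-vertex numeric vectors.
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  V <- mesh$positions
  F <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "triangulated vesicle", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(V))), con)
  writeLines(apply(format(V, digits = 17, scientific = TRUE, trim = TRUE), 1,
                   paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(F), 4 * nrow(F)), con)
  writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(V)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(point_data[[nm]], digits = 17, scientific = TRUE,
                        trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Run configuration
#'
#' Assembles the physical target parameters of a run (reduced volume,
#' Peclet number, filament concentration or explicit counts, stiffness
#' ratio, filament length, mesh resolution, duration, cadence, seed) plus
#' any `model_params` overrides, with validation.  Exactly one of `phi`
#' (volume-fraction concentration, in percent) or the pair (`n_f`, `n_bf`)
#' must be given.
#'
#' @param v Target reduced volume in (0, 1].
#' @param Pe Peclet number (>= 0); sets `f_p = Pe k_BT / sigma`.
#' @param phi Filament concentration in percent (alternative to `n_f`).
#' @param n_f,n_bf Explicit chain count / beads per chain.
#' @param chi Stiffness ratio `kappa_f / kappa`.
#' @param L Rescaled filament length; sets `r_0` given `n_bf`.
#' @param subdivisions Icosphere subdivision level of the initial mesh.
#' @param duration Production run length (time units).
#' @param burn_in Deflation ramp time from the sphere to the target `v`.
#' @param sample_every Frame cadence.
#' @param tail_window Averaging window for summary statistics.
#' @param seed Master seed.
#' @param ... Overrides forwarded to [model_params()].
#' @return A classed list `run_config`.
#' @export
run_config <- function(v = 0.25, Pe = 3.75, phi = NULL, n_f = NULL, n_bf = 6,
                       chi = 25, L = 6.12, subdivisions = 3, duration = 50,
                       burn_in = 10, sample_every = 0.01, tail_window = 30,
                       seed = 1L, ...) {
  if (v <= 0 || v > 1) stop("v must lie in (0, 1]")
  if (Pe < 0) stop("Pe must be non-negative")
  if (is.null(phi) == is.null(n_f))
    stop("give exactly one of phi or n_f")
  dots <- list(...)
  base <- do.call(model_params, dots)
  R <- icosphere_radius_for_edge(subdivisions, base$l_0)
  if (is.null(n_f)) {
    n_f <- round((phi / 100) * (2 * R / base$sigma)^3 / n_bf)
    if (n_f < 1) stop("phi too small: no filaments fit this vesicle size")
  }
  r_0 <- if (n_bf >= 2) bond_length_for_L(L, n_bf, base$sigma) else base$r_0
  pars <- utils::modifyList(
    dots, list(f_p = Pe * base$k_BT / base$sigma, kappa_f = chi * base$kappa,
               r_0 = r_0))
  params <- do.call(model_params, pars)
  structure(list(v = v, Pe = Pe, n_f = as.integer(n_f),
                 n_bf = as.integer(n_bf), chi = chi, L = L,
                 subdivisions = as.integer(subdivisions), R = R,
                 duration = duration, burn_in = burn_in,
                 sample_every = sample_every, tail_window = tail_window,
                 seed = as.integer(seed), params = params),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: v = %g, Pe = %g, N_f x N_bf = %d x %d, chi = %g, L = %g\n",
              x$v, x$Pe, x$n_f, x$n_bf, x$chi, x$L))
  cat(sprintf("  mesh: icosphere s = %d (R = %.3g), run %g + %g burn-in, seed %d\n",
              x$subdivisions, x$R, x$duration, x$burn_in, x$seed))
  invisible(x)
}

#' Load / save a run configuration as YAML
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  keep <- config[c("v", "Pe", "n_f", "n_bf", "chi", "L", "subdivisions",
                   "duration", "burn_in", "sample_every", "tail_window",
                   "seed")]
  yaml::write_yaml(keep, path)
  invisible(path)
}

#' Build the initial simulation state of a run
#'
#' Icosphere vesicle sized so the reference edge length equals `l_0`
#' (hence \eqn{A_0 = 4\pi R^2}), with straight filaments rejection-seeded
#' in the interior.  The volume target is not applied here: [simulate_run()]
#' ramps it from the sphere volume to the target over the burn-in, which
#' avoids mesh collapse under a sudden deflation.
#'
#' @param config A `run_config`.
#' @return A list with `state` (a `sim_state`), the `params` with `A_0`
#'   and `V_0` (sphere values) filled in, and `config`.
#' @export
make_initial_state <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(derive_seeds(config$seed)[["init"]])
  mesh <- build_icosphere(config$subdivisions, config$R)
  fil <- seed_filaments(config$n_f, config$n_bf, config$params$r_0,
                        config$R, config$params$sigma)
  params <- config$params
  params$A_0 <- mesh_area(mesh)
  params$V_0 <- mesh_volume(mesh)
  list(state = sim_state(mesh, fil), params = params, config = config)
}

#' Run a configured simulation end to end
#'
#' Burn-in with a linear volume-target ramp from the sphere down to the
#' configured reduced volume, followed by the production run.
#'
#' @param config A `run_config`.
#' @param record_frames Keep per-frame coordinates (needed for junction
#'   analysis).
#' @return A `ves_trajectory` of the production segment, with the burn-in
#'   trajectory attached as attribute `"burn_in"`.
#' @export
simulate_run <- function(config, record_frames = TRUE) {
  init <- make_initial_state(config)
  burn <- sim_run(init$state, init$params, duration = config$burn_in,
                  sample_every = max(config$sample_every, config$burn_in / 50),
                  seed = config$seed,
                  v_ramp = list(v_target = config$v,
                                ramp_time = 0.8 * config$burn_in),
                  record_frames = FALSE)
  params <- init$params
  params$V_0 <- config$v * params$A_0^1.5 / (6 * sqrt(pi))
  prod <- sim_run(burn$state, params, duration = config$duration,
                  sample_every = config$sample_every,
                  seed = config$seed + 1L, record_frames = record_frames)
  attr(prod, "burn_in") <- burn
  attr(prod, "config") <- config
  prod
}

#' Shape and dynamics analysis of a trajectory
#'
#' Adds the shape index and classification per frame, counts tubular
#' junctions on stored frames, derives turnover rates over the tail
#' window, and summarizes the tension estimate.
#'
#' @param traj A `ves_trajectory` with stored frames.
#' @param tail_window Averaging window (time units; default 60\% of the
#'   run).
#' @param junction_stride Analyze every `junction_stride`-th frame for
#'   junctions (skeletonization is the costly step).
#' @param turnover_window Persistence window for event counting, in time
#'   units (default 0.5).
#' @return List of class `shape_analysis`: per-frame data frame `frames`
#'   (t, A, V, v, da, alpha, label, J on analyzed frames), `turnover`
#'   (a `turnover_stats`), `tension` (a `tension_report`), and `summary`
#'   (tail-window means and standard deviations).
#' @export
analyze_trajectory <- function(traj, tail_window = NULL, junction_stride = 10L,
                               turnover_window = 0.5) {
  stopifnot(inherits(traj, "ves_trajectory"))
  obs <- traj$observables
  ref <- reference_asymmetries(pmin(obs$v, 1))
  alpha <- obs$da / ref$da_T
  label <- classify_shape(obs$da, pmin(obs$v, 1))
  J <- rep(NA_integer_, nrow(obs))
  idx <- seq(1, length(traj$frames), by = junction_stride)
  for (i in idx) {
    m <- frame_mesh(traj, i)
    J[i] <- as.integer(count_junctions(m))
  }
  tmax <- max(obs$t)
  if (is.null(tail_window)) tail_window <- 0.6 * (tmax - min(obs$t))
  keep <- obs$t >= tmax - tail_window
  Jt <- J[idx]
  tt <- obs$t[idx]
  frame_dt <- if (length(tt) > 1) diff(tt)[1] else 1
  w <- max(1L, round(turnover_window / frame_dt))
  turn <- turnover_rates(Jt, times = tt, window = w)
  tens <- mean_tension(traj, window = tail_window)
  summ <- list(
    v = mean(obs$v[keep]), v_sd = sd(obs$v[keep]),
    da = mean(obs$da[keep]), da_sd = sd(obs$da[keep]),
    alpha = mean(alpha[keep]), alpha_sd = sd(alpha[keep]),
    J = mean(Jt[tt >= tmax - tail_window], na.rm = TRUE),
    label = names(which.max(table(label[keep]))))
  structure(list(frames = data.frame(obs, alpha = alpha, label = label, J = J),
                 turnover = turn, tension = tens, summary = summ),
            class = "shape_analysis")
}

#' @export
print.shape_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("shape analysis (tail window): v = %.3f +/- %.3f, da = %.3f +/- %.3f\n",
              s$v, s$v_sd, s$da, s$da_sd))
  cat(sprintf("  alpha = %.3f +/- %.3f, dominant label: %s, <J> = %.2f\n",
              s$alpha, s$alpha_sd, s$label, s$J))
  print(x$turnover)
  print(x$tension)
  invisible(x)
}

#' Write per-frame analysis CSV and summary JSON
#'
#' @param analysis A `shape_analysis`.
#' @param csv_path,json_path Output paths (NULL to skip either).
#' @return Invisibly, the summary list written to JSON.
#' @export
write_analysis <- function(analysis, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(analysis$frames, csv_path, row.names = FALSE)
  summary <- c(analysis$summary,
               list(r_e = analysis$turnover$r_e, r_r = analysis$turnover$r_r,
                    r = analysis$turnover$r,
                    emergence_fraction = analysis$turnover$emergence_fraction,
                    lambda_bar = analysis$tension$lambda_bar,
                    lambda_0 = analysis$tension$lambda_0,
                    lambda_ratio = analysis$tension$ratio))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a trajectory bit-identically:
#' configuration, seeds, timestep, cadence and package version.
#'
#' @param traj A `ves_trajectory` produced by [simulate_run()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(traj, path) {
  config <- attr(traj, "config")
  man <- list(
    package_version = as.character(utils::packageVersion("trivesicle")),
    seed = config$seed, derived_seeds = as.list(derive_seeds(config$seed)),
    dt = traj$params$dt, sample_every = config$sample_every,
    time_mapping = "1 s == 1 tau = sigma * sqrt(m / k_BT)",
    config = unclass(write_run_config_list(config)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_run_config_list <- function(config) {
  config[c("v", "Pe", "n_f", "n_bf", "chi", "L", "subdivisions", "duration",
           "burn_in", "sample_every", "tail_window", "seed")]
}
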