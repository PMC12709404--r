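#' Construct a simulation state
#'
#' Bundles the membrane mesh, the filament system, velocities and the
#' current time into the unit advanced by the Langevin integrator and
#' mutated by flip sweeps.
#'
#' @param mesh A `tri_mesh`.
#' @param filaments A `filament_system` (default: none).
#' @param vel_vertices,vel_beads Velocity matrices (default zero).
#' @param time Current simulation time.
#' @return A classed list `sim_state`.
#' @export
sim_state <- function(mesh, filaments = filament_system(matrix(0, 0, 3), 0, 1),
                      vel_vertices = NULL, vel_beads = NULL, time = 0) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(filaments, "filament_system"))
  nv <- mesh$n_vertices
  nb <- nrow(filaments$positions)
  if (is.null(vel_vertices)) vel_vertices <- matrix(0, nv, 3)
  if (is.null(vel_beads)) vel_beads <- matrix(0, nb, 3)
  stopifnot(nrow(vel_vertices) == nv, nrow(vel_beads) == nb)
  structure(list(mesh = mesh, filaments = filaments,
                 vel_vertices = as.matrix(vel_vertices),
                 vel_beads = as.matrix(vel_beads), time = time),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state at t = %.4g: %d vertices, %d filament beads\n",
              x$time, x$mesh$n_vertices, nrow(x$filaments$positions)))
  print(x$mesh)
  invisible(x)
}

# assemble the flat parameter list the compiled run loop expects
cpp_param_list <- function(params, state, v_ramp = NULL) {
  mesh <- state$mesh
  A0 <- if (is.finite(params$A_0)) params$A_0 else mesh_area(mesh)
  V_now <- mesh_volume(mesh)
  V0 <- if (is.finite(params$V_0)) params$V_0 else V_now
  V0_start <- V0
  V0_end <- V0
  ramp_steps <- 0
  if (!is.null(v_ramp)) {
    V0_start <- v_ramp$V0_start
    V0_end <- v_ramp$V0_end
    ramp_steps <- v_ramp$ramp_steps
  }
  list(kappa = params$kappa, k_A = params$k_A, A_0 = A0, k_V = params$k_V,
       V0_start = V0_start, V0_end = V0_end, ramp_steps = as.numeric(ramp_steps),
       k_b = params$k_b, r_rep = params$r_rep, r_att = params$r_att,
       k_bb = params$k_bb, k_bv = params$k_bv, k_vv = params$k_vv,
       sigma = params$sigma, sigma_bv = params$sigma_bv,
       sigma_vv = params$sigma_vv, k_fb = params$k_fb, r_0 = params$r_0,
       kappa_f = params$kappa_f, f_p = params$f_p, gamma = params$gamma,
       m_b = params$m_b, m_v = params$m_v, k_BT = params$k_BT,
       dt = params$dt, tail_drive = params$tail_mode == "drive",
       vv_exclusion = params$vv_exclusion,
       n_f = state$filaments$n_f, n_bf = state$filaments$n_bf,
       fd_h = params$fd_h)
}

#' Advance the system with underdamped Langevin dynamics
#'
#' Integrates the coupled membrane + filament equations of motion with the
#' Gronbech-Jensen/Farago velocity-Verlet scheme (which reduces to plain
#' velocity Verlet at `gamma = 0`, `k_BT = 0`), interleaving Metropolis
#' flip sweeps at frequency `omega` and collecting observables every
#' `sample_every` time units.  Runs are deterministic for a given `seed`:
#' the thermostat, the flip sweeps and any initialization draw from
#' independent streams derived from it.
#'
#' @param state A `sim_state`.
#' @param params A `model_params`.  `A_0`/`V_0` default to the current mesh
#'   values when `NA`.
#' @param duration Simulation time to advance.
#' @param sample_every Observable/frame cadence in time units (default
#'   0.01).
#' @param seed Integer master seed.
#' @param flips Enable flip sweeps (default: `params$omega > 0`).
#' @param v_ramp Optional deflation schedule
#'   `list(v_target =, ramp_time =)`: the volume target is ramped linearly
#'   from the current volume to the volume giving reduced volume
#'   `v_target` over `ramp_time`, then held.
#' @param record_frames Store mesh + bead coordinates per sample (needed
#'   for shape analysis; disable to save memory on long runs).
#' @return A `ves_trajectory`: list with `observables` (data frame: time,
#'   area, volume, reduced volume, asymmetry, energy breakdown, tension
#'   estimate, flip acceptance), `frames`, the final `state`, and the
#'   `params` used.
#' @export
sim_run <- function(state, params, duration, sample_every = 0.01,
                    seed = 1L, flips = params$omega > 0, v_ramp = NULL,
                    record_frames = TRUE) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "model_params"),
            duration >= 0)
  n_steps <- round(duration / params$dt)
  samp <- max(1L, round(sample_every / params$dt))
  flip_every <- 0L
  if (flips && params$omega > 0)
    flip_every <- max(1L, round(1 / (params$omega * params$dt)))
  ramp <- NULL
  A0 <- if (is.finite(params$A_0)) params$A_0 else mesh_area(state$mesh)
  if (!is.null(v_ramp)) {
    V_target <- v_ramp$v_target * A0^1.5 / (6 * sqrt(pi))
    ramp <- list(V0_start = mesh_volume(state$mesh), V0_end = V_target,
                 ramp_steps = round(v_ramp$ramp_time / params$dt))
  }
  plist <- cpp_param_list(params, state, ramp)
  seeds <- derive_seeds(seed)
  out <- cpp_run(state$mesh$positions, state$mesh$triangles,
                 state$filaments$positions, state$vel_vertices,
                 state$vel_beads, plist, n_steps, samp, flip_every,
                 params$q, seeds["thermostat"], seeds["flips"],
                 t0 = state$time, record_frames = record_frames,
                 record_virial = TRUE)
  final_mesh <- tri_mesh(out$vertices, out$triangles)
  final_fil <- filament_system(out$beads, state$filaments$n_f,
                               state$filaments$n_bf)
  final <- sim_state(final_mesh, final_fil, out$vel_vertices, out$vel_beads,
                     out$t_final)
  structure(list(observables = out$observables, frames = out$frames,
                 state = final, params = params,
                 A_0 = plist$A_0, V_0 = plist$V0_end,
                 flips_attempted = out$flips_attempted,
                 flips_accepted = out$flips_accepted, seed = seed),
            class = "ves_trajectory")
}

# independent integer streams for thermostat / flips / initialization,
# derived from one master seed (kept well below 2^31)
derive_seeds <- function(seed) {
  s <- as.integer(seed)
  c(thermostat = (s * 2654435L + 101L) %% 2147480000L,
    flips = (s * 9301L + 49297L) %% 2147480000L,
    init = (s * 69621L + 12345L) %% 2147480000L)
}

#' @export
print.ves_trajectory <- function(x, ...) {
  obs <- x$observables
  n <- nrow(obs)
  cat(sprintf("ves_trajectory: %d samples over t = [%.4g, %.4g]\n",
              n, obs$t[1], obs$t[n]))
  cat(sprintf("  final: A = %.4g, V = %.4g, v = %.4g, da = %.4g\n",
              obs$A[n], obs$V[n], obs$v[n], obs$da[n]))
  if (x$flips_attempted > 0)
    cat(sprintf("  flips: %d accepted / %d attempted (%.1f%%)\n",
                x$flips_accepted, x$flips_attempted,
                100 * x$flips_accepted / x$flips_attempted))
  invisible(x)
}

#' Mesh of a stored trajectory frame
#' @param traj A `ves_trajectory`.
#' @param i Frame index (default last).
#' @return A `tri_mesh`.
#' @export
frame_mesh <- function(traj, i = length(traj$frames)) {
  f <- traj$frames[[i]]
  tri_mesh(f$vertices, f$triangles)
}

#' Single integrator step
#'
#' Convenience wrapper advancing the state by one timestep (no flips, no
#' sampling); mainly for inspection and testing.
#' @inheritParams sim_run
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, params, seed = 1L) {
  traj <- sim_run(state, params, duration = params$dt,
                  sample_every = params$dt, seed = seed, flips = FALSE,
                  record_frames = FALSE)
  traj$state
}
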