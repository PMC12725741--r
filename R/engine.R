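# Langevin integration and experiment protocol.

#' Integrate Langevin dynamics
#'
#' Advances a system with the BAOAB splitting of underdamped Langevin
#' dynamics (velocity-Verlet drift/kick with an exact Ornstein-Uhlenbeck
#' friction/noise step), or with overdamped Euler-Maruyama when
#' `overdamped = TRUE`. Tethered particles are exempt from integration.
#' Thermostat noise is drawn from a dedicated generator seeded with `seed`,
#' so the update is reproducible and independent of R's RNG state.
#'
#' @param state a `bd_system` from [init_system()].
#' @param config an [experiment_config()] supplying dt, gamma, temperature,
#'   kb and kappa.
#' @param nsteps number of steps.
#' @param save_every save a frame every this many steps (0 = none).
#' @param seed seed of the thermostat noise stream.
#' @param overdamped use overdamped Euler-Maruyama instead of BAOAB.
#' @return the advanced `bd_system`; if frames were saved they are attached
#'   as attributes `frames` (n x 3 x nframes), `frame_steps` and `frame_pe`.
#' @export
integrate_system <- function(state, config, nsteps,
                             save_every = 0, seed = config$seed,
                             overdamped = FALSE) {
  stopifnot(inherits(state, "bd_system"),
            inherits(config, "experiment_config"))
  res <- cpp_run_bd(state$positions, state$velocities, state$kind,
                    state$eps_mp, state$eps_pp, state$bonds, state$angles,
                    state$tethered, state$box,
                    config$kb, config$bond_length, config$kappa,
                    config$dt, config$gamma, config$temperature,
                    as.numeric(nsteps), as.numeric(save_every),
                    as.integer(seed), overdamped)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$time <- state$time + nsteps * config$dt
  attr(state, "potential_energy") <- res$potential_energy
  attr(state, "kinetic_energy") <- res$kinetic_energy
  if (save_every > 0) {
    attr(state, "frames") <- res$frames
    attr(state, "frame_steps") <- res$frame_steps
    attr(state, "frame_pe") <- res$frame_pe
  }
  state
}

.new_trajectory <- function(frames, times, state, config, seed,
                            frame_pe = NULL) {
  structure(
    list(
      frames = frames, times = times,
      kind = state$kind, n_monomers = state$n_monomers,
      n_proteins = state$n_proteins,
      bonds = state$bonds, tethered = state$tethered,
      eps_mp = state$eps_mp, eps_pp = state$eps_pp,
      box = state$box, config = config, seed = seed,
      frame_pe = frame_pe
    ),
    class = "bd_trajectory"
  )
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(
    "BD trajectory: %d frames, %d monomers + %d proteins, t in [%g, %g] tau\n",
    dim(x$frames)[3], x$n_monomers, x$n_proteins,
    min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `bd_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as a coordinate matrix
#' @param traj a `bd_trajectory`.
#' @param i frame index.
#' @return n x 3 matrix.
#' @export
frame_coords <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Bond lengths of every frame
#'
#' @param traj a `bd_trajectory`.
#' @return matrix of dimension n_bonds x n_frames (sigma), minimum-image.
#' @export
bond_lengths <- function(traj) {
  stopifnot(inherits(traj, "bd_trajectory"))
  i <- traj$bonds[, 1] + 1L
  j <- traj$bonds[, 2] + 1L
  box <- traj$box
  nf <- n_frames(traj)
  out <- matrix(NA_real_, length(i), nf)
  for (f in seq_len(nf)) {
    p <- traj$frames[, , f]
    dx <- .min_image(p[i, 1] - p[j, 1], box[1])
    dy <- .min_image(p[i, 2] - p[j, 2], box[2])
    dz <- .min_image(p[i, 3] - p[j, 3], box[3])
    out[, f] <- sqrt(dx^2 + dy^2 + dz^2)
  }
  out
}

# largest DBSCAN cluster size, used as an equilibration diagnostic
.largest_cluster <- function(positions, box, eps = 1.2, min_pts = 6L) {
  if (nrow(positions) < min_pts) return(0L)
  labels <- cpp_dbscan(positions, eps, min_pts, box)
  if (all(labels == 0L)) 0L else max(tabulate(labels[labels > 0L]))
}

#' Equilibrate a system with a plateau criterion
#'
#' Runs the equilibration budget in 10 equal windows and stops early once
#' both the window-averaged potential energy and the largest-cluster size
#' change by less than `tol` (relative) across two consecutive windows.
#'
#' @param state a `bd_system`.
#' @param config an [experiment_config()].
#' @param budget total step budget (default `config$equil_steps`).
#' @param seed base seed; window w uses `seed + w` for its noise stream.
#' @param tol relative plateau tolerance (default 0.02).
#' @param verbose print per-window diagnostics.
#' @return the equilibrated `bd_system` with attribute `equil_log`, a data
#'   frame of per-window steps, potential energy and largest cluster size.
#' @export
equilibrate_system <- function(state, config, budget = config$equil_steps,
                               seed = config$seed, tol = 0.02,
                               verbose = FALSE) {
  chunk <- ceiling(budget / 10)
  pe <- numeric(0)
  clus <- numeric(0)
  plateau_runs <- 0L
  for (w in seq_len(10L)) {
    state <- integrate_system(state, config, chunk,
                              seed = seed + w)
    pe[w] <- attr(state, "potential_energy")
    clus[w] <- .largest_cluster(state$positions, state$box)
    if (verbose)
      message(sprintf("equil window %d: PE=%.2f, largest cluster=%d",
                      w, pe[w], clus[w]))
    if (w >= 2L) {
      dpe <- abs(pe[w] - pe[w - 1]) / max(abs(pe[w - 1]), 1e-9)
      dcl <- abs(clus[w] - clus[w - 1]) / max(clus[w - 1], 1)
      plateau_runs <- if (dpe < tol && dcl < tol) plateau_runs + 1L else 0L
      if (plateau_runs >= 2L) break
    }
  }
  attr(state, "equil_log") <- data.frame(
    window = seq_along(pe), steps = chunk * seq_along(pe),
    potential_energy = pe, largest_cluster = clus)
  state
}

#' Run a complete co-condensation experiment
#'
#' Protocol: (1) equilibrate the bare DNA chain (no proteins) from the
#' initial tent path; (2) insert proteins and equilibrate with the plateau
#' criterion of [equilibrate_system()]; (3) run production and save
#' `config$n_frames` frames. With `equilibrate = FALSE` production starts
#' right after protein insertion, which is the mode used to observe
#' coarsening kinetics from nucleation onwards.
#'
#' @param config an [experiment_config()].
#' @param profile an [affinity_profile]; defaults to the profile named by
#'   `config$model`.
#' @param seed replicate seed (defaults to `config$seed`); the DNA
#'   equilibration, protein placement and thermostat streams are derived
#'   from it.
#' @param dna_state optional pre-equilibrated bare-DNA `bd_system` (as used
#'   by the replicate protocol: several uncorrelated DNA configurations
#'   feeding protein runs).
#' @param dna_equil_steps steps of bare-DNA pre-equilibration when
#'   `dna_state` is not supplied.
#' @param equilibrate run the protein-phase equilibration before production.
#' @param verbose print phase diagnostics.
#' @return a `bd_trajectory` of the production phase.
#' @export
run_experiment <- function(config, profile = NULL, seed = config$seed,
                           dna_state = NULL,
                           dna_equil_steps = max(2e4, config$equil_steps / 10),
                           equilibrate = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(profile)) profile <- profile_for_config(config)
  if (is.null(dna_state)) {
    dna_state <- equilibrate_dna(config, profile, seed = seed,
                                 nsteps = dna_equil_steps)
  }
  state <- add_proteins(dna_state, config, profile, seed = seed + 500L)
  if (verbose) message("proteins inserted: n = ", state$n_proteins)
  if (equilibrate) {
    state <- equilibrate_system(state, config, seed = seed + 1000L,
                                verbose = verbose)
  }
  state <- integrate_system(state, config, config$prod_steps,
                            save_every = config$save_every,
                            seed = seed + 2000L)
  frames <- attr(state, "frames")
  times <- attr(state, "frame_steps") * config$dt
  .new_trajectory(frames, times, state, config, seed,
                  frame_pe = attr(state, "frame_pe"))
}

#' Equilibrate a bare DNA chain
#'
#' Produces an uncorrelated tethered-DNA configuration to seed protein
#' runs, mirroring the replicate protocol in which several independent
#' DNA-only equilibrations feed the runs with proteins.
#'
#' @inheritParams run_experiment
#' @param nsteps equilibration steps.
#' @param tether tether the chain ends (default) or leave the chain free.
#' @return a protein-free `bd_system`.
#' @export
equilibrate_dna <- function(config, profile = NULL, seed = config$seed,
                            nsteps = 2e4, tether = TRUE) {
  if (is.null(profile)) profile <- profile_for_config(config)
  state <- init_system(config, profile, seed = seed, tether = tether,
                       with_proteins = FALSE)
  integrate_system(state, config, nsteps, seed = seed + 100L)
}

#' Insert proteins into an equilibrated DNA system
#'
#' @param dna_state a protein-free `bd_system`.
#' @param config an [experiment_config()] (supplies the protein count).
#' @param profile an [affinity_profile].
#' @param seed seed of the placement stream.
#' @return a `bd_system` with proteins added (overlap-rejected placement,
#'   minimum distance 0.9 sigma).
#' @export
add_proteins <- function(dna_state, config, profile, seed) {
  stopifnot(inherits(dna_state, "bd_system"), dna_state$n_proteins == 0L)
  np <- config$n_proteins
  if (np == 0L) return(dna_state)
  box <- dna_state$box
  set.seed(seed)
  pos_p <- matrix(NA_real_, np, 3L)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * np
  pos_all <- dna_state$positions
  while (placed < np) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", np, " proteins without overlap: box too dense")
    cand <- stats::runif(3) * box
    d2 <- .min_image(pos_all[, 1] - cand[1], box[1])^2 +
          .min_image(pos_all[, 2] - cand[2], box[2])^2 +
          .min_image(pos_all[, 3] - cand[3], box[3])^2
    if (min(d2) >= 0.81) {
      placed <- placed + 1L
      pos_p[placed, ] <- cand
      pos_all <- rbind(pos_all, cand)
    }
  }
  state <- dna_state
  state$positions <- rbind(dna_state$positions, pos_p)
  state$velocities <- rbind(
    dna_state$velocities,
    matrix(stats::rnorm(3L * np, sd = sqrt(config$temperature)), ncol = 3L))
  state$kind <- c(dna_state$kind, rep(-1L, np))
  state$n_proteins <- np
  state$eps_pp <- config$eps_pp
  state$eps_mp <- profile$affinities
  state
}

#' Run a bare-chain reference trajectory
#'
#' Convenience wrapper producing the protein-free trajectories needed by the
#' force pipeline (tethered baseline and free-ends baseline) and by the
#' persistence-length estimator.
#'
#' @param config an [experiment_config()].
#' @param tether tether the ends (`TRUE`) or run a free chain (`FALSE`).
#' @param nsteps production steps (default `config$prod_steps`).
#' @param nframes saved frames.
#' @param equil_steps pre-equilibration steps.
#' @param seed seed.
#' @return a `bd_trajectory` without proteins.
#' @export
run_bare_chain <- function(config, tether = TRUE,
                           nsteps = config$prod_steps,
                           nframes = config$n_frames,
                           equil_steps = max(2e4, nsteps / 10),
                           seed = config$seed) {
  profile <- profile_for_config(config)
  state <- init_system(config, profile, seed = seed, tether = tether,
                       with_proteins = FALSE)
  state <- integrate_system(state, config, equil_steps, seed = seed + 100L)
  save_every <- max(1, floor(nsteps / nframes))
  nsteps <- save_every * nframes
  state <- integrate_system(state, config, nsteps,
                            save_every = save_every, seed = seed + 200L)
  .new_trajectory(attr(state, "frames"),
                  attr(state, "frame_steps") * config$dt,
                  state, config, seed, attr(state, "frame_pe"))
}
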