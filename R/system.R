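# System construction: tethered semiflexible chain + protein beads.

.min_image <- function(d, L) d - L * round(d / L)

#' Initialize a particle system
#'
#' Places the DNA chain between two tether anchors on the box long axis
#' (z), symmetric about the box center and separated by `Re = re_prime * s`.
#' The chain is laid out as a helix of exact unit steps between the
#' anchors: each bond advances `Re/(Nm-1)` along z and rotates its
#' transverse component through a whole number of turns, chosen so the
#' helix radius stays below a quarter of the box cross-section. This takes
#' up arbitrary slack without ever leaving the box or crossing itself; a
#' small Gaussian perturbation (0.05 sigma) breaks residual symmetry.
#' Proteins are inserted uniformly at random with
#' overlap rejection (minimum distance 0.9 sigma to every placed particle).
#' Velocities are Maxwell-Boltzmann at the configured temperature; tethered
#' particles start at rest and never move.
#'
#' @param config an [experiment_config()].
#' @param profile an [affinity_profile] with `config$n_monomers` monomers.
#' @param seed integer seed; the same seed reproduces the system exactly.
#' @param tether if `FALSE`, build an untethered chain (straight along z
#'   through the box center) for free-chain reference runs.
#' @param with_proteins if `FALSE`, no proteins are placed (bare-DNA runs).
#' @return object of class `bd_system`: positions/velocities (n x 3),
#'   `kind` (0-based monomer index, -1 for proteins), bond/angle lists
#'   (0-based), tethered indices (0-based), box, eps_mp, time.
#' @export
init_system <- function(config, profile, seed = config$seed,
                        tether = TRUE, with_proteins = TRUE) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(profile, "affinity_profile"))
  nm <- config$n_monomers
  if (profile$n_monomers != nm)
    stop("profile has ", profile$n_monomers, " monomers, config expects ",
         nm)
  box <- config$box
  np <- if (with_proteins) config$n_proteins else 0L
  s <- config$s
  set.seed(seed)

  center <- box / 2
  if (tether) {
    re <- config$re
    a1 <- c(center[1], center[2], center[3] - re / 2)
    nb <- nm - 1L
    dz <- re / nb                       # per-bond advance along z
    lat <- sqrt(max(0, config$bond_length^2 - dz^2))
    if (lat > 1e-9) {
      # whole number of turns returns the transverse component to the
      # axis at the far anchor; radius target min(5, box/4)
      r_target <- min(5, min(box[1:2]) / 4)
      turns <- max(1, round(lat * nb / (2 * pi * r_target)))
      phi0 <- stats::runif(1, 0, 2 * pi)
      phi <- phi0 + 2 * pi * turns * (seq_len(nb) - 0.5) / nb
      steps <- unname(cbind(lat * cos(phi), lat * sin(phi), rep(dz, nb)))
    } else {
      steps <- cbind(0, 0, rep(dz, nb))
    }
    pos_m <- rbind(a1, sweep(apply(steps, 2L, cumsum), 2L, a1, "+"),
                   deparse.level = 0)
    # close tiny transverse residue so the last bead sits on the anchor
    resid <- c(center[1], center[2], center[3] + re / 2) - pos_m[nm, ]
    pos_m <- pos_m + outer((seq_len(nm) - 1) / nb, resid)
    noise <- matrix(stats::rnorm(3L * nm, sd = 0.05), ncol = 3L)
    noise[c(1L, nm), ] <- 0
    pos_m <- pos_m + noise
    tethered <- c(0L, nm - 1L)
  } else {
    z0 <- center[3] - s / 2
    pos_m <- cbind(center[1], center[2],
                   z0 + (seq_len(nm) - 1) * config$bond_length)
    pos_m <- pos_m + cbind(stats::rnorm(nm, sd = 0.05),
                           stats::rnorm(nm, sd = 0.05), 0)
    tethered <- integer(0)
  }

  pos <- pos_m
  if (np > 0L) {
    pos_p <- matrix(NA_real_, np, 3L)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * np
    while (placed < np) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", np, " proteins without overlap after ",
             max_attempts, " attempts: box too dense")
      cand <- stats::runif(3) * box
      all_pos <- rbind(pos, pos_p[seq_len(placed), , drop = FALSE])
      d <- sqrt(.min_image(all_pos[, 1] - cand[1], box[1])^2 +
                .min_image(all_pos[, 2] - cand[2], box[2])^2 +
                .min_image(all_pos[, 3] - cand[3], box[3])^2)
      if (min(d) >= 0.9) {
        placed <- placed + 1L
        pos_p[placed, ] <- cand
      }
    }
    pos <- rbind(pos, pos_p)
  }

  n <- nm + np
  vel <- matrix(stats::rnorm(3L * n, sd = sqrt(config$temperature)),
                ncol = 3L)
  vel[tethered + 1L, ] <- 0

  bonds <- cbind(0L:(nm - 2L), 1L:(nm - 1L))
  angles <- if (nm >= 3L) cbind(0L:(nm - 3L), 1L:(nm - 2L), 2L:(nm - 1L))
            else matrix(integer(0), 0L, 3L)

  structure(
    list(
      positions = pos, velocities = vel,
      kind = c(0L:(nm - 1L), rep(-1L, np)),
      eps_mp = profile$affinities,
      eps_pp = config$eps_pp,
      bonds = bonds, angles = angles, tethered = tethered,
      box = box, n_monomers = nm, n_proteins = np,
      time = 0
    ),
    class = "bd_system"
  )
}

#' @export
print.bd_system <- function(x, ...) {
  cat(sprintf(
    "BD system: %d monomers + %d proteins, box (%g, %g, %g) sigma, t=%g tau\n",
    x$n_monomers, x$n_proteins, x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Pairwise nonbonded interaction energy
#'
#' Attractive pairs (protein-protein and monomer-protein) interact through a
#' 12-6 Lennard-Jones potential of well depth `eps`, truncated at 2.5 sigma
#' and shifted so the energy vanishes at the cutoff. Repulsive pairs
#' (monomer-monomer) use the WCA form: the same potential with `eps = 1`,
#' truncated at its minimum 2^(1/6) sigma and shifted. Attractive pairs with
#' `eps <= 0` do not interact.
#'
#' @param r distance in sigma (vectorized, must be > 0).
#' @param kind `"attractive"` or `"repulsive"`.
#' @param eps well depth in kBT (ignored for repulsive pairs).
#' @return energy in kBT.
#' @export
pair_energy <- function(r, kind = c("attractive", "repulsive"), eps = 1) {
  kind <- match.arg(kind)
  if (any(r <= 0)) stop("pair distance must be positive")
  rc <- if (kind == "repulsive") 2^(1 / 6) else 2.5
  e <- if (kind == "repulsive") 1 else eps
  if (e <= 0) return(rep(0, length(r)))
  shift <- 4 * e * (rc^-12 - rc^-6)
  out <- ifelse(r < rc, 4 * e * (r^-12 - r^-6) - shift, 0)
  out
}

#' Bonded energy and forces of a system state
#'
#' Harmonic bonds `0.5 * kb * (l - l0)^2` plus bending
#' `kappa * (1 - cos theta)` over consecutive bond pairs. Forces are exact
#' negative gradients (evaluated by the compiled kernel with all nonbonded
#' terms switched off).
#'
#' @param state a `bd_system`.
#' @param kb bond constant (kBT/sigma^2).
#' @param kappa bending constant (kBT).
#' @param l0 bond rest length (sigma).
#' @return list with `energy` (kBT) and `forces` (n x 3, kBT/sigma).
#' @export
bonded_energy_forces <- function(state, kb = 100, kappa = 15, l0 = 1) {
  stopifnot(inherits(state, "bd_system"))
  n <- nrow(state$positions)
  cpp_forces_energy(state$positions,
                    kind = rep(-1L, n),          # all "protein": no MM WCA
                    eps_mp = numeric(max(1L, n)), eps_pp = 0,
                    bonds = state$bonds, angles = state$angles,
                    box = state$box, kb = kb, l0 = l0, kappa = kappa)
}

#' Total potential energy and forces of a system state
#'
#' Full force field: nonbonded LJ/WCA pairs (with 1-2 exclusion), harmonic
#' bonds, and bending terms.
#'
#' @param state a `bd_system`.
#' @param kb,kappa,l0 bonded parameters.
#' @return list with `energy` and `forces`.
#' @export
system_energy_forces <- function(state, kb = 100, kappa = 15, l0 = 1) {
  stopifnot(inherits(state, "bd_system"))
  cpp_forces_energy(state$positions, kind = state$kind,
                    eps_mp = state$eps_mp, eps_pp = state$eps_pp,
                    bonds = state$bonds, angles = state$angles,
                    box = state$box, kb = kb, l0 = l0, kappa = kappa)
}
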