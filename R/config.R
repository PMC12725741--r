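#' Experiment configuration
#'
#' Bundles every parameter of a tethered-DNA co-condensation run in reduced
#' units (energy kBT = 1, length sigma = 1, mass m = 1, time
#' tau = sigma*sqrt(m/kBT)). Defaults follow the reference study conditions:
#' a 500-monomer chain (5 kb at 10 bp per monomer) in an 80 x 80 x 600 sigma
#' box, Langevin thermostat at T = 1 kBT with damping 0.1 / tau, time step
#' 0.01 tau, harmonic bonds (kb = 100 kBT/sigma^2, rest length 1 sigma) and
#' a bending stiffness of 15 kBT giving a persistence length of 15 monomers
#' (150 bp).
#'
#' The tether separation is `Re = re_prime * s` with contour length
#' `s = (n_monomers - 1) * sigma`. The protein count is derived from the
#' micromolar bulk concentration `rho_uM` and the box volume via
#' [concentration_to_count()] unless `n_proteins` is given explicitly.
#'
#' @param model DNA model name: `"homogeneous"`, `"het1"`, `"het2"` or
#'   `"sequence_mapped"`.
#' @param n_monomers chain length in monomers.
#' @param box numeric length-3, box dimensions in sigma (x, y, z); the chain
#'   is tethered along z.
#' @param re_prime normalized end-to-end distance in (0, 1].
#' @param rho_uM bulk protein concentration in micromolar.
#' @param n_proteins optional explicit protein count (overrides `rho_uM`).
#' @param eps_pp protein-protein attraction strength (kBT).
#' @param temperature thermostat temperature (kBT).
#' @param gamma Langevin damping coefficient (1/tau).
#' @param dt integration time step (tau).
#' @param kb harmonic bond constant (kBT/sigma^2).
#' @param kappa bending constant (kBT); the persistence length in monomers
#'   approximately equals kappa/kBT.
#' @param equil_steps equilibration step budget.
#' @param prod_steps production steps.
#' @param n_frames number of saved frames; `prod_steps` must be a multiple.
#' @param sigma_nm physical bead diameter in nm (for muM and pN conversion).
#' @param seed integer random seed for the run.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(model = "homogeneous",
                              n_monomers = 500L,
                              box = c(80, 80, 600),
                              re_prime = 0.6,
                              rho_uM = 84.5,
                              n_proteins = NULL,
                              eps_pp = 2.0,
                              temperature = 1.0,
                              gamma = 0.1,
                              dt = 0.01,
                              kb = 100,
                              kappa = 15,
                              equil_steps = 1e6,
                              prod_steps = 1.5e7,
                              n_frames = 3000L,
                              sigma_nm = 3.4,
                              seed = 1L) {
  model <- match.arg(model,
                     c("homogeneous", "het1", "het2", "sequence_mapped"))
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 3L) stop("n_monomers must be >= 3")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (sigma)")
  if (!is.finite(re_prime) || re_prime <= 0 || re_prime > 1)
    stop("re_prime must lie in (0, 1]")
  s <- n_monomers - 1
  re <- re_prime * s
  if (re > box[3L])
    stop("tether separation Re = ", signif(re, 4),
         " sigma exceeds the box long axis (", box[3L], " sigma)")
  if (is.null(n_proteins)) {
    if (!is.finite(rho_uM) || rho_uM < 0) stop("rho_uM must be >= 0")
    n_proteins <- concentration_to_count(rho_uM, box, sigma_nm)
  } else {
    n_proteins <- as.integer(n_proteins)
    if (n_proteins < 0L) stop("n_proteins must be >= 0")
    rho_uM <- count_to_concentration(n_proteins, box, sigma_nm)
  }
  if (dt <= 0) stop("dt must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (temperature < 0) stop("temperature must be >= 0")
  if (kb <= 0 || kappa < 0) stop("kb must be > 0 and kappa >= 0")
  prod_steps <- as.numeric(prod_steps)
  equil_steps <- as.numeric(equil_steps)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (prod_steps %% n_frames != 0)
    stop("n_frames (", n_frames, ") must divide prod_steps (", prod_steps,
         ")")
  structure(
    list(
      model = model, n_monomers = n_monomers, box = as.numeric(box),
      re_prime = re_prime, re = re, s = s,
      rho_uM = rho_uM, n_proteins = n_proteins,
      eps_pp = eps_pp, temperature = temperature, gamma = gamma, dt = dt,
      kb = kb, kappa = kappa, bond_length = 1.0,
      equil_steps = equil_steps, prod_steps = prod_steps,
      n_frames = n_frames, save_every = prod_steps / n_frames,
      sigma_nm = sigma_nm, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config: %s DNA, Nm=%d, box=(%g, %g, %g) sigma\n",
              x$model, x$n_monomers, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  Re'=%.2f (Re=%.1f sigma), rho_p=%.2f uM (Np=%d), eps_pp=%.2f kBT\n",
              x$re_prime, x$re, x$rho_uM, x$n_proteins, x$eps_pp))
  cat(sprintf("  T=%g kBT, gamma=%g/tau, dt=%g tau, kb=%g, kappa=%g\n",
              x$temperature, x$gamma, x$dt, x$kb, x$kappa))
  cat(sprintf("  equil<=%g steps, production %g steps -> %d frames (every %g)\n",
              x$equil_steps, x$prod_steps, x$n_frames, x$save_every))
  invisible(x)
}

#' Desk-scale configuration preset
#'
#' Shrinks the reference system proportionally so that an experiment runs in
#' minutes on a single core: the chain is shortened (default 100 monomers),
#' the box cross-section is reduced to 20 x 20 sigma with the long axis
#' scaled to the chain (at least 1.25 x the contour length), and step counts
#' are cut while keeping the same concentration-to-count conversion. Block
#' layouts of the DNA models scale proportionally with the chain
#' (see [build_block_profile()]).
#'
#' @inheritParams experiment_config
#' @param ... further overrides passed to [experiment_config()].
#' @return object of class `experiment_config`.
#' @export
scaled_config <- function(model = "homogeneous",
                          n_monomers = 100L,
                          re_prime = 0.6,
                          rho_uM = 84.5,
                          equil_steps = 4e5,
                          prod_steps = 6e5,
                          n_frames = 300L,
                          seed = 1L, ...) {
  n_monomers <- as.integer(n_monomers)
  s <- n_monomers - 1
  long_axis <- max(ceiling(1.25 * s), 600 * n_monomers / 500)
  experiment_config(model = model, n_monomers = n_monomers,
                    box = c(20, 20, long_axis),
                    re_prime = re_prime, rho_uM = rho_uM,
                    equil_steps = equil_steps, prod_steps = prod_steps,
                    n_frames = n_frames, seed = seed, ...)
}

#' Build the affinity profile named by a configuration
#'
#' @param config an [experiment_config()].
#' @param dna_sequence required when `config$model == "sequence_mapped"`.
#' @return an [affinity_profile].
#' @export
profile_for_config <- function(config, dna_sequence = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$model == "sequence_mapped") {
    if (is.null(dna_sequence))
      stop("sequence_mapped model needs a dna_sequence")
    prof <- sequence_to_profile(dna_sequence)
    if (prof$n_monomers != config$n_monomers)
      stop("sequence yields ", prof$n_monomers, " monomers but config says ",
           config$n_monomers)
    prof
  } else {
    build_block_profile(config$model, config$n_monomers)
  }
}

# --- YAML config files -----------------------------------------------------

.config_keys <- c("model", "n_monomers", "box", "re_prime", "rho_uM",
                  "n_proteins", "eps_pp", "temperature", "gamma", "dt",
                  "kb", "kappa", "equil_steps", "prod_steps", "n_frames",
                  "sigma_nm", "seed")

#' Parse a YAML experiment configuration
#'
#' Reads a key/value YAML file, validates keys against the known parameter
#' set and resolves defaults through [experiment_config()]. Unknown keys
#' raise a named error.
#'
#' @param path YAML file.
#' @return object of class `experiment_config`.
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Write a configuration back to YAML
#'
#' Emits only the canonical parameter keys, so that
#' `parse_config(write_config(cfg, f))` round-trips.
#'
#' @param config an [experiment_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  keep <- config[intersect(.config_keys, names(config))]
  keep$n_proteins <- NULL  # derived from rho_uM and the box on re-parse
  yaml::write_yaml(keep, path)
  invisible(path)
}

#' Conversion constant: 1 kBT/sigma in piconewtons
#'
#' Uses kBT = 4.11 pN nm (room temperature) and sigma = 3.4 nm, giving
#' 4.11/3.4 = 1.2088 pN per kBT/sigma.
#'
#' @param sigma_nm bead diameter in nm.
#' @param kBT_pN_nm thermal energy in pN nm.
#' @return pN per (kBT/sigma).
#' @export
kbt_per_sigma_in_pN <- function(sigma_nm = 3.4, kBT_pN_nm = 4.11) {
  kBT_pN_nm / sigma_nm
}
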