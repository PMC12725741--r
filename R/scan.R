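# Experiment scans over tether extension and protein concentration with
# replicate orchestration.

#' Scan specification
#'
#' Defines a grid experiment: for every grid point, `n_replicates`
#' protein runs are started from independently seeded bare-DNA
#' equilibrations, condensates are detected, and the capillary force,
#' condensate count, volumes and interfacial affinity are aggregated as
#' mean +/- sd over replicates.
#'
#' @param base_config an [experiment_config()] supplying everything not
#'   scanned.
#' @param re_prime_grid numeric grid of normalized extensions (NULL = keep
#'   the base value).
#' @param rho_grid numeric grid of protein concentrations in micromolar
#'   (NULL = keep the base value).
#' @param n_replicates replicates per grid point (default 5).
#' @param params a [detection_params()].
#' @param dna_sequence sequence for the sequence-mapped model.
#' @return object of class `scan_spec`.
#' @export
scan_spec <- function(base_config, re_prime_grid = NULL, rho_grid = NULL,
                      n_replicates = 5L, params = detection_params(),
                      dna_sequence = NULL) {
  stopifnot(inherits(base_config, "experiment_config"))
  if (is.null(re_prime_grid)) re_prime_grid <- base_config$re_prime
  if (is.null(rho_grid)) rho_grid <- base_config$rho_uM
  if (length(re_prime_grid) == 0L || length(rho_grid) == 0L)
    stop("grids must be non-empty")
  structure(list(base_config = base_config,
                 re_prime_grid = sort(unique(re_prime_grid)),
                 rho_grid = sort(unique(rho_grid)),
                 n_replicates = as.integer(n_replicates),
                 params = params, dna_sequence = dna_sequence),
            class = "scan_spec")
}

.config_at <- function(spec, re_prime, rho, seed) {
  cfg <- spec$base_config
  experiment_config(model = cfg$model, n_monomers = cfg$n_monomers,
                    box = cfg$box, re_prime = re_prime, rho_uM = rho,
                    eps_pp = cfg$eps_pp, temperature = cfg$temperature,
                    gamma = cfg$gamma, dt = cfg$dt, kb = cfg$kb,
                    kappa = cfg$kappa, equil_steps = cfg$equil_steps,
                    prod_steps = cfg$prod_steps, n_frames = cfg$n_frames,
                    sigma_nm = cfg$sigma_nm, seed = seed)
}

#' Run a grid scan
#'
#' For each (Re', rho_p) grid point: a bare tethered reference run and
#' `n_replicates` protein runs from independently seeded DNA
#' configurations; the free-ends bare reference is shared across the grid.
#' Per replicate the capillary force ([capillary_force()]), equilibrium
#' condensate count, total condensate volume and average interfacial
#' affinity ([interfacial_affinity()]) are recorded. Failed replicates are
#' logged, excluded, and mark the grid point incomplete.
#'
#' @param spec a [scan_spec()].
#' @param seed master seed; replicate r at grid point g uses
#'   `seed + 1000 * g + r`.
#' @param verbose print progress.
#' @return list with `replicates` (per-replicate rows) and `summary`
#'   (per-grid-point mean +/- sd), both data frames carrying the base
#'   config seed and package version as provenance attributes.
#' @export
run_scan <- function(spec, seed = spec$base_config$seed, verbose = FALSE) {
  stopifnot(inherits(spec, "scan_spec"))
  base <- spec$base_config
  profile_for <- function(cfg) profile_for_config(cfg, spec$dna_sequence)

  # shared free-ends baseline
  cfg0 <- .config_at(spec, base$re_prime, base$rho_uM, seed)
  free_traj <- run_bare_chain(cfg0, tether = FALSE, seed = seed + 11L)
  l0_bar <- .mean_bond_length(bond_lengths(free_traj))

  rows <- list()
  g <- 0L
  for (re in spec$re_prime_grid) {
    for (rho in spec$rho_grid) {
      g <- g + 1L
      cfg <- .config_at(spec, re, rho, seed + 1000L * g)
      bare <- run_bare_chain(cfg, tether = TRUE, seed = seed + 1000L * g)
      for (r in seq_len(spec$n_replicates)) {
        rseed <- seed + 1000L * g + r
        row <- tryCatch({
          traj <- run_experiment(cfg, profile_for(cfg), seed = rseed)
          det <- detect_trajectory(traj, spec$params)
          fr <- capillary_force(traj, det, bare, l0_bar = l0_bar,
                                kb = cfg$kb)
          ncond <- count_equilibrium_condensates(det, spec$params)
          occ <- occupancy(det)
          ia <- tryCatch(
            interfacial_affinity(occ, profile_for(cfg))$ia_average,
            error = function(e) NA_real_)
          vol <- if (nrow(det$table) > 0L) {
            last <- det$table[det$table$frame == max(det$table$frame), ]
            sum(last$volume)
          } else NA_real_
          data.frame(re_prime = re, rho_uM = rho, replicate = r,
                     seed = rseed, f = fr$f, f_pN = fr$f_pN,
                     f_dna = fr$f_dna, f_dna_protein = fr$f_dna_protein,
                     n_condensates = ncond, volume = vol, ia = ia,
                     ok = TRUE)
        }, error = function(e) {
          warning(sprintf("replicate %d at Re'=%g rho=%g failed: %s",
                          r, re, rho, conditionMessage(e)))
          data.frame(re_prime = re, rho_uM = rho, replicate = r,
                     seed = rseed, f = NA_real_, f_pN = NA_real_,
                     f_dna = NA_real_, f_dna_protein = NA_real_,
                     n_condensates = NA_integer_, volume = NA_real_,
                     ia = NA_real_, ok = FALSE)
        })
        rows[[length(rows) + 1L]] <- row
        if (verbose)
          message(sprintf("Re'=%.2f rho=%.2f rep %d: F=%.3f kBT/sigma, %s",
                          re, rho, r, row$f,
                          if (row$ok) paste0(row$n_condensates,
                                             " condensate(s)") else
                            "FAILED"))
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(
    cbind(f, f_pN, n_condensates, volume, ia) ~ re_prime + rho_uM,
    data = reps[reps$ok, ], FUN = mean, na.action = stats::na.pass)
  sds <- stats::aggregate(
    cbind(f, f_pN) ~ re_prime + rho_uM,
    data = reps[reps$ok, ], FUN = stats::sd, na.action = stats::na.pass)
  names(sds)[3:4] <- c("f_sd", "f_pN_sd")
  summary <- merge(agg, sds, by = c("re_prime", "rho_uM"))
  inc <- stats::aggregate(ok ~ re_prime + rho_uM, data = reps,
                          FUN = function(x) sum(!x))
  names(inc)[3] <- "n_failed"
  summary <- merge(summary, inc, by = c("re_prime", "rho_uM"))
  prov <- list(seed = seed,
               version = as.character(utils::packageVersion("cocondense")))
  attr(reps, "provenance") <- prov
  attr(summary, "provenance") <- prov
  list(replicates = reps, summary = summary, l0_bar = l0_bar)
}

#' Locate the sharp force increase along an extension scan
#'
#' Finds the grid interval with the largest increase of the mean capillary
#' force and reports its midpoint: the switch-point estimate of the
#' force-extension curve.
#'
#' @param summary the `summary` data frame of [run_scan()] for a single
#'   concentration.
#' @return list with `re_switch` (interval midpoint), `jump` (force
#'   increase across the interval, kBT/sigma) and the interval endpoints.
#' @export
force_switch_point <- function(summary) {
  s <- summary[order(summary$re_prime), ]
  if (nrow(s) < 2L) stop("need at least two grid points")
  dif <- diff(s$f)
  i <- which.max(dif)
  list(re_switch = (s$re_prime[i] + s$re_prime[i + 1L]) / 2,
       jump = dif[i],
       interval = c(s$re_prime[i], s$re_prime[i + 1L]))
}
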