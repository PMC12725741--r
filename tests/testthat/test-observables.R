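test_that("occupancy is the exact frame fraction inside condensates", {
  m <- make_membership_series(function(mono, fr) as.integer(fr %% 2 == 0),
                              n_monomers = 5L, omega_c = 3000L)
  occ <- occupancy(m)
  expect_equal(occ$p_m, rep(0.5, 5))
  expect_equal(occ$omega_c, 3000L)
  # always inside -> 1; 1500 of 3000 -> 0.5
  m2 <- rbind(rep(1L, 3000), c(rep(1L, 1500), rep(0L, 1500)))
  expect_equal(occupancy(m2)$p_m, c(1, 0.5))
  expect_error(occupancy(matrix(integer(0), 2, 0)), "no frames")
  expect_error(occupancy(matrix(2L, 2, 3)), "0 or 1")
})

test_that("occupancy conserves the total count of inside events", {
  set.seed(1)
  m <- matrix(rbinom(50 * 40, 1, 0.3), 50, 40)
  occ <- occupancy(m)
  expect_equal(sum(occ$p_m) * occ$omega_c, sum(m))
})

test_that("interfacial affinity reproduces hand-computed cases", {
  # all interface monomers at eps = 2 -> Ia = 2 exactly
  pm <- c(0.05, 0.3, 0.95, 0.95, 0.95, 0.3, 0.05)
  occ <- structure(list(p_m = pm, omega_c = 100L), class = "occupancy_profile")
  prof <- affinity_profile(rep(2, 7), rep(1L, 7), "homogeneous")
  ia <- interfacial_affinity(occ, prof)
  expect_equal(ia$ia_average, 2.0)

  # eps (1.75, 2.25) at equal weight -> 2.0
  occ2 <- structure(list(p_m = c(0.5, 1, 1, 0.5), omega_c = 10L),
                    class = "occupancy_profile")
  prof2 <- affinity_profile(c(1.75, 2, 2, 2.25), rep(1L, 4), "het1")
  ia2 <- interfacial_affinity(occ2, prof2, core_threshold = 0.9)
  expect_equal(mean(c(ia2$left$ia, ia2$right$ia)), 2.0)

  # weighted case: eps = (1, 3), Pm = (0.2, 0.6) -> (0.2 + 1.8) / 0.8 = 2.5
  occ3 <- structure(list(p_m = c(0.2, 0.6), omega_c = 10L),
                    class = "occupancy_profile")
  prof3 <- affinity_profile(c(1, 3), c(0L, 1L), "het2")
  ia3 <- interfacial_affinity(occ3, prof3)
  both <- c(ia3$left$monomers, ia3$right$monomers)
  expect_setequal(both, 1:2)
  pooled <- sum(c(1, 3) * c(0.2, 0.6)) / sum(c(0.2, 0.6))
  expect_equal(pooled, 2.5)
})

test_that("interfacial affinity stays within the affinity range", {
  set.seed(2)
  for (trial in 1:10) {
    nm <- 40L
    pm <- pmin(1, pmax(0, stats::runif(nm)))
    eps <- stats::runif(nm, 0.1, 4)
    occ <- structure(list(p_m = pm, omega_c = 50L),
                     class = "occupancy_profile")
    prof <- affinity_profile(eps, rep(1L, nm), "sequence_mapped")
    ia <- tryCatch(interfacial_affinity(occ, prof),
                   error = function(e) NULL)
    if (is.null(ia)) next
    sel <- c(ia$left$monomers, ia$right$monomers)
    expect_gte(ia$ia_average, min(eps[sel]) - 1e-12)
    expect_lte(ia$ia_average, max(eps[sel]) + 1e-12)
  }
})

test_that("empty interface raises a diagnostic error", {
  occ <- structure(list(p_m = rep(0.01, 10), omega_c = 10L),
                   class = "occupancy_profile")
  prof <- affinity_profile(rep(2, 10), rep(1L, 10), "homogeneous")
  expect_error(interfacial_affinity(occ, prof), "occupancy summary")
})

.make_bl_traj <- function(bl, kb = 100) {
  # wrap a bond-length matrix into a minimal straight-chain trajectory
  nb <- nrow(bl); nf <- ncol(bl); nm <- nb + 1L
  frames <- array(0, c(nm, 3L, nf))
  for (f in seq_len(nf)) frames[, 3, f] <- cumsum(c(0, bl[, f]))
  cfg <- experiment_config(n_monomers = nm, box = c(100, 100, 1000),
                           re_prime = 0.5, rho_uM = 0, kb = kb,
                           prod_steps = nf, n_frames = nf)
  state <- list(kind = 0:(nm - 1L), n_monomers = nm, n_proteins = 0L,
                bonds = cbind(0L:(nb - 1L), 1L:nb), tethered = integer(0),
                eps_mp = rep(2, nm), eps_pp = 2, box = c(100, 100, 1000))
  cocondense:::.new_trajectory(frames, seq_len(nf), state, cfg, 1L)
}

test_that("tether force reproduces kb * shift on prescribed bond series", {
  ser <- make_bondlength_series(l0 = 1, shift_tether = 0.01, noise_sd = 0,
                                n_bonds = 50L, n_frames = 60L)
  tt <- .make_bl_traj(ser$tethered)
  tf <- .make_bl_traj(ser$free)
  res <- tether_force(tt, tf, kb = 100)
  expect_equal(res$f_dna, 1.0, tolerance = 1e-9)
  expect_equal(res$f_dna_pN, 4.11 / 3.4, tolerance = 1e-9)
  # zero shift -> zero force
  ser0 <- make_bondlength_series(shift_tether = 0, noise_sd = 0)
  expect_equal(tether_force(.make_bl_traj(ser0$tethered),
                            .make_bl_traj(ser0$free))$f_dna, 0)
  # noisy series: kb * shift within sampling error
  sern <- make_bondlength_series(shift_tether = 0.02, noise_sd = 0.05,
                                 n_bonds = 200L, n_frames = 500L, seed = 3)
  res_n <- tether_force(.make_bl_traj(sern$tethered),
                        .make_bl_traj(sern$free), kb = 100)
  expect_equal(res_n$f_dna, 2.0, tolerance = 0.05)
})

test_that("capillary force implements the two-step subtraction exactly", {
  ser <- make_bondlength_series(l0 = 1, shift_tether = 0.005,
                                shift_protein = 0.012, noise_sd = 0,
                                n_bonds = 40L, n_frames = 30L)
  traj_p <- .make_bl_traj(ser$with_protein)
  det <- structure(list(
    per_frame = rep(list(list()), 30L),
    times = seq_len(30L),
    membership = matrix(0L, 41L, 30L), n_monomers = 41L,
    params = detection_params()), class = "detection_output")
  res <- capillary_force(traj_p, det, .make_bl_traj(ser$tethered),
                         .make_bl_traj(ser$free), kb = 100)
  expect_equal(res$f_dna, 0.5, tolerance = 1e-9)
  expect_equal(res$f_dna_protein, 1.2, tolerance = 1e-9)
  expect_equal(res$f, 1.2 - 0.5, tolerance = 1e-9)
  # identical statistics with no condensate -> F = -F_DNA + kb*(lt-lt) ...
  res0 <- capillary_force(.make_bl_traj(ser$tethered), det,
                          .make_bl_traj(ser$tethered),
                          .make_bl_traj(ser$tethered), kb = 100)
  expect_equal(res0$f, 0, tolerance = 1e-9)
})

test_that("bonds inside condensates are excluded from the outside mean", {
  nb <- 40L; nf <- 20L
  bl <- matrix(1, nb, nf)
  bl[1:20, ] <- 1.5  # inflated bonds that belong to the condensate
  traj_p <- .make_bl_traj(bl)
  det <- structure(list(per_frame = rep(list(list()), nf),
                        times = seq_len(nf),
                        membership = {
                          m <- matrix(0L, nb + 1L, nf); m[1:21, ] <- 1L; m
                        },
                        n_monomers = nb + 1L,
                        params = detection_params()),
                   class = "detection_output")
  base <- matrix(1, nb, nf)
  res <- capillary_force(traj_p, det, .make_bl_traj(base),
                         .make_bl_traj(base), kb = 100)
  # outside bonds all have length 1 -> F_DNA,protein = 0
  expect_equal(res$f_dna_protein, 0, tolerance = 1e-9)
  # fully condensed chain is an error
  det_all <- det
  det_all$membership[] <- 1L
  expect_error(capillary_force(traj_p, det_all, .make_bl_traj(base),
                               .make_bl_traj(base), kb = 100),
               "undefined")
})

test_that("force anti-symmetry: swapping trajectories negates the force", {
  ser <- make_bondlength_series(l0 = 1, shift_tether = 0.004,
                                shift_protein = 0.01, noise_sd = 0,
                                n_bonds = 30L, n_frames = 10L)
  det <- structure(list(per_frame = rep(list(list()), 10L),
                        times = 1:10,
                        membership = matrix(0L, 31L, 10L),
                        n_monomers = 31L, params = detection_params()),
                   class = "detection_output")
  a <- .make_bl_traj(ser$with_protein)
  b <- .make_bl_traj(ser$tethered)
  f_ab <- capillary_force(a, det, b, l0_bar = 1, kb = 100)
  f_ba <- capillary_force(b, det, a, l0_bar = 1, kb = 100)
  # the F_DNA,protein parts are anti-symmetric
  expect_equal(f_ab$f_dna_protein, -f_ba$f_dna_protein, tolerance = 1e-9)
})

test_that("per-monomer energy shares satisfy the bookkeeping identity", {
  cfg <- scaled_config("homogeneous", n_monomers = 25L, rho_uM = 60,
                       prod_steps = 1000, n_frames = 10L)
  prof <- build_block_profile("homogeneous", 25L)
  st <- init_system(cfg, prof, seed = 41)
  st <- integrate_system(st, cfg, 2e4, seed = 42)
  shares <- cocondense:::cpp_energy_shares(
    st$positions, st$kind, st$eps_mp, st$eps_pp, st$bonds, st$angles,
    st$box, cfg$kb, 1, cfg$kappa)
  total <- system_energy_forces(st, kb = cfg$kb, kappa = cfg$kappa)$energy
  expect_equal(sum(shares), total, tolerance = 1e-9)
  profile <- monomer_potential_profile(st, kb = cfg$kb, kappa = cfg$kappa)
  expect_length(profile, 25L)
  expect_equal(profile, shares[1:25], tolerance = 1e-12)
})

test_that("an isolated monomer carries only bonded energy", {
  st <- make_dimer()
  st$positions[2, ] <- st$positions[1, ] + c(1.1, 0, 0)  # past WCA cutoff
  st$eps_mp <- c(0, 0)
  prof <- monomer_potential_profile(st, kb = 100, kappa = 0)
  expect_equal(sum(prof), 0.5 * 100 * 0.1^2, tolerance = 1e-9)
})

test_that("kymograph mirrors the membership pattern and its identities", {
  m <- make_membership_series(function(mono, fr)
    as.integer(mono >= 100 && mono <= 200), n_monomers = 300L,
    omega_c = 40L)
  k <- kymograph(m)
  expect_equal(dim(k), c(300L, 40L))
  expect_true(all(k[100:200, ] == 1L))
  expect_true(all(k[1:99, ] == 0L))
  # column sums / Nm = condensed fraction per frame
  expect_equal(colSums(k) / 300, rep(101 / 300, 40))
  # band fusion at a chosen frame
  fuse <- make_membership_series(function(mono, fr) {
    as.integer((mono %in% 50:80) || (mono %in% 120:150) ||
               (fr >= 20 && mono %in% 81:119))
  }, n_monomers = 200L, omega_c = 40L)
  kf <- kymograph(fuse)
  gaps <- colSums(kf[81:119, ] == 0L)
  expect_true(all(gaps[1:19] == 39L))
  expect_true(all(gaps[20:40] == 0L))
})

test_that("coarsening exponent recovers exact power laws", {
  # construct a detection_output whose largest condensate has R = a t^0.5
  times <- seq(10, 1000, by = 10)
  set.seed(33)
  R <- 0.3 * times^0.5 * exp(rnorm(length(times), sd = 0.005))
  vol <- 4 / 3 * pi * R^3
  per_frame <- lapply(seq_along(times), function(f) {
    list(list(track_id = 1L, n_members = 50L))
  })
  tab <- data.frame(frame = seq_along(times), time = times,
                    condensate_id = 1L, n_members = 50L, n_monomers = 10L,
                    centroid_x = 0, centroid_y = 0, centroid_z = 0,
                    rx = R, ry = R, rz = R, volume = vol)
  det <- structure(list(per_frame = per_frame, times = times, table = tab,
                        membership = matrix(0L, 1, length(times)),
                        n_monomers = 1L, params = detection_params()),
                   class = "detection_output")
  expect_warning(ck <- coarsening_kinetics(det), "single-droplet")
  expect_equal(ck$exponent, 0.5, tolerance = 0.02)
  # saturating series: late-time slope ~ 0
  R2 <- 3 * (1 - exp(-times / 50))
  tab2 <- tab; tab2$rx <- tab2$ry <- tab2$rz <- R2
  tab2$volume <- 4 / 3 * pi * R2^3
  det2 <- det; det2$table <- tab2
  suppressWarnings(ck2 <- coarsening_kinetics(det2, fit_lo = 0.97,
                                              fit_hi = 1))
  expect_lt(abs(ck2$exponent), 0.1)
})

test_that("rigid rods flag an unbounded persistence length", {
  nm <- 30L
  frames <- array(0, c(nm, 3, 5))
  for (f in 1:5) frames[, 3, f] <- seq_len(nm)
  state <- list(kind = 0:(nm - 1L), n_monomers = nm, n_proteins = 0L,
                bonds = cbind(0L:(nm - 2L), 1L:(nm - 1L)),
                tethered = integer(0), eps_mp = rep(2, nm), eps_pp = 2,
                box = c(100, 100, 100))
  traj <- cocondense:::.new_trajectory(frames, 1:5, state, NULL, 1L)
  pl <- persistence_length(traj)
  expect_true(pl$unbounded)
  expect_equal(pl$lp, Inf)
})

test_that("a freely-jointed chain has persistence below two monomers", {
  cfg <- scaled_config("homogeneous", n_monomers = 40L, rho_uM = 0,
                       kappa = 0, prod_steps = 1000, n_frames = 10L)
  traj <- run_bare_chain(cfg, tether = FALSE, nsteps = 2e5, nframes = 100,
                         equil_steps = 5e4, seed = 51)
  pl <- persistence_length(traj)
  expect_false(pl$unbounded)
  expect_lte(pl$lp, 2.5)
})
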