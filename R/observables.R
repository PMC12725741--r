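# Quantitative readouts: occupancy, interfacial affinity, capillary force,
# per-monomer energies, kymographs, coarsening kinetics, persistence length.

#' Per-monomer occupancy probability
#'
#' The probability `P_m` of monomer m lying inside a detected condensate,
#' estimated as the fraction of analysis frames in which the monomer is a
#' condensate member: `P_m = sum_c s_mc / Omega_c` with per-frame scores
#' `s_mc` in {0, 1}.
#'
#' @param x either a `detection_output` (its monomer-membership matrix is
#'   used) or a 0/1 membership matrix (monomers x frames).
#' @param frames optional column indices restricting the analysis window.
#' @return object of class `occupancy_profile`: `p_m` (per-monomer
#'   probability), `omega_c` (frames used) and the membership matrix.
#' @export
occupancy <- function(x, frames = NULL) {
  membership <- if (inherits(x, "detection_output")) x$membership else
    as.matrix(x)
  if (!is.null(frames)) membership <- membership[, frames, drop = FALSE]
  omega <- ncol(membership)
  if (omega == 0L) stop("no frames available for occupancy")
  if (any(membership != 0L & membership != 1L))
    stop("membership scores must be 0 or 1")
  structure(list(p_m = rowSums(membership) / omega, omega_c = omega,
                 membership = membership),
            class = "occupancy_profile")
}

#' Interfacial affinity of a condensate
#'
#' Interface monomers are those with occupancy in the closed band
#' `0.1 < P_m <= 1` (default) or, alternatively, the open band
#' `0.1 < P_m < 0.9`. The interface set is split into a left and a right
#' interface by contour position relative to the condensate core, taken as
#' the longest contiguous run of monomers with `P_m >= core_threshold`.
#' Each side's interfacial affinity is the occupancy-weighted mean binding
#' energy
#' `I_a = sum(eps_mp * P_m) / sum(P_m)` over its monomers, and the reported
#' value is the average of the two sides.
#'
#' @param occ an [occupancy()] profile.
#' @param profile an [affinity_profile] of matching length.
#' @param band `"closed"` (0.1 < Pm <= 1) or `"open"` (0.1 < Pm < 0.9).
#' @param core_threshold occupancy defining the condensate core (default
#'   0.9).
#' @return object of class `interface_result` with per-side monomer sets
#'   and affinities (`left`, `right`), `ia_average`, and `n_interface`.
#' @export
interfacial_affinity <- function(occ, profile,
                                 band = c("closed", "open"),
                                 core_threshold = 0.9) {
  stopifnot(inherits(occ, "occupancy_profile"),
            inherits(profile, "affinity_profile"))
  band <- match.arg(band)
  pm <- occ$p_m
  if (length(pm) != profile$n_monomers)
    stop("occupancy and affinity profiles differ in length")
  in_band <- if (band == "closed") pm > 0.1 & pm <= 1 else
    pm > 0.1 & pm < 0.9
  if (!any(in_band))
    stop("empty interface set; occupancy summary: min=",
         signif(min(pm), 3), " max=", signif(max(pm), 3), " mean=",
         signif(mean(pm), 3))
  # core: longest contiguous run with Pm >= core_threshold
  core_mask <- pm >= core_threshold
  core_center <- if (any(core_mask)) {
    r <- rle(core_mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    (starts[best] + ends[best]) / 2
  } else {
    which.max(pm)  # no saturated core: split about the occupancy peak
  }
  idx <- which(in_band)
  side <- ifelse(idx < core_center, "left", "right")
  ia_side <- function(ii) {
    if (length(ii) == 0L) return(NA_real_)
    sum(profile$affinities[ii] * pm[ii]) / sum(pm[ii])
  }
  left <- idx[side == "left"]
  right <- idx[side == "right"]
  ia_l <- ia_side(left)
  ia_r <- ia_side(right)
  structure(list(
    left = list(monomers = left, ia = ia_l),
    right = list(monomers = right, ia = ia_r),
    ia_average = mean(c(ia_l, ia_r), na.rm = TRUE),
    n_interface = length(idx), band = band,
    core_center = core_center),
    class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf(
    "Interface: %d monomers (band %s), Ia left=%.3f right=%.3f avg=%.3f kBT\n",
    x$n_interface, x$band, x$left$ia, x$right$ia, x$ia_average))
  invisible(x)
}

# mean of per-frame mean bond lengths, optionally restricted per frame
.mean_bond_length <- function(bl) mean(colMeans(bl))

#' Tether force on bare DNA
#'
#' The force needed to hold the chain at its tether separation,
#' `F_DNA = kb * (mean(l_t) - mean(l_0))`, from the mean bond lengths of a
#' tethered and a free-ends bare-chain trajectory, each averaged over
#' analysis frames.
#'
#' @param traj_tethered_bare bare tethered `bd_trajectory`.
#' @param traj_free_bare bare free-ends `bd_trajectory` of the same chain.
#' @param kb bond constant (defaults to the tethered config's).
#' @return list with `f_dna` (kBT/sigma), `f_dna_pN`, `lt_bar`, `l0_bar`.
#' @export
tether_force <- function(traj_tethered_bare, traj_free_bare,
                         kb = traj_tethered_bare$config$kb) {
  stopifnot(inherits(traj_tethered_bare, "bd_trajectory"),
            inherits(traj_free_bare, "bd_trajectory"))
  if (traj_tethered_bare$n_monomers != traj_free_bare$n_monomers)
    stop("trajectories have different chain lengths")
  lt <- .mean_bond_length(bond_lengths(traj_tethered_bare))
  l0 <- .mean_bond_length(bond_lengths(traj_free_bare))
  f <- kb * (lt - l0)
  list(f_dna = f, f_dna_pN = f * kbt_per_sigma_in_pN(),
       lt_bar = lt, l0_bar = l0, kb = kb)
}

#' Capillary force of a protein-DNA co-condensate
#'
#' Bond-stretch force pipeline: with proteins present, the mean bond length
#' is taken over bonds whose two endpoint monomers both lie outside every
#' detected condensate of that frame (`l_tp`), giving
#' `F_DNA,protein = kb * (mean(l_tp) - mean(l_t))`; the capillary force is
#' `F = F_DNA,protein - F_DNA` with `F_DNA` the bare tether force.
#'
#' @param traj protein-DNA `bd_trajectory`.
#' @param det matching `detection_output`.
#' @param traj_tethered_bare bare tethered reference trajectory at the same
#'   extension.
#' @param traj_free_bare bare free-ends reference (for `F_DNA`); optional if
#'   `l0_bar` is given.
#' @param kb bond constant.
#' @param l0_bar precomputed free-ends mean bond length (overrides
#'   `traj_free_bare`).
#' @return object of class `force_result`: `f` (kBT/sigma), `f_pN`,
#'   `f_dna`, `f_dna_protein`, and the three mean bond lengths.
#' @export
capillary_force <- function(traj, det, traj_tethered_bare,
                            traj_free_bare = NULL,
                            kb = traj$config$kb, l0_bar = NULL) {
  stopifnot(inherits(traj, "bd_trajectory"),
            inherits(det, "detection_output"))
  if (is.null(l0_bar)) {
    if (is.null(traj_free_bare))
      stop("either traj_free_bare or l0_bar is required")
    l0_bar <- .mean_bond_length(bond_lengths(traj_free_bare))
  }
  lt_bar <- .mean_bond_length(bond_lengths(traj_tethered_bare))
  bl <- bond_lengths(traj)
  nf <- ncol(bl)
  if (length(det$per_frame) != nf)
    stop("detection output not aligned with trajectory frames")
  inside <- det$membership > 0L
  per_frame <- rep(NA_real_, nf)
  bi <- traj$bonds[, 1] + 1L
  bj <- traj$bonds[, 2] + 1L
  for (f in seq_len(nf)) {
    outside <- !(inside[bi, f] | inside[bj, f])
    if (any(outside)) per_frame[f] <- mean(bl[outside, f])
  }
  if (all(is.na(per_frame)))
    stop("all bonds are inside condensates in every frame; force undefined")
  ltp_bar <- mean(per_frame, na.rm = TRUE)
  f_dna <- kb * (lt_bar - l0_bar)
  f_dna_protein <- kb * (ltp_bar - lt_bar)
  f <- f_dna_protein - f_dna
  structure(list(f = f, f_pN = f * kbt_per_sigma_in_pN(),
                 f_dna = f_dna, f_dna_protein = f_dna_protein,
                 ltp_bar = ltp_bar, lt_bar = lt_bar, l0_bar = l0_bar,
                 kb = kb,
                 n_frames_used = sum(!is.na(per_frame))),
            class = "force_result")
}

#' @export
print.force_result <- function(x, ...) {
  cat(sprintf(
    "Capillary force F = %.4f kBT/sigma (%.4f pN); F_DNA=%.4f, F_DNA,protein=%.4f\n",
    x$f, x$f_pN, x$f_dna, x$f_dna_protein))
  invisible(x)
}

#' Per-monomer potential-energy profile
#'
#' For one frame, sums each monomer's half-share of its nonbonded pair
#' energies (monomer-monomer and monomer-protein) plus its share of bonded
#' terms, giving the energy profile along the contour. The energy drops
#' sharply for monomers inside a condensate, so the profile steps at the
#' condensate interfaces.
#'
#' @param state a `bd_system` (or a trajectory plus frame index via
#'   `frame`).
#' @param traj alternatively, a `bd_trajectory`.
#' @param frame frame index when `traj` is given.
#' @param kb,kappa,l0 bonded parameters (default from the trajectory
#'   config or 100/15/1).
#' @return numeric vector of per-monomer energies (kBT).
#' @export
monomer_potential_profile <- function(state = NULL, traj = NULL,
                                      frame = NULL, kb = NULL,
                                      kappa = NULL, l0 = 1) {
  if (is.null(state)) {
    stopifnot(inherits(traj, "bd_trajectory"), !is.null(frame))
    kb <- kb %||% traj$config$kb
    kappa <- kappa %||% traj$config$kappa
    shares <- cpp_energy_shares(frame_coords(traj, frame), traj$kind,
                                traj$eps_mp, traj$eps_pp, traj$bonds,
                                .angles_from_bonds(traj$bonds),
                                traj$box, kb, l0, kappa)
    return(shares[seq_len(traj$n_monomers)])
  }
  stopifnot(inherits(state, "bd_system"))
  kb <- kb %||% 100
  kappa <- kappa %||% 15
  shares <- cpp_energy_shares(state$positions, state$kind, state$eps_mp,
                              state$eps_pp, state$bonds, state$angles,
                              state$box, kb, l0, kappa)
  shares[seq_len(state$n_monomers)]
}

.angles_from_bonds <- function(bonds) {
  nm <- max(bonds) + 1L
  if (nm >= 3L) cbind(0L:(nm - 3L), 1L:(nm - 2L), 2L:(nm - 1L))
  else matrix(integer(0), 0L, 3L)
}

#' Monomer-occupancy kymograph
#'
#' Monomer x time matrix with entry 1 when the monomer lies inside any
#' condensate at that frame, visualizing where condensed regions sit along
#' the DNA contour over time.
#'
#' @param x a `detection_output` or a 0/1 membership matrix.
#' @return integer matrix (monomers x frames) with frame times as
#'   `attr(, "times")` when available.
#' @export
kymograph <- function(x) {
  m <- if (inherits(x, "detection_output")) {
    out <- x$membership
    attr(out, "times") <- x$times
    out
  } else as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Coarsening kinetics of tracked condensates
#'
#' Per-frame effective radius `R = (3 Vc / 4 pi)^(1/3)` of every tracked
#' condensate, normalized by the final radius of the largest one, plus a
#' log-log growth-exponent fit for the largest condensate over its growth
#' regime (frames where its radius lies between `fit_lo` and `fit_hi` of
#' the final value).
#'
#' @param det a `detection_output`.
#' @param fit_lo,fit_hi growth-window bounds as fractions of the final
#'   radius (defaults 0.2 and 0.8).
#' @return list with `series` (data frame: time, condensate_id, R,
#'   R_scaled), `exponent`, `exponent_se`, `n_fit`, and
#'   `n_tracked`. When fewer than 2 condensates are tracked a warning marks
#'   the single-droplet downgrade.
#' @export
coarsening_kinetics <- function(det, fit_lo = 0.2, fit_hi = 0.8) {
  stopifnot(inherits(det, "detection_output"))
  tab <- det$table
  if (nrow(tab) == 0L) stop("no condensates detected")
  tab$R <- (3 * tab$volume / (4 * pi))^(1 / 3)
  # rank ids by maximum size
  sizes <- tapply(tab$n_members, tab$condensate_id, max)
  ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  if (length(ids) < 2L)
    warning("fewer than 2 tracked condensates; single-droplet analysis")
  largest <- ids[1L]
  final_R <- tab$R[tab$condensate_id == largest]
  final_R <- final_R[length(final_R)]
  tab$R_scaled <- tab$R / final_R
  big <- tab[tab$condensate_id == largest, ]
  win <- big$R >= fit_lo * final_R & big$R <= fit_hi * final_R &
         big$time > 0
  exponent <- NA_real_; exponent_se <- NA_real_
  if (sum(win) >= 3L) {
    fit <- stats::lm(log(R) ~ log(time), data = big[win, ])
    exponent <- unname(stats::coef(fit)[2L])
    exponent_se <- unname(sqrt(diag(stats::vcov(fit)))[2L])
  }
  list(series = tab[, c("time", "condensate_id", "R", "R_scaled")],
       exponent = exponent, exponent_se = exponent_se,
       n_fit = sum(win), n_tracked = length(ids))
}

#' Persistence length from tangent-tangent correlations
#'
#' Fits `<t(s) . t(s + Delta)> = exp(-Delta / lp)` to the mean bond-tangent
#' correlation of a free chain over separations `Delta <= max_delta`,
#' returning the persistence length in monomer (bond) units with the fit
#' standard error. A non-decaying correlation (rigid rod) is flagged
#' `unbounded`.
#'
#' After a first pass over all separations up to `max_delta`, the fit is
#' refined over `Delta <= 2 * lp_hat`, which confines it to the exponential
#' regime and limits the upward bias that excluded-volume swelling induces
#' at large contour separations.
#'
#' @param traj a protein-free, untethered `bd_trajectory`.
#' @param max_delta largest contour separation used in the fit (default 30
#'   bonds).
#' @param refine refit over `Delta <= 2 * lp_hat` (default TRUE).
#' @return list with `lp`, `lp_se`, `correlation` (per-Delta means) and
#'   `unbounded`.
#' @export
persistence_length <- function(traj, max_delta = 30L, refine = TRUE) {
  stopifnot(inherits(traj, "bd_trajectory"))
  nm <- traj$n_monomers
  nf <- n_frames(traj)
  max_delta <- min(max_delta, nm - 2L)
  corr <- numeric(max_delta)
  counts <- numeric(max_delta)
  box <- traj$box
  for (f in seq_len(nf)) {
    p <- traj$frames[seq_len(nm), , f]
    b <- diff(p)
    for (d in 1:3) b[, d] <- .min_image(b[, d], box[d])
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (delta in seq_len(max_delta)) {
      i <- seq_len(nb - delta)
      corr[delta] <- corr[delta] + sum(rowSums(b[i, , drop = FALSE] *
                                               b[i + delta, , drop = FALSE]))
      counts[delta] <- counts[delta] + length(i)
    }
  }
  corr <- corr / counts
  if (all(corr > 0.99))
    return(list(lp = Inf, lp_se = NA_real_, correlation = corr,
                unbounded = TRUE))
  fit_range <- function(dmax) {
    usable <- which(corr > 0.05 & seq_len(max_delta) <= dmax)
    deltas <- usable
    fit <- stats::lm(log(corr[usable]) ~ 0 + deltas)
    slope <- unname(stats::coef(fit)[1L])
    se <- unname(sqrt(diag(stats::vcov(fit)))[1L])
    c(lp = -1 / slope, se = se)
  }
  est <- fit_range(max_delta)
  if (refine)
    est <- fit_range(max(4L, ceiling(2 * est[["lp"]])))
  lp <- est[["lp"]]
  list(lp = lp, lp_se = lp^2 * est[["se"]], correlation = corr,
       unbounded = FALSE)
}
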