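# Synthetic frames, trajectories and bond-length series with known ground
# truth, so the detection and observables stacks are testable without
# running dynamics.

#' Fixture specification for blob frames
#'
#' @param blob_centers matrix (n_blobs x 3) of blob centroids.
#' @param blob_sizes particles per blob.
#' @param blob_spread isotropic Gaussian sd per blob (sigma).
#' @param n_background uniformly scattered background points.
#' @param box length-3 box dimensions.
#' @param drift optional matrix (n_blobs x 3) of per-frame centroid drift.
#' @param seed RNG seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(blob_centers, blob_sizes, blob_spread = 0.5,
                         n_background = 0L, box = c(20, 20, 60),
                         drift = NULL, seed = 1L) {
  blob_centers <- if (is.null(blob_centers))
    matrix(numeric(0), 0L, 3L) else as.matrix(blob_centers)
  nb <- nrow(blob_centers)
  blob_sizes <- rep_len(as.integer(blob_sizes), nb)
  blob_spread <- rep_len(blob_spread, nb)
  if (nb >= 2L) {
    dmin <- min(stats::dist(blob_centers))
    if (dmin <= 5 * max(blob_spread))
      stop("blobs must be separated by > 5x their spread for unambiguous ",
           "ground truth")
  }
  if (is.null(drift)) drift <- matrix(0, max(nb, 1L), 3L)
  structure(list(blob_centers = blob_centers, blob_sizes = blob_sizes,
                 blob_spread = blob_spread,
                 n_background = as.integer(n_background),
                 box = box, drift = as.matrix(drift),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate one frame of Gaussian blobs plus background scatter
#'
#' @param spec a [fixture_spec()].
#' @param frame frame index (applies `drift * (frame - 1)` to centroids).
#' @return list with `points` (n x 3) and `truth` (integer blob label per
#'   point; 0 = background).
#' @export
make_blob_frame <- function(spec, frame = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 7919L * (frame - 1L))
  pts <- NULL
  truth <- integer(0)
  nb <- nrow(spec$blob_centers)
  for (b in seq_len(nb)) {
    center <- spec$blob_centers[b, ] + spec$drift[b, ] * (frame - 1L)
    p <- matrix(stats::rnorm(3L * spec$blob_sizes[b],
                             sd = spec$blob_spread[b]), ncol = 3L)
    p <- sweep(p, 2L, center, "+")
    pts <- rbind(pts, p)
    truth <- c(truth, rep(b, spec$blob_sizes[b]))
  }
  if (spec$n_background > 0L) {
    bg <- matrix(stats::runif(3L * spec$n_background), ncol = 3L)
    bg <- sweep(bg, 2L, spec$box, "*")
    pts <- rbind(pts, bg)
    truth <- c(truth, rep(0L, spec$n_background))
  }
  list(points = pts, truth = truth)
}

#' Build a synthetic trajectory of blob frames
#'
#' Wraps [make_blob_frame()] over `n_frames` frames into a `bd_trajectory`
#' whose first `n_monomers` particles are flagged as monomers, so the
#' detection and occupancy pipeline can run on it end to end.
#'
#' @param spec a [fixture_spec()].
#' @param n_frames number of frames.
#' @param n_monomers how many leading particles count as DNA monomers
#'   (default 0: all proteins).
#' @param dt_frame time between frames (tau).
#' @return a `bd_trajectory` with attribute `truth` (per-frame label list).
#' @export
make_blob_trajectory <- function(spec, n_frames = 10L, n_monomers = 0L,
                                 dt_frame = 1) {
  frames <- NULL
  truth <- vector("list", n_frames)
  n <- NULL
  for (f in seq_len(n_frames)) {
    fr <- make_blob_frame(spec, f)
    if (is.null(frames)) {
      n <- nrow(fr$points)
      frames <- array(NA_real_, c(n, 3L, n_frames))
    }
    frames[, , f] <- fr$points
    truth[[f]] <- fr$truth
  }
  nm <- as.integer(n_monomers)
  state <- list(kind = c(seq_len(nm) - 1L, rep(-1L, n - nm)),
                n_monomers = nm, n_proteins = n - nm,
                bonds = if (nm >= 2L) cbind(0L:(nm - 2L), 1L:(nm - 1L))
                        else matrix(integer(0), 0L, 2L),
                tethered = integer(0),
                eps_mp = rep(2, max(nm, 1L)), eps_pp = 2,
                box = spec$box)
  traj <- .new_trajectory(frames, dt_frame * seq_len(n_frames), state,
                          config = NULL, seed = spec$seed)
  attr(traj, "truth") <- truth
  traj
}

#' Synthetic monomer-membership series
#'
#' Builds an exact 0/1 membership matrix (monomers x frames) from a pattern
#' function or matrix, for testing occupancy, interfacial affinity and
#' kymographs against hand-computable truth.
#'
#' @param pattern either a matrix of 0/1 scores, or a function
#'   `(monomer, frame) -> 0/1` applied over the grid.
#' @param n_monomers,omega_c dimensions when `pattern` is a function.
#' @return integer membership matrix.
#' @export
make_membership_series <- function(pattern, n_monomers = NULL,
                                   omega_c = NULL) {
  if (is.function(pattern)) {
    stopifnot(!is.null(n_monomers), !is.null(omega_c))
    m <- outer(seq_len(n_monomers), seq_len(omega_c),
               Vectorize(pattern))
  } else {
    m <- as.matrix(pattern)
  }
  if (any(m != 0 & m != 1)) stop("pattern must produce 0/1 scores")
  storage.mode(m) <- "integer"
  m
}

#' Synthetic bond-length series for the force pipeline
#'
#' Gaussian bond lengths with prescribed means, in the shape the force
#' equations consume: a free-ends series at mean `l0`, a tethered series at
#' `l0 + shift_tether` and a with-proteins outside-bond series at
#' `l0 + shift_tether + shift_protein`.
#'
#' @param l0 free-chain mean bond length (sigma).
#' @param shift_tether tether-induced mean shift.
#' @param shift_protein condensate-induced additional shift.
#' @param noise_sd Gaussian sd of individual bond lengths.
#' @param n_bonds,n_frames series dimensions.
#' @param seed RNG seed.
#' @return list of three matrices (`free`, `tethered`, `with_protein`),
#'   each n_bonds x n_frames.
#' @export
make_bondlength_series <- function(l0 = 1, shift_tether = 0,
                                   shift_protein = 0, noise_sd = 0,
                                   n_bonds = 50L, n_frames = 100L,
                                   seed = 1L) {
  stopifnot(n_frames >= 1L, n_bonds >= 1L, noise_sd >= 0)
  set.seed(seed)
  gen <- function(mu) matrix(stats::rnorm(n_bonds * n_frames, mean = mu,
                                          sd = noise_sd),
                             n_bonds, n_frames)
  list(free = gen(l0),
       tethered = gen(l0 + shift_tether),
       with_protein = gen(l0 + shift_tether + shift_protein))
}
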