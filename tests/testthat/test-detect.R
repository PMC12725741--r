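test_that("k-distance curve matches a brute-force k-NN oracle", {
  set.seed(1)
  for (trial in 1:5) {
    n <- sample(20:80, 1)
    pts <- matrix(runif(3 * n) * 10, n)
    k <- sample(3:6, 1)
    d <- as.matrix(stats::dist(pts))
    oracle <- sort(apply(d, 1, function(row) sort(row)[k + 1]))
    expect_equal(kdistance_curve(pts, k), unname(oracle),
                 tolerance = 1e-12)
  }
  expect_error(kdistance_curve(matrix(0, 3, 3), k = 5), "at least")
})

test_that("coincident points give an all-zero k-distance curve", {
  pts <- matrix(1, 10, 3)
  expect_equal(kdistance_curve(pts, 5), rep(0, 10))
})

test_that("two tight blobs produce a flat curve near the blob spacing", {
  spec <- fixture_spec(rbind(c(5, 5, 5), c(5, 5, 25)), blob_sizes = 50L,
                       blob_spread = 0.5, seed = 2)
  fr <- make_blob_frame(spec)
  curve <- kdistance_curve(fr$points, 5)
  # every point has >= 5 neighbors inside its own blob: no 20-sigma values
  expect_lt(max(curve), 5)
})

test_that("Savitzky-Golay reproduces cubics exactly and keeps constants", {
  x <- seq_len(301)
  cubic <- 2 + 0.5 * x - 0.01 * x^2 + 1e-5 * x^3
  expect_equal(smooth_kdistance(cubic, 99, 3), cubic, tolerance = 1e-8)
  expect_equal(smooth_kdistance(rep(3.3, 250), 199, 3), rep(3.3, 250))
  # noisy ramp keeps its slope
  set.seed(3)
  ramp <- x + rnorm(301, sd = 0.5)
  sm <- smooth_kdistance(ramp, 99, 3)
  fit <- stats::lm(sm ~ x)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  expect_error(smooth_kdistance(1:10, 4, 3), "odd")
  expect_error(smooth_kdistance(1:10, 99, 3), "shorter")
})

test_that("knee detection recovers a constructed flat-then-ramp knee", {
  # flat at 0.1 for 80% of points, then linear ramp to 5.0
  n <- 500
  joint <- floor(0.8 * n)
  curve <- c(rep(0.1, joint), seq(0.1, 5, length.out = n - joint))
  eps <- knee_epsilon(curve)
  expect_lt(abs(eps - 0.1), 0.15)
  # straight line: no knee
  expect_error(knee_epsilon(seq(0, 1, length.out = 100)), "degenerate")
  expect_error(knee_epsilon(rep(2, 100)), "degenerate")
})

test_that("DBSCAN equals the brute-force eps-graph oracle on random data", {
  set.seed(4)
  for (trial in 1:20) {
    n <- sample(30:200, 1)
    # mixture of a few dense spots and scatter to exercise border cases
    centers <- matrix(runif(9, 0, 20), 3)
    pts <- rbind(
      centers[rep(1:3, each = n %/% 4), ] + rnorm(3 * (n %/% 4) * 3, sd = 0.4),
      matrix(runif(3 * (n - 3 * (n %/% 4))) * 20, ncol = 3))
    eps <- runif(1, 0.5, 2)
    minp <- sample(4:8, 1)
    mine <- cluster_frame(pts, eps, minp)
    oracle <- dbscan_oracle(pts, eps, minp)
    expect_true(same_partition(mine, oracle),
                info = sprintf("trial %d n=%d eps=%.2f minp=%d",
                               trial, n, eps, minp))
  }
})

test_that("isolated points are all noise", {
  pts <- cbind(seq(0, 90, by = 10), 0, 0)
  expect_true(all(cluster_frame(pts, 1, 6) == 0L))
})

test_that("detect_condensates recovers an implanted blob among scatter", {
  spec <- fixture_spec(matrix(c(20, 20, 100), 1), blob_sizes = 120L,
                       blob_spread = 0.6, n_background = 500L,
                       box = c(40, 40, 200), seed = 5)
  fr <- make_blob_frame(spec)
  recs <- detect_condensates(fr$points, detection_params(),
                             box = spec$box)
  expect_equal(length(recs), 1L)
  truth <- which(fr$truth == 1L)
  recovered <- length(intersect(recs[[1]]$members, truth)) / length(truth)
  expect_gte(recovered, 0.95)
})

test_that("a frame of isolated points yields no condensates", {
  # periodic lattice: every point equivalent -> constant k-distance curve
  # -> degenerate knee -> fallback epsilon under which all points are noise
  g <- expand.grid(x = seq(5, 35, 10), y = seq(5, 35, 10),
                   z = seq(5, 45, 10))
  pts <- as.matrix(g)
  box <- c(40, 40, 50)
  params <- detection_params(fallback_epsilon = 1)
  expect_length(detect_condensates(pts, params, box = box), 0L)
  # without a fallback the degenerate knee is an error
  expect_error(detect_condensates(pts, detection_params(), box = box),
               "degenerate")
  # explicit epsilon below the spacing: everything is noise
  expect_length(detect_condensates(pts, detection_params(), epsilon = 1),
                0L)
})

test_that("condensate volume follows the ellipsoid formula", {
  # unit radii along each axis: Vc = 4/3 pi
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  pts <- pts + 20
  set.seed(20)
  cl <- matrix(rnorm(3 * 60, sd = 0.45), ncol = 3) + 20
  all_pts <- rbind(pts, cl)
  params <- detection_params(min_size = 6L)
  recs <- detect_condensates(all_pts, params, epsilon = 1.5)
  expect_equal(length(recs), 1L)
  r <- recs[[1]]
  expect_equal(r$volume, 4 / 3 * pi * r$rx * r$ry * r$rz)
  expect_equal(r$rx, (max(all_pts[, 1]) - min(all_pts[, 1])) / 2)
  expect_equal(r$ry, (max(all_pts[, 2]) - min(all_pts[, 2])) / 2)
})

test_that("volume of uniformly filled spheres converges to 4/3 pi r^3", {
  set.seed(7)
  radius <- 3
  rel_err <- sapply(c(100, 3000), function(n) {
    p <- matrix(rnorm(3 * n), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * radius * runif(n)^(1 / 3)
    rec <- detect_condensates(p + 20, detection_params(), epsilon = 2)
    abs(rec[[1]]$volume - 4 / 3 * pi * radius^3) / (4 / 3 * pi * radius^3)
  })
  expect_lt(rel_err[2], rel_err[1] + 0.02)
  expect_lt(rel_err[2], 0.1)
})

test_that("detection is invariant to particle re-ordering", {
  spec <- fixture_spec(rbind(c(6, 6, 10), c(14, 14, 40)),
                       blob_sizes = c(60L, 40L), blob_spread = 0.5,
                       n_background = 100L, box = c(20, 20, 60), seed = 8)
  fr <- make_blob_frame(spec)
  params <- detection_params(min_size = 20L)
  recs <- detect_condensates(fr$points, params, box = spec$box)
  set.seed(9)
  perm <- sample(nrow(fr$points))
  recs_p <- detect_condensates(fr$points[perm, ], params, box = spec$box)
  expect_equal(length(recs), length(recs_p))
  sets <- lapply(recs, function(r) sort(r$members))
  sets_p <- lapply(recs_p, function(r) sort(perm[r$members]))
  expect_setequal(sapply(sets, paste, collapse = ","),
                  sapply(sets_p, paste, collapse = ","))
})

test_that("equilibrium counting respects persistence across frames", {
  # two stationary blobs in all frames -> 2
  spec <- fixture_spec(rbind(c(6, 6, 10), c(14, 14, 40)),
                       blob_sizes = c(60L, 50L), blob_spread = 0.5,
                       n_background = 40L, box = c(20, 20, 60), seed = 10)
  traj <- make_blob_trajectory(spec, n_frames = 12L)
  det <- detect_trajectory(traj, detection_params())
  expect_equal(count_equilibrium_condensates(det), 2L)

  # drifting blob keeps its identity and is counted once
  spec_d <- fixture_spec(matrix(c(6, 6, 10), 1), blob_sizes = 80L,
                         blob_spread = 0.5, n_background = 40L,
                         box = c(20, 20, 120),
                         drift = matrix(c(0, 0, 0.4), 1), seed = 11)
  traj_d <- make_blob_trajectory(spec_d, n_frames = 15L)
  det_d <- detect_trajectory(traj_d, detection_params(fallback_epsilon = 2))
  expect_equal(count_equilibrium_condensates(det_d), 1L)
  expect_equal(length(unique(det_d$table$condensate_id)), 1L)
})

test_that("a blob present in few frames falls below the persistence bar", {
  # second blob only in 30% of frames; persistence 0.8 keeps one condensate
  spec2 <- fixture_spec(rbind(c(6, 6, 10), c(14, 14, 40)),
                        blob_sizes = c(60L, 50L), blob_spread = 0.5,
                        n_background = 50L, box = c(20, 20, 60), seed = 12)
  spec1 <- fixture_spec(matrix(c(6, 6, 10), 1), blob_sizes = 60L,
                        blob_spread = 0.5, n_background = 100L,
                        box = c(20, 20, 60), seed = 12)
  frames <- array(NA_real_, c(160, 3, 10))
  for (f in 1:10) {
    fr <- if (f <= 3) make_blob_frame(spec2, f) else make_blob_frame(spec1, f)
    frames[, , f] <- fr$points
  }
  state <- list(kind = rep(-1L, 160), n_monomers = 0L, n_proteins = 160L,
                bonds = matrix(integer(0), 0, 2), tethered = integer(0),
                eps_mp = 0, eps_pp = 2, box = spec2$box)
  traj <- cocondense:::.new_trajectory(frames, 1:10, state, NULL, 1L)
  det <- detect_trajectory(traj, detection_params(fallback_epsilon = 1.5))
  expect_equal(count_equilibrium_condensates(det, window = 1:10), 1L)
})
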