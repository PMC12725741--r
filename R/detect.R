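# Condensate detection: k-distance curve -> Savitzky-Golay smoothing ->
# knee-point epsilon -> DBSCAN, plus cross-frame tracking.

#' Detection parameters
#'
#' @param min_points DBSCAN MinPts (default 6, twice the dimensionality of
#'   3D point data).
#' @param k neighbor rank for the k-distance curve; defaults to
#'   `min_points - 1`.
#' @param window Savitzky-Golay window length (odd; default 199). When a
#'   frame holds fewer points than `window` and `auto_window` is `TRUE`,
#'   the window shrinks to the largest odd length not exceeding the curve.
#' @param degree Savitzky-Golay polynomial degree (default 3).
#' @param min_size minimum particles for a cluster to count as a condensate
#'   (default 20, suppressing transient oligomers).
#' @param persistence fraction of window frames a tracked condensate must
#'   appear in to be counted at equilibrium (default 0.8).
#' @param jaccard_threshold member-overlap threshold for cross-frame
#'   identity (default 0.3).
#' @param auto_window allow shrinking the smoothing window for small frames.
#' @param fallback_epsilon epsilon used if the knee is degenerate (NULL =
#'   raise an error).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(min_points = 6L, k = min_points - 1L,
                             window = 199L, degree = 3L, min_size = 20L,
                             persistence = 0.8, jaccard_threshold = 0.3,
                             auto_window = TRUE, fallback_epsilon = NULL) {
  window <- as.integer(window)
  degree <- as.integer(degree)
  if (window %% 2L == 0L || window <= degree)
    stop("window must be odd and greater than degree")
  if (k != min_points - 1L)
    message("note: k differs from min_points - 1")
  structure(list(min_points = as.integer(min_points), k = as.integer(k),
                 window = window, degree = degree,
                 min_size = as.integer(min_size),
                 persistence = persistence,
                 jaccard_threshold = jaccard_threshold,
                 auto_window = auto_window,
                 fallback_epsilon = fallback_epsilon),
            class = "detection_params")
}

#' Sorted k-nearest-neighbor distance curve
#'
#' Distance from every point to its k-th nearest neighbor, sorted ascending.
#'
#' @param points n x 3 coordinate matrix.
#' @param k neighbor rank (default 5).
#' @param box optional periodic box (minimum-image metric).
#' @return non-decreasing numeric vector of length n.
#' @export
kdistance_curve <- function(points, k = 5L, box = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < k + 1L)
    stop("need at least k+1 = ", k + 1L, " points")
  sort(cpp_knn_dist(points, as.integer(k), box))
}

#' Savitzky-Golay smoothing of a k-distance curve
#'
#' Least-squares local polynomial smoothing via [signal::sgolayfilt()];
#' output length equals input length, and polynomials up to `degree` are
#' reproduced exactly.
#'
#' @param curve numeric vector.
#' @param window odd window length > degree.
#' @param degree polynomial degree.
#' @return smoothed curve.
#' @export
smooth_kdistance <- function(curve, window = 199L, degree = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= degree)
    stop("window must be odd and greater than degree")
  if (length(curve) < window)
    stop("curve shorter than smoothing window (", length(curve), " < ",
         window, ")")
  as.numeric(signal::sgolayfilt(curve, p = degree, n = window))
}

#' Knee-point epsilon from a smoothed k-distance curve
#'
#' Rescales both axes to [0, 1], evaluates the discrete curvature
#' |y''| / (1 + y'^2)^(3/2) by central differences, and returns the curve
#' value at the first prominent curvature maximum: the smallest index whose
#' curvature reaches at least `prominence` of the global maximum. With
#' `prominence = 1` this is the strict argmax with ties broken toward the
#' smaller index; the default 0.2 keeps the selection on the lower knee
#' (the end of the dense plateau) when a sorted curve carries a second
#' elbow between intermediate- and low-density points, which happens when
#' the bare-chain fraction of the frame is large. A curve without
#' curvature (straight line) raises a degenerate-curve error.
#'
#' @param curve smoothed, (approximately) non-decreasing curve.
#' @param edge number of points at each end excluded from the knee search
#'   (the smoothing filter's startup regions; [detect_condensates()] passes
#'   half its smoothing window).
#' @param prominence fraction of the maximum curvature a knee candidate
#'   must reach; the smallest qualifying index wins.
#' @return epsilon, on the scale of the input curve.
#' @export
knee_epsilon <- function(curve, edge = 0L, prominence = 0.2) {
  n <- length(curve)
  if (n < 5L) stop("curve too short for knee detection")
  if (n - 2L * edge < 3L) edge <- max(0L, (n - 3L) %/% 2L)
  span <- max(curve) - min(curve)
  if (span <= 0) stop("degenerate k-distance curve: no knee (constant)")
  x <- seq(0, 1, length.out = n)
  y <- (curve - min(curve)) / span
  h <- x[2] - x[1]
  yp <- c(NA, (y[3:n] - y[1:(n - 2)]) / (2 * h), NA)
  ypp <- c(NA, (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2, NA)
  curv <- abs(ypp) / (1 + yp^2)^1.5
  curv[is.na(curv)] <- -Inf
  if (edge > 0L) {
    curv[seq_len(edge)] <- -Inf
    curv[(n - edge + 1L):n] <- -Inf
  }
  if (max(curv) < 1e-6)
    stop("degenerate k-distance curve: no knee (zero curvature)")
  idx <- which(curv >= prominence * max(curv))[1L]  # first prominent knee
  curve[idx]
}

#' DBSCAN cluster labels for one frame
#'
#' Standard DBSCAN: a point is a core point when its epsilon-neighborhood,
#' counting the point itself, holds at least `min_points` points; clusters
#' are the connected components of core points with border points attached
#' to the first cluster that reaches them (deterministic given point
#' order). Noise is labeled 0.
#'
#' @param points n x 3 coordinate matrix.
#' @param epsilon neighborhood radius.
#' @param min_points core-point threshold (default 6).
#' @param box optional periodic box (minimum-image metric).
#' @return integer vector of cluster ids (0 = noise).
#' @export
cluster_frame <- function(points, epsilon, min_points = 6L, box = NULL) {
  points <- as.matrix(points)
  cpp_dbscan(points, epsilon, as.integer(min_points), box)
}

# unwrap cluster member coordinates about the first member (minimum image)
.unwrap_members <- function(p, box) {
  if (is.null(box)) return(p)
  ref <- p[1L, ]
  for (d in 1:3)
    p[, d] <- ref[d] + .min_image(p[, d] - ref[d], box[d])
  p
}

.condensate_record <- function(members, points, box, is_monomer, time = NA) {
  p <- .unwrap_members(points[members, , drop = FALSE], box)
  half_extent <- (apply(p, 2, max) - apply(p, 2, min)) / 2
  mono <- members[is_monomer[members]]
  list(
    members = members,
    centroid = colMeans(p),
    rx = half_extent[1], ry = half_extent[2], rz = half_extent[3],
    volume = 4 / 3 * pi * prod(half_extent),
    n_members = length(members),
    n_monomers = length(mono),
    monomer_span = if (length(mono)) range(mono) else c(NA_integer_,
                                                        NA_integer_),
    time = time
  )
}

#' Detect condensates in a single frame
#'
#' Full per-frame pipeline: k-distance curve, Savitzky-Golay smoothing,
#' knee-point epsilon, DBSCAN, and filtering of clusters below
#' `params$min_size`. Each retained cluster becomes a condensate record
#' carrying its members, centroid, per-axis radii (half the maximum extent
#' along each axis), ellipsoidal volume `4/3 pi rx ry rz`, and the monomer
#' index span.
#'
#' @param points n x 3 coordinate matrix (monomers and proteins jointly).
#' @param params a [detection_params()].
#' @param box optional periodic box.
#' @param is_monomer logical vector marking which rows are DNA monomers
#'   (default: none).
#' @param time frame time attached to the records.
#' @param epsilon explicit DBSCAN radius; skips the k-distance/knee
#'   selection entirely when given.
#' @return list of condensate records (possibly empty), with the chosen
#'   epsilon as attribute `epsilon`.
#' @export
detect_condensates <- function(points, params = detection_params(),
                               box = NULL, is_monomer = NULL, time = NA,
                               epsilon = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(is_monomer)) is_monomer <- rep(FALSE, n)
  if (n < params$min_points)
    stop("frame has fewer points than min_points")
  eps <- epsilon %||% {
    curve <- kdistance_curve(points, params$k, box)
    window <- params$window
    if (length(curve) < 10L * window) {
      if (!params$auto_window && length(curve) < window)
        stop("frame smaller than smoothing window")
      # short curve: the window must stay a local filter, and sqrt(n)
      # keeps the dense-to-dilute jump from being smeared across the knee
      window <- max(params$degree + 2L, ceiling(sqrt(length(curve))))
      window <- window - (1L - window %% 2L)
    }
    smoothed <- if (window > params$degree + 1L && length(curve) >= window)
      smooth_kdistance(curve, window, params$degree) else curve
    # the k-distance curve is non-decreasing by construction: project the
    # smoothed estimate back onto the monotone cone (removes filter
    # ringing around jumps) and keep it inside the data range
    smoothed <- stats::isoreg(smoothed)$yf
    smoothed <- pmin(pmax(smoothed, min(curve)), max(curve))
    e <- tryCatch(knee_epsilon(smoothed, edge = window %/% 2L),
                  error = function(err) {
      if (!is.null(params$fallback_epsilon)) params$fallback_epsilon
      else stop(err)
    })
    if (e <= 0) e <- params$fallback_epsilon %||% min(curve[curve > 0])
    e
  }
  labels <- cluster_frame(points, eps, params$min_points, box)
  ids <- setdiff(unique(labels), 0L)
  records <- list()
  for (id in ids) {
    members <- which(labels == id)
    if (length(members) < params$min_size) next
    records[[length(records) + 1L]] <-
      .condensate_record(members, points, box, is_monomer, time)
  }
  attr(records, "epsilon") <- eps
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect condensates in every frame of a trajectory
#'
#' @param traj a `bd_trajectory`.
#' @param params a [detection_params()].
#' @param epsilon optional explicit DBSCAN radius applied to every frame.
#' @return object of class `detection_output`: per-frame record lists,
#'   frame times, a tidy per-condensate table (`$table`), and the
#'   monomer-membership matrix (`$membership`, monomers x frames, 0/1).
#' @export
detect_trajectory <- function(traj, params = detection_params(),
                              epsilon = NULL) {
  stopifnot(inherits(traj, "bd_trajectory"))
  nf <- n_frames(traj)
  nm <- traj$n_monomers
  is_monomer <- traj$kind >= 0L
  per_frame <- vector("list", nf)
  membership <- matrix(0L, nm, nf)
  for (f in seq_len(nf)) {
    recs <- detect_condensates(frame_coords(traj, f), params,
                               box = traj$box, is_monomer = is_monomer,
                               time = traj$times[f], epsilon = epsilon)
    per_frame[[f]] <- recs
    for (r in recs) {
      mono <- r$members[r$members <= nm]
      membership[mono, f] <- 1L
    }
  }
  out <- structure(list(per_frame = per_frame, times = traj$times,
                        membership = membership, n_monomers = nm,
                        params = params),
                   class = "detection_output")
  out$per_frame <- .track_condensates(out, params$jaccard_threshold)
  out$table <- .detection_table(out)
  out
}

# greedy maximum-Jaccard matching of condensates across frames; a registry
# keeps every track's last-seen member set, so identities survive frames in
# which a condensate is temporarily missed or spuriously merged. When both
# records contain DNA monomers the overlap is computed on monomer members
# only: the chain segment held by a condensate is far more persistent than
# its protein complement, which exchanges with the dilute phase.
.track_condensates <- function(det, threshold) {
  per_frame <- det$per_frame
  nm <- det$n_monomers
  next_id <- 1L
  registry <- list()  # track_id (as character) -> last member set
  overlap_set <- function(members) {
    mono <- members[members <= nm]
    if (length(mono) >= 3L) mono else members
  }
  for (f in seq_along(per_frame)) {
    recs <- per_frame[[f]]
    if (length(recs) == 0L) next
    taken <- integer(0)
    # assign larger condensates first: a fission product never steals the
    # parent id from the main body
    ord <- order(vapply(recs, function(r) -r$n_members, 0))
    for (ri in ord) {
      best <- 0; best_id <- NA_integer_
      mem_r <- overlap_set(recs[[ri]]$members)
      for (id_chr in names(registry)) {
        id <- as.integer(id_chr)
        if (id %in% taken) next
        mem <- overlap_set(registry[[id_chr]])
        jac <- length(intersect(mem_r, mem)) / length(union(mem_r, mem))
        if (jac > best) { best <- jac; best_id <- id }
      }
      if (!is.na(best_id) && best >= threshold) {
        recs[[ri]]$track_id <- best_id
        taken <- c(taken, best_id)
      } else {
        recs[[ri]]$track_id <- next_id
        next_id <- next_id + 1L
      }
      registry[[as.character(recs[[ri]]$track_id)]] <- recs[[ri]]$members
    }
    per_frame[[f]] <- recs
  }
  per_frame
}

.detection_table <- function(det) {
  rows <- list()
  for (f in seq_along(det$per_frame)) {
    for (r in det$per_frame[[f]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, time = det$times[f], condensate_id = r$track_id,
        n_members = r$n_members, n_monomers = r$n_monomers,
        centroid_x = r$centroid[1], centroid_y = r$centroid[2],
        centroid_z = r$centroid[3],
        rx = r$rx, ry = r$ry, rz = r$rz, volume = r$volume)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), time = numeric(0),
                      condensate_id = integer(0), n_members = integer(0),
                      n_monomers = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), centroid_z = numeric(0),
                      rx = numeric(0), ry = numeric(0), rz = numeric(0),
                      volume = numeric(0)))
  do.call(rbind, rows)
}

#' Count condensates present at equilibrium
#'
#' Counts the tracked condensates that appear in at least
#' `params$persistence` of the frames inside the analysis window.
#'
#' @param det a `detection_output` from [detect_trajectory()].
#' @param params a [detection_params()] (persistence fraction).
#' @param window frame indices of the analysis window (default: the last
#'   half of the trajectory, at least 10 frames).
#' @return integer number of persistent condensates.
#' @export
count_equilibrium_condensates <- function(det,
                                          params = det$params,
                                          window = NULL) {
  nf <- length(det$per_frame)
  if (is.null(window)) {
    start <- max(1L, nf - max(10L, nf %/% 2L) + 1L)
    window <- start:nf
  }
  if (length(window) < 10L) stop("analysis window needs >= 10 frames")
  counts <- integer(0)
  for (f in window) {
    for (r in det$per_frame[[f]]) {
      id <- as.character(r$track_id)
      counts[id] <- (if (is.na(counts[id])) 0L else counts[id]) + 1L
    }
  }
  sum(counts >= params$persistence * length(window))
}

#' Write the per-frame detection table as TSV
#'
#' @param det a `detection_output`.
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_detection_tsv <- function(det, path) {
  utils::write.table(det$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(det$table)
}
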