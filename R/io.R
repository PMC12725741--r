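# Extended-XYZ trajectory persistence and TSV result tables.

#' Write a trajectory as extended-XYZ text
#'
#' One block per frame: particle count, a comment line carrying
#' `Time=<tau> Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` and the property layout,
#' then one line per particle with species (`M` monomer / `P` protein),
#' coordinates, and the integer monomer kind (-1 for proteins).
#'
#' @param traj a `bd_trajectory`.
#' @param path output file.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, digits = 8) {
  stopifnot(inherits(traj, "bd_trajectory"))
  nf <- n_frames(traj)
  n <- dim(traj$frames)[1]
  species <- ifelse(traj$kind >= 0L, "M", "P")
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "g %.", digits, "g %.", digits, "g %d")
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Time=%.8g Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:kind:I:1',
      traj$times[f], traj$box[1], traj$box[2], traj$box[3]), con)
    p <- traj$frames[, , f]
    writeLines(sprintf(fmt, species, p[, 1], p[, 2], p[, 3], traj$kind),
               con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory_xyz()]. A malformed or truncated frame
#' raises an error naming the last complete frame.
#'
#' @param path file written by [write_trajectory_xyz()].
#' @return a `bd_trajectory` (config is `NULL`; bonds are reconstructed as
#'   the monomer path).
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  kind <- NULL
  box <- NULL
  nframe <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed frame header after frame ", nframe, " in ", path)
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop("truncated trajectory in ", path, ": last complete frame is ",
           nframe)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    t_val <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else
      nframe + 1
    lat <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
    if (length(lat)) {
      vals <- as.numeric(strsplit(
        sub('Lattice="', "", sub('"$', "", lat)), "\\s+")[[1L]])
      box <- vals[c(1L, 5L, 9L)]
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 5L)
    if (length(bad))
      stop("malformed particle line in frame ", nframe + 1L, " of ", path)
    mat <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3L, byrow = TRUE)
    k <- as.integer(vapply(parts, `[`, "", 5L))
    if (is.null(kind)) kind <- k
    else if (!identical(kind, k))
      stop("particle types change at frame ", nframe + 1L, " of ", path)
    nframe <- nframe + 1L
    frames[[nframe]] <- mat
    times[nframe] <- t_val
    i <- i + 2L + n
  }
  if (nframe == 0L) stop("no frames in ", path)
  n <- nrow(frames[[1L]])
  arr <- array(NA_real_, c(n, 3L, nframe))
  for (f in seq_len(nframe)) arr[, , f] <- frames[[f]]
  nm <- sum(kind >= 0L)
  state <- list(kind = kind, n_monomers = nm, n_proteins = n - nm,
                bonds = if (nm >= 2L) cbind(0L:(nm - 2L), 1L:(nm - 1L))
                        else matrix(integer(0), 0L, 2L),
                tethered = integer(0),
                eps_mp = rep(2, max(nm, 1L)), eps_pp = 2,
                box = box %||% c(Inf, Inf, Inf))
  .new_trajectory(arr, times, state, config = NULL, seed = NA_integer_)
}

#' Write an occupancy profile as TSV
#' @param occ an [occupancy()] profile.
#' @param path output file.
#' @return the data frame, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  df <- data.frame(monomer = seq_along(occ$p_m) - 1L, Pm = occ$p_m)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
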