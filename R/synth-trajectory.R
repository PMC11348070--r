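#' Build a bead-trajectory object
#'
#' A coarse-grained trajectory: static bead metadata plus a coordinate array.
#' The nanotube axis is canonically the z-axis through the origin and the
#' box is periodic along it (the tube is bonded across the boundary).
#'
#' @param beads tibble with columns `bead_id`, `role` ("backbone", "base",
#'   "cnt"), `base` ("A","C","G","T" or "-"), `nt_index` (1..30 or NA).
#' @param coords numeric array, dim (n_frames, n_beads, 3), nm.
#' @param box length-3 box dimensions (nm).
#' @param radius nanotube radius (nm).
#' @return a `bead_trajectory` object.
#' @export
bead_trajectory <- function(beads, coords, box = c(20, 20, 20.759), radius = 0.6) {
  beads <- as_tibble(beads)
  stopifnot(
    all(c("bead_id", "role", "base", "nt_index") %in% names(beads)),
    length(dim(coords)) == 3, dim(coords)[2] == nrow(beads),
    dim(coords)[3] == 3, dim(coords)[1] >= 1
  )
  if (!all(beads$role %in% c("backbone", "base", "cnt"))) {
    abort("Bead roles must be backbone, base or cnt.")
  }
  base_rows <- beads$role == "base"
  if (any(is.na(beads$nt_index[base_rows])) ||
      any(beads$nt_index[base_rows] < 1 | beads$nt_index[base_rows] > INSERT_LEN)) {
    abort("Every base bead needs nt_index in 1..30.")
  }
  structure(
    list(beads = beads, coords = coords, box = box, radius = radius),
    class = "bead_trajectory"
  )
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bead_trajectory> %d frames, %d beads (%d base, %d backbone, %d cnt), box %s nm\n",
    n_frames(x), nrow(x$beads), sum(x$beads$role == "base"),
    sum(x$beads$role == "backbone"), sum(x$beads$role == "cnt"),
    paste(signif(x$box, 4), collapse = " x ")
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [bead_trajectory()].
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a tidy tibble
#' @param traj a [bead_trajectory()].
#' @param frame frame index (1-based).
#' @return tibble with bead metadata and x, y, z columns (nm).
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  traj$beads |>
    mutate(
      x = traj$coords[frame, , 1],
      y = traj$coords[frame, , 2],
      z = traj$coords[frame, , 3]
    )
}

#' Simulate a toy ssDNA-on-nanotube trajectory
#'
#' A geometric fixture, not physics: a 30-nt bead chain (backbone + base
#' beads) wrapped helically around a cylinder of radius `radius` along z,
#' with chosen base pairs "planted" as hydrogen-bonded contacts (the two
#' base beads within 0.3 nm of each other) at a prescribed distance from
#' the tube surface. Unplanted base beads sit on a helix at 1 nm surface
#' distance with >= 0.8 nm spacing between non-neighbour base beads, so
#' the only sub-cutoff base-base contacts are the planted ones. Each frame
#' adds independent Gaussian positional wobble to the DNA beads.
#'
#' @param n_frames number of frames (the analysis window default is 2000
#'   frames, i.e. the last 200 ns at one frame per 0.1 ns).
#' @param planted_pairs list of `c(i, j, radial_offset_nm)` triples with
#'   `|i - j| >= 2`; each plants an H-bonded pair at that surface distance.
#' @param wobble_sd_nm per-frame Gaussian positional noise for DNA beads.
#' @param seed integer seed.
#' @param radius nanotube radius (nm), default 0.6 (1.2-nm diameter tube).
#' @return a [bead_trajectory()].
#' @export
simulate_toy_trajectory <- function(n_frames = 2000L, planted_pairs = list(),
                                    wobble_sd_nm = 0, seed = 1L, radius = 0.6) {
  stopifnot(n_frames >= 1, wobble_sd_nm >= 0)
  idx <- unlist(lapply(planted_pairs, function(p) p[1:2]))
  if (length(planted_pairs)) {
    for (p in planted_pairs) {
      stopifnot(length(p) == 3)
      if (abs(p[1] - p[2]) < 2) abort("Planted pairs need |i - j| >= 2.")
      if (p[3] < 0) abort("Planted radial offsets must be >= 0.")
      if (any(p[1:2] < 1 | p[1:2] > INSERT_LEN)) abort("Planted indices must be in 1..30.")
    }
    if (anyDuplicated(idx)) abort("Planted pairs must not share a nucleotide index.")
  }

  box <- c(20, 20, 20.759)
  dz <- 0.45
  dtheta <- 0.7
  nt <- seq_len(INSERT_LEN)
  theta <- nt * dtheta
  z <- (nt - (INSERT_LEN + 1) / 2) * dz

  bases <- withr::with_seed(derive_seed(seed, 1), {
    sample(DNA_BASES, INSERT_LEN, replace = TRUE)
  })

  backbone <- cbind((radius + 0.3) * cos(theta), (radius + 0.3) * sin(theta), z)
  base_xyz <- cbind((radius + 1.0) * cos(theta), (radius + 1.0) * sin(theta), z)

  for (k in seq_along(planted_pairs)) {
    p <- planted_pairs[[k]]
    i <- p[1]; j <- p[2]; off <- p[3]
    r_pl <- radius + off
    th_pl <- theta[round((i + j) / 2)] + pi + 0.3 * (k - 1)
    z_pl <- (z[i] + z[j]) / 2
    # the paired beads sit 0.2 nm apart along z (< 0.35 nm H-bond cutoff)
    base_xyz[i, ] <- c(r_pl * cos(th_pl), r_pl * sin(th_pl), z_pl - 0.1)
    base_xyz[j, ] <- c(r_pl * cos(th_pl), r_pl * sin(th_pl), z_pl + 0.1)
  }

  # nanotube: rings of beads exactly on the cylinder surface
  ring_z <- seq(-9, 9, by = 1.5)
  ring_th <- seq(0, 2 * pi, length.out = 13)[-13]
  cnt_xyz <- do.call(rbind, lapply(ring_z, function(zz) {
    cbind(radius * cos(ring_th), radius * sin(ring_th), zz)
  }))

  beads <- bind_rows(
    tibble(role = "backbone", base = bases, nt_index = nt),
    tibble(role = "base", base = bases, nt_index = nt),
    tibble(role = "cnt", base = "-", nt_index = NA_integer_)[rep(1, nrow(cnt_xyz)), ]
  ) |>
    mutate(bead_id = dplyr::row_number(), .before = 1)
  ref <- rbind(backbone, base_xyz, cnt_xyz)

  nb <- nrow(ref)
  n_dna <- 2L * INSERT_LEN
  coords <- array(0, dim = c(n_frames, nb, 3))
  noise <- if (wobble_sd_nm > 0) {
    withr::with_seed(derive_seed(seed, 2),
                     array(rnorm(n_frames * n_dna * 3, 0, wobble_sd_nm),
                           dim = c(n_frames, n_dna, 3)))
  } else {
    NULL
  }
  for (f in seq_len(n_frames)) {
    fr <- ref
    if (!is.null(noise)) fr[seq_len(n_dna), ] <- fr[seq_len(n_dna), ] + noise[f, , ]
    coords[f, , ] <- fr
  }
  bead_trajectory(beads, coords, box = box, radius = radius)
}
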