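#' Distance from a point to the nanotube surface
#'
#' Radial distance to the tube axis minus the tube radius, clamped at zero
#' (points inside the tube wall report 0). The axis is the z-axis through
#' the origin unless another axis point/direction is given.
#'
#' @param points numeric matrix (n x 3) or length-3 vector, nm.
#' @param radius_nm tube radius (default 0.6).
#' @param axis_point,axis_dir axis definition (defaults: origin, +z).
#' @return numeric vector of surface distances (>= 0), nm.
#' @export
surface_distance <- function(points, radius_nm = 0.6,
                             axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1)) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  rel <- sweep(points, 2, axis_point)
  along <- rel %*% axis_dir
  perp <- rel - along %*% t(axis_dir)
  pmax(0, sqrt(rowSums(perp^2)) - radius_nm)
}

#' Detect intramolecular hydrogen bonds in one frame
#'
#' Two base beads form a hydrogen bond when their Euclidean distance
#' (minimum image along the periodic tube axis) is at most `cutoff_nm`
#' (3.5 Angstrom rule) and their nucleotide positions are at least
#' `min_seq_sep` apart (adjacent bases are covalently tethered and would
#' trivially satisfy the cutoff; set `min_seq_sep = 0` to disable).
#'
#' @param frame tidy frame tibble from [trajectory_frame()].
#' @param cutoff_nm H-bond distance cutoff (default 0.35 nm = 3.5 A).
#' @param min_seq_sep minimum |nt_index difference| (default 2).
#' @param box_z periodic box length along z (default from frame attr or 20.759).
#' @return tibble (i, j, dist_nm) with i < j by nt_index.
#' @export
detect_hbonds <- function(frame, cutoff_nm = 0.35, min_seq_sep = 2,
                          box_z = 20.759) {
  bb <- frame |> filter(.data$role == "base")
  if (nrow(bb) == 0) return(tibble(i = integer(), j = integer(), dist_nm = numeric()))
  if (any(!is.finite(as.matrix(bb[, c("x", "y", "z")])))) {
    abort("Frame contains missing or non-finite coordinates.")
  }
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  nt <- bb$nt_index
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  dz <- dz - box_z * round(dz / box_z)
  dmat <- sqrt(dx^2 + dy^2 + dz^2)
  sep <- abs(outer(nt, nt, "-"))
  hit <- which(upper.tri(dmat) & dmat <= cutoff_nm & sep >= min_seq_sep,
               arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(i = integer(), j = integer(), dist_nm = numeric()))
  }
  tibble(
    i = pmin(nt[hit[, 1]], nt[hit[, 2]]),
    j = pmax(nt[hit[, 1]], nt[hit[, 2]]),
    dist_nm = dmat[hit]
  ) |>
    arrange(.data$i, .data$j)
}

#' Classify hydrogen bonds as near or far from the nanotube surface
#'
#' A bonded pair is "near" when the smaller of its two base beads' surface
#' distances is below `cutoff_nm` (6 Angstrom rule), else "far".
#'
#' @param pairs tibble from [detect_hbonds()] (columns i, j).
#' @param frame the same tidy frame the pairs were detected on.
#' @param radius_nm tube radius.
#' @param cutoff_nm near/far surface-distance cutoff (default 0.6 nm = 6 A).
#' @return `pairs` with added `surface_dist_nm` and `class` ("near"/"far").
#' @export
classify_near_far <- function(pairs, frame, radius_nm = 0.6, cutoff_nm = 0.6) {
  bb <- frame |> filter(.data$role == "base")
  sd_by_nt <- setNames(
    as.numeric(surface_distance(as.matrix(bb[, c("x", "y", "z")]), radius_nm)),
    bb$nt_index
  )
  pairs |>
    mutate(
      surface_dist_nm = unname(pmin(
        sd_by_nt[as.character(.data$i)],
        sd_by_nt[as.character(.data$j)]
      )),
      class = ifelse(.data$surface_dist_nm < cutoff_nm, "near", "far")
    )
}

#' Hydrogen-bond statistics over an analysis window
#'
#' Runs H-bond detection and near/far classification on the last
#' `window_frames` frames of a trajectory and accumulates: per-frame pair
#' lists, per-position mean H-bond counts, and near/far counts with
#' percentages (`near% = near / (near + far) * 100`).
#'
#' @param traj a [bead_trajectory()].
#' @param window_frames analysis window (default 2000 frames, the last
#'   200 ns at 0.1 ns per frame).
#' @param hbond_cutoff_nm H-bond distance cutoff (default 0.35).
#' @param nearfar_cutoff_nm surface-distance cutoff (default 0.6).
#' @param min_seq_sep minimum sequence separation for bonds.
#' @return an `hbond_stats` object: list with `pairs` (tibble frame, i, j,
#'   dist_nm, surface_dist_nm, class), `per_position` (tibble nt_index,
#'   mean_hbonds), `near_count`, `far_count`, `near_pct`, `far_pct`.
#' @export
hbond_stats <- function(traj, window_frames = 2000L, hbond_cutoff_nm = 0.35,
                        nearfar_cutoff_nm = 0.6, min_seq_sep = 2) {
  nf <- n_frames(traj)
  if (nf < window_frames) {
    abort(sprintf("Trajectory has %d frames; window needs %d.", nf, window_frames))
  }
  frames <- seq(nf - window_frames + 1L, nf)
  all_pairs <- purrr::map_dfr(frames, function(f) {
    fr <- trajectory_frame(traj, f)
    p <- detect_hbonds(fr, cutoff_nm = hbond_cutoff_nm,
                       min_seq_sep = min_seq_sep, box_z = traj$box[3])
    if (nrow(p) == 0) return(p)
    classify_near_far(p, fr, radius_nm = traj$radius,
                      cutoff_nm = nearfar_cutoff_nm) |>
      mutate(frame = f, .before = 1)
  })

  per_position <- tibble(nt_index = seq_len(INSERT_LEN)) |>
    mutate(mean_hbonds = map_dbl(.data$nt_index, function(p) {
      if (nrow(all_pairs) == 0) return(0)
      sum(all_pairs$i == p | all_pairs$j == p) / length(frames)
    }))

  near_count <- if (nrow(all_pairs)) sum(all_pairs$class == "near") else 0L
  far_count <- if (nrow(all_pairs)) sum(all_pairs$class == "far") else 0L
  tot <- near_count + far_count
  structure(
    list(
      pairs = all_pairs, per_position = per_position,
      near_count = near_count, far_count = far_count,
      near_pct = if (tot > 0) 100 * near_count / tot else NA_real_,
      far_pct = if (tot > 0) 100 * far_count / tot else NA_real_,
      window_frames = length(frames)
    ),
    class = "hbond_stats"
  )
}

#' @export
print.hbond_stats <- function(x, ...) {
  cat(sprintf(
    "<hbond_stats> window %d frames: %d near / %d far H-bonds (near %.1f%%, far %.1f%%)\n",
    x$window_frames, x$near_count, x$far_count,
    x$near_pct %||% NA, x$far_pct %||% NA
  ))
  invisible(x)
}

#' Per-position mean hydrogen-bond count
#'
#' Mean number of H-bond pairs involving each nucleotide position over the
#' last `window_frames` frames.
#'
#' @inheritParams hbond_stats
#' @return tibble (nt_index, mean_hbonds).
#' @export
per_position_hbond_mean <- function(traj, window_frames = 2000L,
                                    hbond_cutoff_nm = 0.35, min_seq_sep = 2) {
  hbond_stats(traj, window_frames = window_frames,
              hbond_cutoff_nm = hbond_cutoff_nm,
              min_seq_sep = min_seq_sep)$per_position
}

#' Mean square displacement of a bead group
#'
#' Center-of-mass MSD of the selected beads:
#' `MSD(lag) = <|r(t + lag) - r(t)|^2>`, averaged over all time origins t
#' (multi-origin estimator; `origin = "single"` gives the strict
#' fixed-origin form `|r(t) - r(0)|^2`). Coordinates are unwrapped along
#' the periodic tube axis before the center of mass is taken.
#'
#' @param traj a [bead_trajectory()].
#' @param roles bead roles to include (default "base" and "backbone", the
#'   DNA molecule).
#' @param origin "multi" (all time origins) or "single".
#' @return tibble (lag, msd_nm2) of class `msd_curve`; lag 0 included.
#' @export
msd <- function(traj, roles = c("base", "backbone"), origin = c("multi", "single")) {
  origin <- match.arg(origin)
  sel <- which(traj$beads$role %in% roles)
  if (length(sel) == 0) abort("Bead selection is empty.")
  nf <- n_frames(traj)
  if (nf < 2) abort("Need at least 2 frames for an MSD.")

  xyz <- traj$coords[, sel, , drop = FALSE]
  # unwrap each bead's z across frames
  Lz <- traj$box[3]
  z <- xyz[, , 3, drop = FALSE]
  dz <- z[-1, , , drop = FALSE] - z[-nf, , , drop = FALSE]
  dz <- dz - Lz * round(dz / Lz)
  for (f in 2:nf) z[f, , ] <- z[f - 1, , ] + dz[f - 1, , ]
  xyz[, , 3] <- z[, , 1]

  com <- vapply(
    1:3,
    function(d) rowMeans(matrix(xyz[, , d], nrow = nf)),
    numeric(nf)
  ) # nf x 3

  lags <- 0:(nf - 1)
  vals <- vapply(lags, function(L) {
    if (L == 0) return(0)
    if (origin == "multi") {
      disp <- com[(1 + L):nf, , drop = FALSE] - com[1:(nf - L), , drop = FALSE]
      mean(rowSums(disp^2))
    } else {
      disp <- com[1 + L, ] - com[1, ]
      sum(disp^2)
    }
  }, numeric(1))
  out <- tibble(lag = lags, msd_nm2 = vals)
  class(out) <- c("msd_curve", class(out))
  out
}
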