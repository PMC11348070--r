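#' Write/read a kinetic trace as TSV with a JSON sidecar
#'
#' The trace goes to a two-column TSV (`time_s`, `wavelength_nm`); the
#' surfactant-addition time goes to `<path>.json` as `{"t_add_s": ...}`.
#'
#' @param trace a [kinetic_trace()].
#' @param path TSV path.
#' @return `path` invisibly (write) / a [kinetic_trace()] (read).
#' @export
write_trace <- function(trace, path) {
  readr::write_tsv(as_tibble(trace), path)
  jsonlite::write_json(list(t_add_s = t_add(trace)), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), wavelength_nm = readr::col_double()
  ))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  kinetic_trace(df$time_s, df$wavelength_nm, meta$t_add_s)
}

#' Write/read a bead trajectory as long TSV with a JSON header
#'
#' Frames go to a TSV (frame, bead_id, role, base, nt_index, x, y, z); the
#' box, tube radius and axis go to `<path>.json`.
#'
#' @param traj a [bead_trajectory()].
#' @param path TSV path.
#' @return `path` invisibly (write) / a [bead_trajectory()] (read).
#' @export
write_trajectory <- function(traj, path) {
  long <- purrr::map_dfr(seq_len(n_frames(traj)), function(f) {
    trajectory_frame(traj, f) |> mutate(frame = f, .before = 1)
  })
  readr::write_tsv(long, path)
  jsonlite::write_json(
    list(box = traj$box, radius = traj$radius,
         axis = list(point = c(0, 0, 0), dir = c(0, 0, 1))),
    paste0(path, ".json")
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    frame = readr::col_integer(), bead_id = readr::col_integer(),
    role = readr::col_character(), base = readr::col_character(),
    nt_index = readr::col_integer(), x = readr::col_double(),
    y = readr::col_double(), z = readr::col_double()
  ))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  beads <- long |>
    filter(.data$frame == min(.data$frame)) |>
    select("bead_id", "role", "base", "nt_index")
  nf <- length(unique(long$frame))
  nb <- nrow(beads)
  long <- long |> arrange(.data$frame, .data$bead_id)
  coords <- array(0, c(nf, nb, 3))
  coords[, , 1] <- matrix(long$x, nrow = nf, byrow = TRUE)
  coords[, , 2] <- matrix(long$y, nrow = nf, byrow = TRUE)
  coords[, , 3] <- matrix(long$z, nrow = nf, byrow = TRUE)
  bead_trajectory(beads, coords, box = meta$box, radius = meta$radius)
}
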