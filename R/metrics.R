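#' Polarization order parameter
#'
#' Norm of the mean unit-heading vector of the group: 1 when all agents
#' move in the same direction, near 0 for fully disordered headings.
#'
#' @param headings n x 2 matrix of unit headings.
#' @return Scalar in `[0, 1]`.
#' @export
polarization <- function(headings) {
  h <- rbind2cols(headings)
  if (nrow(h) == 0L) stop("empty heading set", call. = FALSE)
  mh <- colMeans(h)
  min(1, sqrt(sum(mh^2)))
}

#' Motion-aligned elongation ratio
#'
#' Length-to-width ratio of the bounding rectangle of the group with one
#' axis constrained to the group's direction of motion: positions are
#' projected onto the motion direction (length L) and its perpendicular
#' (width W) and the ratio `L / max(W, w_min)` is returned. Values well
#' above 1 indicate a longitudinal queue stretched along the travel
#' direction. The width floor `w_min` (default one body length) keeps the
#' ratio finite for perfectly collinear groups.
#'
#' @param positions n x 2 matrix of agent positions (n >= 2).
#' @param motion_direction Length-2 unit vector, the centroid motion
#'   direction.
#' @param w_min Width floor. Default 1.
#' @return Scalar elongation ratio (> 0).
#' @export
elongation <- function(positions, motion_direction, w_min = 1) {
  p <- rbind2cols(positions)
  stopifnot(nrow(p) >= 2L, length(motion_direction) == 2L, w_min > 0)
  d <- motion_direction / sqrt(sum(motion_direction^2))
  along <- p %*% d
  across <- p %*% c(-d[2], d[1])
  (max(along) - min(along)) / max(max(across) - min(across), w_min)
}

#' Finite-difference centroid motion direction
#'
#' Normalized displacement of the centroid between two instants; when the
#' centroid barely moved (norm below 1e-9) the direction is undefined and
#' the fallback (typically the last valid direction, or the mean heading at
#' the first step) is returned instead.
#'
#' @param previous_centroid,current_centroid Length-2 points.
#' @param fallback Length-2 unit vector used when the displacement is
#'   degenerate.
#' @return Length-2 unit vector.
#' @export
centroid_direction <- function(previous_centroid, current_centroid, fallback) {
  dv <- current_centroid - previous_centroid
  nv <- sqrt(sum(dv^2))
  if (nv < 1e-9) {
    fallback / sqrt(sum(fallback^2))
  } else {
    dv / nv
  }
}

#' Detect centroid success in a metrics series
#'
#' An episode succeeds when the swarm centroid first comes within
#' `success_radius` of the target.
#'
#' @param metrics Tibble with columns `t` and `dist_to_target` (as produced
#'   by [run_episode()]).
#' @param success_radius Success distance.
#' @return List with `success` (logical) and `hit_step` (first step within
#'   the radius, or `NA`).
#' @export
detect_success <- function(metrics, success_radius = 100) {
  stopifnot(all(c("t", "dist_to_target") %in% names(metrics)))
  w <- which(metrics$dist_to_target <= success_radius)
  if (length(w) == 0L) {
    list(success = FALSE, hit_step = NA_integer_)
  } else {
    list(success = TRUE, hit_step = as.integer(metrics$t[w[1]]))
  }
}

#' Summarize an episode's order-parameter series
#'
#' Computes the derived summary of a per-step metrics series: peak
#' elongation and its step, the first step at which polarization reaches
#' `alignment_threshold`, the mean polarization and mean elongation over
#' the steady navigation window (from first alignment until the first
#' target hit, or the end of the series), and the success flag.
#'
#' @param metrics Tibble from [run_episode()] (columns `t`, `polarization`,
#'   `elongation`, `dist_to_target`).
#' @param alignment_threshold Polarization level defining alignment.
#'   Default 0.9.
#' @param success_radius Success distance for the window end and the flag.
#' @return One-row tibble: `steps`, `alignment_step`, `peak_elongation`,
#'   `peak_elongation_step`, `mean_polarization`, `mean_elongation`,
#'   `success`, `hit_step`.
#' @export
summarize_metrics <- function(metrics, alignment_threshold = 0.9,
                              success_radius = 100) {
  stopifnot(all(c("t", "polarization", "elongation", "dist_to_target")
                %in% names(metrics)))
  n <- nrow(metrics)
  al <- which(metrics$polarization >= alignment_threshold)
  alignment_step <- if (length(al)) as.integer(metrics$t[al[1]]) else NA_integer_
  hit <- detect_success(metrics, success_radius)
  ipk <- which.max(metrics$elongation)
  w0 <- if (length(al)) al[1] else 1L
  w1 <- if (hit$success) which(metrics$t == hit$hit_step)[1] else n
  win <- seq.int(min(w0, w1), w1)
  tibble::tibble(
    steps = as.integer(metrics$t[n]),
    alignment_step = alignment_step,
    peak_elongation = metrics$elongation[ipk],
    peak_elongation_step = as.integer(metrics$t[ipk]),
    mean_polarization = mean(metrics$polarization[win]),
    mean_elongation = mean(metrics$elongation[win]),
    success = hit$success,
    hit_step = hit$hit_step)
}

#' Write a metrics series as CSV
#'
#' @param metrics Tibble from [run_episode()].
#' @param path File path.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}

#' Write a per-agent trajectory as CSV
#'
#' @param trajectory Tibble from [run_episode()] with
#'   `record_trajectory = TRUE`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(trajectory, path)
  invisible(path)
}
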