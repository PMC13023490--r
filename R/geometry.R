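#' Signed angle between two planar vectors
#'
#' Angle by which `u` must rotate counter-clockwise to point along `v`,
#' in `(-pi, pi]`. Positive means `v` lies counter-clockwise (to the left)
#' of `u`; exactly antiparallel vectors give `+pi`. Vectorized: `u` and `v`
#' may be 2-column matrices with one row per pair.
#'
#' @param u,v Length-2 vectors or n x 2 matrices.
#' @return Numeric vector of angles in radians.
#' @export
signed_angle <- function(u, v) {
  u <- rbind2cols(u); v <- rbind2cols(v)
  atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
        u[, 1] * v[, 1] + u[, 2] * v[, 2])
}

rbind2cols <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    x
  } else {
    stopifnot(length(x) == 2L)
    matrix(x, ncol = 2L)
  }
}

#' Indices of the k topologically nearest neighbors
#'
#' Returns the `k` agents closest (Euclidean) to the focal agent, excluding
#' the focal agent itself; distance ties are broken toward the smaller index.
#' Topological (k-nearest) rather than metric interaction keeps the social
#' neighborhood size fixed regardless of local density.
#'
#' @param positions n x 2 matrix of agent positions.
#' @param i Focal agent index (1-based).
#' @param k Number of neighbors, `k < n`.
#' @return Integer vector of `k` neighbor indices, in increasing distance
#'   order.
#' @export
topological_neighbors <- function(positions, i, k) {
  positions <- rbind2cols(positions)
  n <- nrow(positions)
  stopifnot(i >= 1, i <= n, k >= 1)
  if (k >= n) stop("k must be smaller than the number of agents", call. = FALSE)
  d <- sqrt((positions[, 1] - positions[i, 1])^2 +
              (positions[, 2] - positions[i, 2])^2)
  d[i] <- Inf
  order(d, seq_len(n))[seq_len(k)]  # stable: ties to smaller index
}

#' Signed deviation of the neighbor-average direction
#'
#' The local social cue: the signed angle from the focal agent's heading to
#' the normalized average of its neighbors' headings. Positive means the
#' neighbor average lies counter-clockwise (left) of the agent's own
#' heading. If the neighbor headings cancel (norm of the average below
#' 1e-9), the cue carries no directional information and the angle is
#' defined as 0 (treated as aligned).
#'
#' @param heading Focal agent's unit heading (length-2).
#' @param neighbor_headings n x 2 matrix of neighbor unit headings.
#' @return Signed angle in radians, in `(-pi, pi]`.
#' @export
neighbor_angle <- function(heading, neighbor_headings) {
  nh <- rbind2cols(neighbor_headings)
  stopifnot(nrow(nh) >= 1L)
  avg <- colMeans(nh)
  if (sqrt(sum(avg^2)) < 1e-9) return(0)
  as.numeric(signed_angle(heading, avg))
}

#' Signed bearing of the target
#'
#' The global navigational cue: the signed angle from the agent's heading to
#' the direction of the target. Positive means the target is
#' counter-clockwise (left) of the heading, matching the neighbor-cue
#' convention. An agent exactly at the target has bearing 0.
#'
#' @param heading Unit heading (length-2).
#' @param position Agent position (length-2).
#' @param target Target position (length-2).
#' @return Signed angle in radians, in `(-pi, pi]`.
#' @export
target_angle <- function(heading, position, target) {
  v <- c(target[1] - position[1], target[2] - position[2])
  if (sqrt(sum(v^2)) < 1e-12) return(0)
  as.numeric(signed_angle(heading, v))
}

#' Discretize a relative angle into a three-way cue
#'
#' Maps a continuous signed angle to a categorical perception:
#' 1 (aligned) when `|theta| <= pi/6`; 0 (deviation to the right,
#' clockwise) when `theta < -pi/6`; 2 (deviation to the left,
#' counter-clockwise) when `theta > pi/6`. The boundary `|theta| = pi/6`
#' belongs to the aligned cue.
#'
#' @param theta Signed angle(s) in radians, in `[-pi, pi]`.
#' @return Integer cue(s) in `{0, 1, 2}`.
#' @export
discretize_angle <- function(theta) {
  ifelse(abs(theta) <= pi / 6, 1L, ifelse(theta < 0, 0L, 2L))
}

#' Combine the two cues into a percept index
#'
#' The percept state is `3 * s_n + s_t`, giving indices 0..8. State 2
#' (neighbors right, target left) and state 6 (neighbors left, target
#' right) are the two conflict states where social alignment and goal
#' direction disagree.
#'
#' @param s_n Neighbor cue in `{0, 1, 2}`.
#' @param s_t Target cue in `{0, 1, 2}`.
#' @return Integer percept index in 0..8.
#' @export
percept_index <- function(s_n, s_t) {
  if (any(!(s_n %in% 0:2)) || any(!(s_t %in% 0:2))) {
    stop("cues must be 0, 1 or 2", call. = FALSE)
  }
  as.integer(3L * s_n + s_t)
}

#' Perturb a perceived angle with Gaussian sensory noise
#'
#' Adds zero-mean Gaussian noise with standard deviation `sigma` (degrees)
#' to a perceived angle and wraps the result back into `(-pi, pi]`. Models
#' imperfect perception at evaluation time.
#'
#' @param theta Angle(s) in radians.
#' @param sigma Noise standard deviation in degrees (>= 0).
#' @return Noisy angle(s) in radians.
#' @export
apply_sensor_noise <- function(theta, sigma) {
  stopifnot(length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(theta)
  x <- theta + stats::rnorm(length(theta), 0, sigma * pi / 180)
  atan2(sin(x), cos(x))
}

#' Rotate a heading by a steering angle
#'
#' Standard 2D rotation: positive angles turn counter-clockwise (left).
#' Vectorized over rows of `heading` and over `angle`.
#'
#' @param heading Length-2 unit vector or n x 2 matrix.
#' @param angle Steering angle(s) in degrees.
#' @return Rotated heading(s), same shape as the input.
#' @export
turn <- function(heading, angle) {
  h <- rbind2cols(heading)
  a <- angle * pi / 180
  out <- cbind(cos(a) * h[, 1] - sin(a) * h[, 2],
               sin(a) * h[, 1] + cos(a) * h[, 2])
  if (is.matrix(heading)) out else as.numeric(out)
}
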