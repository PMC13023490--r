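#' Weighted Vicsek baseline configuration
#'
#' The rule-based comparator: each agent's new heading is the direction of
#' `(1 - omega) * v_avg_hat + omega * v_target_hat` plus uniform angular
#' noise on `[-noise_halfwidth, noise_halfwidth]` radians, where `v_avg` is
#' the mean heading of its k topological neighbors (self excluded) and
#' `v_target` the bearing of the target. A fixed linear blend of alignment
#' and attraction -- no learning, no state-dependent arbitration.
#'
#' @param omega Target weight in `[0, 1]` (0 = pure alignment, 1 = pure
#'   pursuit). Default 0.5.
#' @param noise_halfwidth Half-width of the uniform angular noise in
#'   radians. Default 0.25.
#' @return Object of class `ps_vicsek_config`.
#' @export
vicsek_config <- function(omega = 0.5, noise_halfwidth = 0.25) {
  stopifnot(omega >= 0, omega <= 1, noise_halfwidth >= 0)
  structure(list(omega = omega, noise_halfwidth = noise_halfwidth),
            class = "ps_vicsek_config")
}

# Mean neighbor heading for every agent (self excluded), k topological.
neighbor_average_all <- function(pos, hd, k) {
  n <- nrow(pos)
  s <- rowSums(pos^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(pos)
  diag(d2) <- Inf
  acc <- matrix(0, n, 2)
  idx <- seq_len(n)
  for (jj in seq_len(k)) {
    j <- max.col(-d2, ties.method = "first")
    acc <- acc + hd[j, , drop = FALSE]
    d2[cbind(idx, j)] <- Inf
  }
  acc / k
}

#' One synchronous step of the weighted Vicsek model
#'
#' All agents compute their blended direction from the same time-`t`
#' snapshot, add independent uniform noise, then rotate and advance
#' together. If the blended vector vanishes the agent keeps its previous
#' heading (before noise).
#'
#' @param state A [init_swarm()] state.
#' @param vconfig A [vicsek_config()].
#' @param config A [swarm_config()] (supplies `k` and `speed`).
#' @return The advanced `ps_swarm` state.
#' @export
vicsek_step <- function(state, vconfig = vicsek_config(),
                        config = swarm_config()) {
  stopifnot(inherits(state, "ps_swarm"), inherits(vconfig, "ps_vicsek_config"),
            inherits(config, "ps_config"))
  pos <- state$positions; hd <- state$headings
  n <- nrow(pos)
  avg <- neighbor_average_all(pos, hd, config$k)
  an <- sqrt(rowSums(avg^2))
  avg_hat <- avg / ifelse(an < 1e-12, 1, an)
  avg_hat[an < 1e-12, ] <- 0
  tx <- state$target[1] - pos[, 1]; ty <- state$target[2] - pos[, 2]
  dn <- pmax(sqrt(tx^2 + ty^2), 1e-12)
  wx <- (1 - vconfig$omega) * avg_hat[, 1] + vconfig$omega * tx / dn
  wy <- (1 - vconfig$omega) * avg_hat[, 2] + vconfig$omega * ty / dn
  degen <- (wx^2 + wy^2) < 1e-18
  th <- atan2(wy, wx)
  th[degen] <- atan2(hd[degen, 2], hd[degen, 1])
  if (vconfig$noise_halfwidth > 0) {
    th <- th + stats::runif(n, -vconfig$noise_halfwidth,
                            vconfig$noise_halfwidth)
  }
  hd2 <- cbind(cos(th), sin(th))
  state$positions <- pos + config$speed * hd2
  state$headings <- hd2
  state$target <- state$target + state$target_velocity
  state$t <- state$t + 1L
  state
}

#' Run a full weighted-Vicsek episode
#'
#' Same initial-condition law, metrics and success criterion as
#' [run_episode()], but with the fixed Vicsek update instead of the learned
#' policy.
#'
#' @param vconfig A [vicsek_config()].
#' @param config A [swarm_config()].
#' @param state Optional pre-built initial state.
#' @return A `ps_episode` object (with `policy = NULL`,
#'   `total_reward = NA`).
#' @export
run_vicsek <- function(vconfig = vicsek_config(), config = swarm_config(),
                       state = NULL) {
  stopifnot(inherits(config, "ps_config"))
  if (is.null(state)) state <- init_swarm(config)
  pos <- state$positions; hd <- state$headings
  tpos <- state$target; tvel <- state$target_velocity
  n <- nrow(pos)
  max_steps <- config$max_steps
  op <- oe <- dtt <- cx <- cy <- numeric(max_steps)
  cen_prev <- colMeans(pos)
  dir_cur <- colMeans(hd)
  dir_cur <- if (sqrt(sum(dir_cur^2)) >= 1e-9) dir_cur / sqrt(sum(dir_cur^2)) else c(1, 0)
  hit <- NA_integer_
  t <- 0L
  st <- state
  while (t < max_steps) {
    t <- t + 1L
    st <- vicsek_step(st, vconfig, config)
    pos <- st$positions; hd <- st$headings; tpos <- st$target
    mh <- colMeans(hd)
    op[t] <- sqrt(sum(mh^2))
    cen <- colMeans(pos)
    dv <- cen - cen_prev
    if (sqrt(sum(dv^2)) >= 1e-9) dir_cur <- dv / sqrt(sum(dv^2))
    proj_l <- pos %*% dir_cur
    proj_w <- pos %*% c(-dir_cur[2], dir_cur[1])
    oe[t] <- (max(proj_l) - min(proj_l)) / max(max(proj_w) - min(proj_w), 1)
    cx[t] <- cen[1]; cy[t] <- cen[2]
    dtt[t] <- sqrt(sum((cen - tpos)^2))
    cen_prev <- cen
    if (is.na(hit) && dtt[t] <= config$success_radius) {
      hit <- t
      if (config$stop_on_success) break
    }
  }
  keep <- seq_len(t)
  structure(list(
    metrics = tibble::tibble(t = keep, polarization = op[keep],
                             elongation = oe[keep], centroid_x = cx[keep],
                             centroid_y = cy[keep],
                             dist_to_target = dtt[keep]),
    trajectory = NULL,
    policy = NULL,
    success = !is.na(hit),
    hit_step = hit,
    steps = t,
    total_reward = NA_real_),
    class = "ps_episode")
}
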