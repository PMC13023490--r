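#' Environment configuration for the navigation task
#'
#' Bundles the parameters of the two-dimensional unbounded navigation
#' environment: swarm size, topological neighborhood, initial conditions,
#' kinematics, target, episode length, sensory noise and the success
#' criterion. Defaults are the reference setup of the model: 30 agents,
#' 6 topological neighbors, unit speed, initial positions uniform in a disk
#' of radius 300 around the origin, a static target at (3000, 3000), and
#' episodes of at most 10,000 steps.
#'
#' @param n Group size (>= 2).
#' @param k Topological neighbor count, `1 <= k < n`.
#' @param init_radius Radius of the disk (centred at the origin) in which
#'   initial positions are drawn uniformly by area.
#' @param speed Distance travelled per step (constant for all agents).
#' @param max_steps Maximum steps per episode.
#' @param target Length-2 target position.
#' @param target_velocity Length-2 target velocity per step (zero = static).
#' @param sensor_noise_sigma Gaussian sensory noise SD in degrees applied to
#'   both perceived angles before discretization (0 = noiseless).
#' @param success_radius An episode counts as successful once the swarm
#'   centroid comes within this distance of the target.
#' @param stop_on_success Stop the episode at the first success.
#' @return Object of class `ps_config` (a validated list).
#' @export
swarm_config <- function(n = 30L, k = 6L, init_radius = 300, speed = 1,
                         max_steps = 10000L, target = c(3000, 3000),
                         target_velocity = c(0, 0), sensor_noise_sigma = 0,
                         success_radius = 100, stop_on_success = TRUE) {
  stopifnot(n >= 2, k >= 1, k < n, init_radius > 0, speed > 0, max_steps >= 1,
            length(target) == 2L, length(target_velocity) == 2L,
            sensor_noise_sigma >= 0, success_radius >= 0)
  structure(list(n = as.integer(n), k = as.integer(k),
                 init_radius = init_radius, speed = speed,
                 max_steps = as.integer(max_steps),
                 target = as.numeric(target),
                 target_velocity = as.numeric(target_velocity),
                 sensor_noise_sigma = sensor_noise_sigma,
                 success_radius = success_radius,
                 stop_on_success = isTRUE(stop_on_success)),
            class = "ps_config")
}

#' Reward weights of the composite navigation reward
#'
#' The per-step reward of each agent combines a distance-progress term
#' (reduction of its distance to the target this step, bounded by the step
#' length) and a heading-consistency term (dot product of the heading with
#' the unit vector toward the target, clipped at zero):
#' `r_total = distance * r_dis + direction * r_dir`.
#'
#' @param distance Weight of the distance-progress term (lambda_d).
#' @param direction Weight of the heading-consistency term (lambda_r).
#' @return Object of class `ps_weights`.
#' @export
reward_weights <- function(distance = 0.5, direction = 0.5) {
  stopifnot(distance >= 0, direction >= 0)
  structure(list(distance = distance, direction = direction),
            class = "ps_weights")
}

#' Draw a fresh swarm state
#'
#' Positions are uniform by area over the disk of radius `init_radius`
#' centred at the origin; headings are independent and uniform on the
#' circle, so the initial group carries no alignment bias (expected
#' polarization is of order `1/sqrt(n)`).
#'
#' @param config A [swarm_config()].
#' @return Object of class `ps_swarm`: list with `positions` (n x 2),
#'   `headings` (n x 2, unit rows), `t`, `target`, `target_velocity`.
#' @export
init_swarm <- function(config = swarm_config()) {
  stopifnot(inherits(config, "ps_config"))
  n <- config$n
  r <- sqrt(stats::runif(n)) * config$init_radius
  phi <- stats::runif(n, 0, 2 * pi)
  ha <- stats::runif(n, 0, 2 * pi)
  structure(list(positions = cbind(r * cos(phi), r * sin(phi)),
                 headings = cbind(cos(ha), sin(ha)),
                 t = 0L,
                 target = config$target,
                 target_velocity = config$target_velocity),
            class = "ps_swarm")
}

#' @export
print.ps_swarm <- function(x, ...) {
  cat("<ps_swarm> ", nrow(x$positions), " agents at t = ", x$t,
      ", target (", paste(signif(x$target, 6), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.ps_swarm <- function(x, ...) {
  tibble::tibble(agent = seq_len(nrow(x$positions)),
                 t = x$t,
                 x = x$positions[, 1], y = x$positions[, 2],
                 heading_x = x$headings[, 1], heading_y = x$headings[, 2])
}

#' Per-agent composite reward for one step
#'
#' `r_dis` is the reduction in distance to the target over the step
#' (positive when the agent got closer; bounded by the step length in
#' magnitude). `r_dir` is the clipped alignment of the post-move heading
#' with the bearing of the target from the post-move position,
#' `max(0, heading . t_hat)`. The total is the weighted sum.
#'
#' @param prev_position,new_position n x 2 matrices (or length-2 vectors) of
#'   pre- and post-move positions.
#' @param new_heading Post-move unit heading(s), same shape.
#' @param target Length-2 target position (post-move; for a moving target
#'   pass `prev_target` as the pre-move position).
#' @param weights A [reward_weights()].
#' @param prev_target Target position before the step; defaults to `target`.
#' @return Tibble with columns `r_dis`, `r_dir`, `r_total`.
#' @export
compute_reward <- function(prev_position, new_position, new_heading,
                           target, weights = reward_weights(),
                           prev_target = target) {
  p0 <- rbind2cols(prev_position); p1 <- rbind2cols(new_position)
  h1 <- rbind2cols(new_heading)
  stopifnot(inherits(weights, "ps_weights"))
  d0 <- sqrt((prev_target[1] - p0[, 1])^2 + (prev_target[2] - p0[, 2])^2)
  tx <- target[1] - p1[, 1]; ty <- target[2] - p1[, 2]
  d1 <- sqrt(tx^2 + ty^2)
  r_dis <- d0 - d1
  r_dir <- pmax(0, (h1[, 1] * tx + h1[, 2] * ty) / pmax(d1, 1e-12))
  tibble::tibble(r_dis = r_dis, r_dir = r_dir,
                 r_total = weights$distance * r_dis + weights$direction * r_dir)
}

# ---- internal vectorized engine ------------------------------------------

# Percepts of every agent from a common snapshot. Returns 0-based indices.
# Neighbor averaging uses k passes of max.col over the negated squared
# distance matrix (ties.method = "first" reproduces the smaller-index tie
# rule of topological_neighbors).
percepts_all <- function(pos, hd, tpos, k, sigma = 0) {
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
  th_n <- ifelse(rowSums(acc^2) < 1e-18, 0,
                 atan2(hd[, 1] * acc[, 2] - hd[, 2] * acc[, 1],
                       hd[, 1] * acc[, 1] + hd[, 2] * acc[, 2]))
  tx <- tpos[1] - pos[, 1]; ty <- tpos[2] - pos[, 2]
  th_t <- atan2(hd[, 1] * ty - hd[, 2] * tx, hd[, 1] * tx + hd[, 2] * ty)
  if (sigma > 0) {
    th_n <- apply_sensor_noise(th_n, sigma)
    th_t <- apply_sensor_noise(th_t, sigma)
  }
  list(percept = 3L * discretize_angle(th_n) + discretize_angle(th_t),
       theta_neighbor = th_n, theta_target = th_t)
}

# Cumulative row-normalized probability matrix of a policy weight matrix.
cumprob_rows <- function(h) {
  p <- h / rowSums(h)
  m <- ncol(p)
  if (m > 1) for (jj in 2:m) p[, jj] <- p[, jj - 1] + p[, jj]
  p
}

# 0-based actions for each agent given cumulative rows and uniform draws.
pick_actions <- function(cum, percept, u) {
  rowSums(u > cum[percept + 1L, , drop = FALSE])
}

resolve_actor <- function(policy) {
  if (inherits(policy, "ps_policy")) {
    list(kind = "memory", h = policy$h, actions = policy$actions)
  } else if (inherits(policy, "ps_policy_table")) {
    list(kind = "table", h = policy$p, actions = policy$actions)
  } else if (is.function(policy)) {
    list(kind = "fixed", fn = policy)
  } else {
    stop("policy must be a ps_policy, ps_policy_table or a function",
         call. = FALSE)
  }
}

# ---- public single step ---------------------------------------------------

#' Advance the swarm by one synchronous step
#'
#' All agents perceive the same time-`t` snapshot, sample their steering
#' actions from the shared policy, rotate, and move forward one step
#' together; then the target advances by its velocity. With `learn = TRUE`
#' the per-agent glow matrices decay and mark the used edges, and the shared
#' memory absorbs the summed per-agent reward-weighted glow, floored at
#' `h_min`.
#'
#' @param state A [init_swarm()] state.
#' @param policy A [policy_memory()], [policy_table()] result, or a function
#'   `f(percepts)` mapping 0-based percept indices to 0-based action indices
#'   (a fixed scripted rule).
#' @param config A [swarm_config()].
#' @param weights A [reward_weights()].
#' @param learn Update the policy from this step's rewards?
#' @param glow Per-agent glow stack: n x (n_states * m) matrix (rows are
#'   agents, columns are state-action edges in state-major order). Created
#'   zeroed if `NULL` and `learn = TRUE`.
#' @param eta Glow decay parameter used when `learn = TRUE`.
#' @param gamma Forgetting rate: each learning update first relaxes every
#'   memory entry toward its initial value 1 by the factor `1 - gamma`
#'   before adding the reward-weighted glow. `gamma = 0` (the default of
#'   the low-level operations) is the purely additive rule; the training
#'   protocols use a small positive value, which bounds the memory and lets
#'   the action probabilities converge to deterministic rules (see the
#'   methods vignette).
#' @return List with `state` (advanced `ps_swarm`), `info` (tibble: agent,
#'   percept, action, angle_deg, r_dis, r_dir, r_total), `policy`, `glow`.
#' @export
env_step <- function(state, policy, config = swarm_config(),
                     weights = reward_weights(), learn = FALSE,
                     glow = NULL, eta = 0.1, gamma = 0) {
  stopifnot(inherits(state, "ps_swarm"), inherits(config, "ps_config"))
  actor <- resolve_actor(policy)
  if (learn && actor$kind != "memory") {
    stop("learning requires a ps_policy memory", call. = FALSE)
  }
  n <- nrow(state$positions)
  pc <- percepts_all(state$positions, state$headings, state$target,
                     config$k, config$sensor_noise_sigma)
  if (actor$kind == "fixed") {
    act <- as.integer(actor$fn(pc$percept))
    ang <- attr(policy, "angles")
    if (is.null(ang)) stop("a fixed policy function needs an 'angles' ",
                           "attribute giving the angle (deg) of each ",
                           "0-based action index", call. = FALSE)
    a_deg <- ang[act + 1L]
  } else {
    m <- ncol(actor$h)
    cum <- cumprob_rows(actor$h)
    act <- pick_actions(cum, pc$percept, stats::runif(n))
    a_deg <- actor$actions$angles[act + 1L]
  }
  hd2 <- turn(state$headings, a_deg)
  pos2 <- state$positions + config$speed * hd2
  tpos2 <- state$target + state$target_velocity
  rew <- compute_reward(state$positions, pos2, hd2, tpos2, weights,
                        prev_target = state$target)
  if (learn) {
    m <- ncol(actor$h)
    if (is.null(glow)) glow <- matrix(0, n, nrow(actor$h) * m)
    glow <- glow * (1 - eta)
    li <- cbind(seq_len(n), pc$percept * m + act + 1L)
    glow[li] <- glow[li] + 1
    hv <- as.vector(t(actor$h))
    hv <- hv - gamma * (hv - 1) + colSums(glow * rew$r_total)
    policy$h <- matrix(pmax(policy$h_min, hv), nrow(actor$h), m, byrow = TRUE,
                       dimnames = dimnames(policy$h))
  }
  state$positions <- pos2
  state$headings <- hd2
  state$target <- tpos2
  state$t <- state$t + 1L
  list(state = state,
       info = tibble::tibble(agent = seq_len(n), percept = pc$percept,
                             action = act, angle_deg = a_deg,
                             r_dis = rew$r_dis, r_dir = rew$r_dir,
                             r_total = rew$r_total),
       policy = policy,
       glow = glow)
}

# ---- episode runner -------------------------------------------------------

#' Run one full episode
#'
#' Runs the swarm from a fresh random initial state for up to
#' `config$max_steps` synchronous steps (stopping early at the first
#' centroid success if `config$stop_on_success`). The glow stack starts at
#' zero; with `learn = TRUE` the shared memory is updated every step and the
#' updated policy is returned. Per-step order parameters are always
#' recorded; the full per-agent trajectory only when `record_trajectory`.
#'
#' @inheritParams env_step
#' @param record_trajectory Also record per-agent poses, percepts and
#'   actions every `thin` steps.
#' @param thin Keep every `thin`-th step of the trajectory record.
#' @param state Optional pre-built initial [init_swarm()] state (drawn fresh
#'   when `NULL`).
#' @param engine `"cpp"` (compiled loop, the default for tabular policies)
#'   or `"r"` (reference interpreter loop). The two are written to draw
#'   random numbers in the same order from R's global stream and perform
#'   arithmetic in the same order, so they agree under a common seed; fixed
#'   rule functions and trajectory recording always use the R loop.
#' @return Object of class `ps_episode`: list with `metrics` (tibble: t,
#'   polarization, elongation, centroid_x, centroid_y, dist_to_target),
#'   `trajectory` (tibble or NULL), `policy`, `success`, `hit_step`,
#'   `steps`, `total_reward`.
#' @export
run_episode <- function(policy, config = swarm_config(),
                        weights = reward_weights(), learn = FALSE,
                        eta = 0.1, gamma = 0, record_trajectory = FALSE,
                        thin = 1L, state = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "ps_config"))
  engine <- match.arg(engine)
  actor <- resolve_actor(policy)
  if (learn && actor$kind != "memory") {
    stop("learning requires a ps_policy memory", call. = FALSE)
  }
  if (is.null(state)) state <- init_swarm(config)
  if (engine == "cpp" && actor$kind != "fixed" && !record_trajectory) {
    return(run_episode_compiled(policy, actor, config, weights, learn, eta,
                                gamma, state))
  }
  n <- nrow(state$positions)
  pos <- state$positions; hd <- state$headings
  tpos <- state$target; tvel <- state$target_velocity
  speed <- config$speed; k <- config$k; sigma <- config$sensor_noise_sigma
  fixed <- actor$kind == "fixed"
  if (!fixed) {
    m <- ncol(actor$h)
    n_states <- nrow(actor$h)
    hv <- as.vector(t(actor$h))
    angles <- actor$actions$angles
  } else {
    ang <- attr(policy, "angles")
    if (is.null(ang)) stop("a fixed policy function needs an 'angles' ",
                           "attribute", call. = FALSE)
  }
  glowm <- if (learn) matrix(0, n, n_states * m) else NULL
  max_steps <- config$max_steps
  op <- oe <- dtt <- cx <- cy <- numeric(max_steps)
  traj <- if (record_trajectory) vector("list", max_steps %/% thin + 1L) else NULL
  cen_prev <- colMeans(pos)
  dir_cur <- colMeans(hd)
  dir_cur <- if (sqrt(sum(dir_cur^2)) >= 1e-9) dir_cur / sqrt(sum(dir_cur^2)) else c(1, 0)
  hit <- NA_integer_
  total_reward <- 0
  t <- 0L
  while (t < max_steps) {
    t <- t + 1L
    pc <- percepts_all(pos, hd, tpos, k, sigma)
    if (fixed) {
      act <- as.integer(actor$fn(pc$percept))
      a_deg <- ang[act + 1L]
    } else {
      cum <- cumprob_rows(matrix(hv, n_states, m, byrow = TRUE))
      act <- pick_actions(cum, pc$percept, stats::runif(n))
      a_deg <- angles[act + 1L]
    }
    ar <- a_deg * pi / 180
    ca <- cos(ar); sa <- sin(ar)
    hd2 <- cbind(ca * hd[, 1] - sa * hd[, 2], sa * hd[, 1] + ca * hd[, 2])
    pos2 <- pos + speed * hd2
    tpos2 <- tpos + tvel
    d0 <- sqrt((tpos[1] - pos[, 1])^2 + (tpos[2] - pos[, 2])^2)
    tx <- tpos2[1] - pos2[, 1]; ty <- tpos2[2] - pos2[, 2]
    d1 <- sqrt(tx^2 + ty^2)
    r_tot <- weights$distance * (d0 - d1) +
      weights$direction * pmax(0, (hd2[, 1] * tx + hd2[, 2] * ty) / pmax(d1, 1e-12))
    total_reward <- total_reward + sum(r_tot)
    if (learn) {
      glowm <- glowm * (1 - eta)
      li <- cbind(seq_len(n), pc$percept * m + act + 1L)
      glowm[li] <- glowm[li] + 1
      hv <- pmax(policy$h_min, hv - gamma * (hv - 1) + colSums(glowm * r_tot))
    }
    pos <- pos2; hd <- hd2; tpos <- tpos2
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
    if (record_trajectory && (t %% thin == 0L)) {
      traj[[t %/% thin]] <- tibble::tibble(
        t = t, agent_id = seq_len(n), x = pos[, 1], y = pos[, 2],
        heading_x = hd[, 1], heading_y = hd[, 2],
        percept = pc$percept, action = act)
    }
    if (is.na(hit) && dtt[t] <= config$success_radius) {
      hit <- t
      if (config$stop_on_success) break
    }
  }
  if (learn) {
    policy$h <- matrix(hv, n_states, m, byrow = TRUE,
                       dimnames = dimnames(policy$h))
  }
  keep <- seq_len(t)
  structure(list(
    metrics = tibble::tibble(t = keep, polarization = op[keep],
                             elongation = oe[keep], centroid_x = cx[keep],
                             centroid_y = cy[keep],
                             dist_to_target = dtt[keep]),
    trajectory = if (record_trajectory) dplyr::bind_rows(traj) else NULL,
    policy = policy,
    success = !is.na(hit),
    hit_step = hit,
    steps = t,
    total_reward = total_reward),
    class = "ps_episode")
}

run_episode_compiled <- function(policy, actor, config, weights, learn, eta,
                                 gamma, state) {
  h <- actor$h
  res <- .ps_episode_engine(
    state$positions, state$headings, state$target, state$target_velocity,
    as.vector(t(h)), nrow(h), ncol(h), actor$actions$angles,
    config$k, config$sensor_noise_sigma, config$speed, config$max_steps,
    config$success_radius, config$stop_on_success, learn, eta, gamma,
    if (inherits(policy, "ps_policy")) policy$h_min else 0.01,
    weights$distance, weights$direction)
  if (learn) {
    policy$h <- matrix(res$hv, nrow(h), ncol(h), byrow = TRUE,
                       dimnames = dimnames(policy$h))
  }
  keep <- seq_len(res$steps)
  structure(list(
    metrics = tibble::tibble(t = keep,
                             polarization = res$polarization[keep],
                             elongation = res$elongation[keep],
                             centroid_x = res$centroid_x[keep],
                             centroid_y = res$centroid_y[keep],
                             dist_to_target = res$dist_to_target[keep]),
    trajectory = NULL,
    policy = policy,
    success = !is.na(res$hit),
    hit_step = res$hit,
    steps = res$steps,
    total_reward = res$total_reward),
    class = "ps_episode")
}

#' @export
print.ps_episode <- function(x, ...) {
  cat("<ps_episode> ", x$steps, " steps; success = ", x$success,
      if (!is.na(x$hit_step)) paste0(" (step ", x$hit_step, ")") else "",
      "; peak elongation = ", round(max(x$metrics$elongation), 2),
      "\n", sep = "")
  invisible(x)
}
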