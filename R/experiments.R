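#' Training and evaluation protocol bundles
#'
#' Collects everything a training run needs: the action space, environment
#' configuration, reward weights, glow and forgetting parameters and episode
#' counts. Two ready-made scales are provided. `"full"` is the reference
#' protocol: target (3000, 3000), 5000 episodes of 10,000 steps. `"desk"`
#' keeps the reference geometry (the queue needs the full transit length to
#' develop; see the methods vignette) but shortens episodes to 6,000 steps
#' and trains for 1,200 episodes, which is where the desk learning curve
#' plateaus. Episodes always run their full length: the post-arrival phase
#' -- where wrong turns are punished hardest -- is a strong teacher during
#' training, and fixed-length evaluation keeps the arrival dynamics in the
#' recorded series (success is still detected from the centroid-target
#' distance).
#'
#' @param scale `"desk"` or `"full"`.
#' @param ... Overrides for any element of the returned list.
#' @return A list with elements `actions`, `train_config`, `eval_config`,
#'   `weights`, `eta`, `h_min`, `episodes`, `eval_episodes`.
#' @export
navigation_protocol <- function(scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  base <- if (scale == "full") {
    list(target = c(3000, 3000), max_steps = 10000L, episodes = 5000L,
         eval_episodes = 30L)
  } else {
    list(target = c(3000, 3000), max_steps = 6000L, episodes = 1200L,
         eval_episodes = 10L)
  }
  proto <- list(
    actions = action_space(15, 2),
    train_config = swarm_config(target = base$target,
                                max_steps = base$max_steps,
                                stop_on_success = FALSE),
    eval_config = swarm_config(target = base$target,
                               max_steps = base$max_steps,
                               stop_on_success = FALSE),
    weights = reward_weights(0.5, 0.5),
    eta = 0.1,
    gamma = 1e-4,
    h_min = 0.01,
    episodes = base$episodes,
    eval_episodes = base$eval_episodes)
  utils::modifyList(proto, list(...))
}

#' Train the shared policy memory
#'
#' Runs `episodes` consecutive training episodes. The shared memory
#' persists across episodes (each episode starts from the previous
#' episode's memory); the glow resets to zero at every episode start. The
#' learning curve records, per episode, the cumulative group reward and
#' the policy's average entropy and certainty.
#'
#' @param episodes Number of training episodes.
#' @param config A [swarm_config()] for training episodes.
#' @param weights A [reward_weights()].
#' @param actions An [action_space()].
#' @param eta Glow decay parameter.
#' @param gamma Forgetting rate of the memory update (see
#'   [update_experience()]); the protocol default is a small positive value
#'   so that training converges to deterministic rules.
#' @param h_min Memory floor.
#' @param policy Optional starting [policy_memory()] (fresh uniform memory
#'   when `NULL`).
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return Object of class `ps_fit`: list with `policy`, `curve` (tibble:
#'   episode, total_reward, avg_entropy, avg_certainty, steps), `config`,
#'   `weights`, `eta`.
#' @export
train_policy <- function(episodes = 300L, config = swarm_config(),
                         weights = reward_weights(),
                         actions = action_space(), eta = 0.1, gamma = 1e-4,
                         h_min = 0.01, policy = NULL, seed = NULL) {
  stopifnot(episodes >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(policy)) policy <- policy_memory(actions, h_min = h_min)
  episodes <- as.integer(episodes)
  curve <- vector("list", episodes)
  ep <- 0L
  while (ep < episodes) {
    ep <- ep + 1L
    run <- run_episode(policy, config, weights, learn = TRUE, eta = eta,
                       gamma = gamma)
    policy <- run$policy
    curve[[ep]] <- tibble::tibble(
      episode = ep, total_reward = run$total_reward,
      avg_entropy = average_entropy(policy),
      avg_certainty = average_certainty(policy),
      steps = run$steps)
  }
  structure(list(policy = policy,
                 curve = if (episodes > 0) dplyr::bind_rows(curve) else
                   tibble::tibble(episode = integer(), total_reward = numeric(),
                                  avg_entropy = numeric(),
                                  avg_certainty = numeric(),
                                  steps = integer()),
                 config = config, weights = weights, eta = eta),
            class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat("<ps_fit> ", nrow(x$curve), " training episodes\n", sep = "")
  print(x$policy)
  invisible(x)
}

#' @export
tidy.ps_fit <- function(x, ...) tidy(x$policy, ...)

#' @export
glance.ps_fit <- function(x, ...) {
  g <- glance(x$policy, ...)
  g$episodes <- nrow(x$curve)
  g$final_total_reward <- if (nrow(x$curve)) x$curve$total_reward[nrow(x$curve)] else NA_real_
  g
}

#' Evaluate a frozen policy
#'
#' Runs evaluation episodes with learning off (the policy is untouched)
#' from fresh random initial conditions, and summarizes each episode:
#' success, first alignment step, maximum polarization within the first 100
#' steps, peak elongation, and the steady-window means from
#' [summarize_metrics()].
#'
#' @param policy A trained [policy_memory()] (or `ps_fit`, or a fixed rule
#'   function as in [env_step()]).
#' @param config A [swarm_config()] for evaluation.
#' @param episodes Number of evaluation episodes.
#' @param alignment_threshold Polarization level defining alignment.
#' @param keep_series Keep every episode's full metrics tibble.
#' @param seed Optional integer seed.
#' @return Object of class `ps_eval`: list with `episodes` (one row per
#'   episode), `aggregate` (one-row tibble of means and the success rate in
#'   percent), and `series` (list of metrics tibbles or `NULL`).
#' @export
evaluate_policy <- function(policy, config = swarm_config(), episodes = 10L,
                            alignment_threshold = 0.9, keep_series = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(policy, "ps_fit")) policy <- policy$policy
  episodes <- as.integer(episodes)
  rows <- vector("list", episodes)
  series <- if (keep_series) vector("list", episodes) else NULL
  for (i in seq_len(episodes)) {
    run <- run_episode(policy, config, learn = FALSE)
    sm <- summarize_metrics(run$metrics, alignment_threshold,
                            config$success_radius)
    sm$episode <- i
    sm$max_polarization_100 <-
      max(run$metrics$polarization[seq_len(min(100L, run$steps))])
    rows[[i]] <- sm
    if (keep_series) series[[i]] <- run$metrics
  }
  eps <- dplyr::bind_rows(rows) |>
    dplyr::relocate("episode")
  agg <- tibble::tibble(
    episodes = episodes,
    success_rate = 100 * mean(eps$success),
    mean_hit_step = mean(eps$hit_step, na.rm = TRUE),
    mean_alignment_step = mean(eps$alignment_step, na.rm = TRUE),
    mean_peak_elongation = mean(eps$peak_elongation),
    mean_polarization = mean(eps$mean_polarization),
    mean_max_polarization_100 = mean(eps$max_polarization_100))
  structure(list(episodes = eps, aggregate = agg, series = series),
            class = "ps_eval")
}

#' @export
print.ps_eval <- function(x, ...) {
  cat("<ps_eval> ", nrow(x$episodes), " evaluation episodes; success rate ",
      x$aggregate$success_rate, "%\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' @export
glance.ps_eval <- function(x, ...) x$aggregate

train_and_score <- function(m, delta_theta, episodes, train_config,
                            eval_config, weights, eta, gamma, h_min,
                            eval_episodes, alignment_threshold = 0.9) {
  fit <- train_policy(episodes, train_config, weights,
                      action_space(m, delta_theta), eta, gamma, h_min)
  ev <- evaluate_policy(fit$policy, eval_config, eval_episodes,
                        alignment_threshold)
  tibble::tibble(
    avg_certainty = average_certainty(fit$policy),
    avg_entropy = average_entropy(fit$policy),
    avg_polarization = mean(ev$episodes$mean_polarization),
    max_elongation = mean(ev$episodes$peak_elongation),
    success_rate = ev$aggregate$success_rate)
}

#' Action-granularity sensitivity sweep
#'
#' Trains and evaluates one policy per (m, delta_theta) setting and
#' tabulates the microscopic (certainty, entropy) and macroscopic
#' (polarization, elongation) outcomes. The default settings hold the
#' maximum steering magnitude near 14 degrees while varying the number of
#' actions, probing the non-monotonic effect of control granularity:
#' too-coarse steering cannot form a queue, too-fine steering cannot be
#' learned in the episode budget.
#'
#' @param settings Tibble/data frame with columns `m` and `delta_theta`.
#' @param protocol A [navigation_protocol()] bundle (episode counts,
#'   configs, weights).
#' @param seed Optional integer seed.
#' @return Tibble with one row per setting: `m`, `delta_theta`,
#'   `avg_certainty`, `avg_entropy`, `avg_polarization`, `max_elongation`,
#'   `success_rate`.
#' @export
sweep_granularity <- function(settings = granularity_settings(),
                              protocol = navigation_protocol("desk"),
                              seed = NULL) {
  stopifnot(all(c("m", "delta_theta") %in% names(settings)))
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap(as.data.frame(settings)[c("m", "delta_theta")],
              function(m, delta_theta) {
                res <- train_and_score(m, delta_theta, protocol$episodes,
                                       protocol$train_config,
                                       protocol$eval_config,
                                       protocol$weights, protocol$eta,
                                       protocol$gamma, protocol$h_min,
                                       protocol$eval_episodes)
                dplyr::bind_cols(tibble::tibble(m = m,
                                                delta_theta = delta_theta),
                                 res)
              }) |>
    dplyr::bind_rows()
}

#' The reference granularity settings
#'
#' Five (m, delta_theta) pairs spanning coarse to fine control at a fixed
#' maximum steering magnitude of about 14 degrees.
#'
#' @return Tibble with columns `m`, `delta_theta`.
#' @export
granularity_settings <- function() {
  tibble::tibble(m = c(5L, 11L, 15L, 19L, 29L),
                 delta_theta = c(7, 3, 2, 1.5, 1))
}

#' Reward-weight sensitivity sweep
#'
#' Trains and evaluates one policy per (lambda_d, lambda_r) pair.
#'
#' @param pairs Tibble/data frame with columns `lambda_d`, `lambda_r`.
#' @inheritParams sweep_granularity
#' @return Tibble with one row per pair plus the scored metrics.
#' @export
sweep_rewards <- function(pairs = reward_weight_pairs(),
                          protocol = navigation_protocol("desk"),
                          seed = NULL) {
  stopifnot(all(c("lambda_d", "lambda_r") %in% names(pairs)))
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap(as.data.frame(pairs)[c("lambda_d", "lambda_r")],
              function(lambda_d, lambda_r) {
                res <- train_and_score(protocol$actions$m,
                                       protocol$actions$delta_theta,
                                       protocol$episodes,
                                       protocol$train_config,
                                       protocol$eval_config,
                                       reward_weights(lambda_d, lambda_r),
                                       protocol$eta, protocol$gamma,
                                       protocol$h_min,
                                       protocol$eval_episodes)
                dplyr::bind_cols(tibble::tibble(lambda_d = lambda_d,
                                                lambda_r = lambda_r),
                                 res)
              }) |>
    dplyr::bind_rows()
}

#' The reference reward-weight pairs
#'
#' @return Tibble with columns `lambda_d`, `lambda_r`.
#' @export
reward_weight_pairs <- function() {
  tibble::tibble(lambda_d = c(0.1, 0.3, 0.5, 0.7, 0.9),
                 lambda_r = c(0.9, 0.7, 0.5, 0.3, 0.1))
}

#' Sensory-noise robustness suite
#'
#' Evaluates a frozen policy under increasing Gaussian sensory noise
#' applied to both perceived angles before discretization.
#'
#' @param policy Trained policy (or `ps_fit`).
#' @param config Evaluation [swarm_config()]; its `sensor_noise_sigma` is
#'   overridden per run.
#' @param sigmas Noise levels in degrees.
#' @param episodes Evaluation episodes per level.
#' @param seed Optional integer seed.
#' @return Tibble with one row per sigma: success rate, mean steady-window
#'   polarization, mean peak elongation, mean alignment step.
#' @export
noise_suite <- function(policy, config = swarm_config(),
                        sigmas = c(0, 10, 20, 30), episodes = 10L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(policy, "ps_fit")) policy <- policy$policy
  purrr::map(sigmas, function(sg) {
    cfg <- config
    cfg$sensor_noise_sigma <- sg
    ev <- evaluate_policy(policy, cfg, episodes)
    tibble::tibble(sigma = sg,
                   success_rate = ev$aggregate$success_rate,
                   mean_polarization = ev$aggregate$mean_polarization,
                   mean_peak_elongation = ev$aggregate$mean_peak_elongation,
                   mean_alignment_step = ev$aggregate$mean_alignment_step)
  }) |>
    dplyr::bind_rows()
}

#' Generalization suite: moving target, rotated targets, larger groups
#'
#' Stress-tests a frozen policy in conditions it was not trained on:
#' a target moving at constant velocity, targets rotated to the coordinate
#' axes at the same distance from the origin, and larger group sizes. The
#' policy is used unchanged in every scenario.
#'
#' @param policy Trained policy (or `ps_fit`).
#' @param config Evaluation [swarm_config()] of the training task; rotated
#'   targets keep its target distance.
#' @param dynamic_velocity Target velocity for the pursuit scenario.
#' @param sizes Group sizes for the scalability scenario.
#' @param episodes Evaluation episodes per scenario.
#' @param seed Optional integer seed.
#' @return Tibble with one row per scenario: `scenario`, `n`, `target_x`,
#'   `target_y`, success rate, mean polarization, mean peak elongation.
#' @export
generalization_suite <- function(policy, config = swarm_config(),
                                 dynamic_velocity = c(-0.35, 0.35),
                                 sizes = c(30L, 100L, 150L), episodes = 5L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(policy, "ps_fit")) policy <- policy$policy
  dist0 <- sqrt(sum(config$target^2))
  scen <- list(
    list(scenario = "dynamic_target", n = config$n, target = config$target,
         tvel = dynamic_velocity),
    list(scenario = "rotated_target_y", n = config$n,
         target = c(0, dist0), tvel = c(0, 0)),
    list(scenario = "rotated_target_x", n = config$n,
         target = c(dist0, 0), tvel = c(0, 0)))
  for (nn in sizes) {
    scen <- c(scen, list(list(scenario = paste0("scale_n", nn),
                              n = as.integer(nn), target = config$target,
                              tvel = c(0, 0))))
  }
  purrr::map(scen, function(sc) {
    cfg <- config
    cfg$n <- sc$n
    cfg$target <- sc$target
    cfg$target_velocity <- sc$tvel
    ev <- evaluate_policy(policy, cfg, episodes)
    tibble::tibble(scenario = sc$scenario, n = sc$n,
                   target_x = sc$target[1], target_y = sc$target[2],
                   success_rate = ev$aggregate$success_rate,
                   mean_polarization = ev$aggregate$mean_polarization,
                   mean_peak_elongation = ev$aggregate$mean_peak_elongation)
  }) |>
    dplyr::bind_rows()
}
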