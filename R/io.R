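#' Write / read a protocol configuration as YAML
#'
#' Serializes a [navigation_protocol()] bundle to a flat YAML file with
#' conventional keys (`group_size`, `topological_k`, `init_radius`,
#' `target`, `target_velocity`, `m`, `delta_theta_deg`, `eta`, `lambda_d`,
#' `lambda_r`, `episodes`, `max_steps`, `sigma_deg`, `success_radius`,
#' `seed`), and rebuilds the bundle from such a file.
#'
#' @param protocol A [navigation_protocol()] list.
#' @param path File path.
#' @param seed Optional seed recorded in the file.
#' @return `write_protocol_yaml` returns `path` invisibly;
#'   `read_protocol_yaml` returns a protocol list (with `$seed`).
#' @export
write_protocol_yaml <- function(protocol, path, seed = NULL) {
  cfg <- protocol$train_config
  out <- list(
    group_size = cfg$n,
    topological_k = cfg$k,
    init_radius = cfg$init_radius,
    speed = cfg$speed,
    target = as.numeric(protocol$eval_config$target),
    target_velocity = as.numeric(protocol$eval_config$target_velocity),
    m = protocol$actions$m,
    delta_theta_deg = protocol$actions$delta_theta,
    eta = protocol$eta,
    gamma = protocol$gamma,
    h_min = protocol$h_min,
    lambda_d = protocol$weights$distance,
    lambda_r = protocol$weights$direction,
    episodes = protocol$episodes,
    eval_episodes = protocol$eval_episodes,
    max_steps = cfg$max_steps,
    sigma_deg = protocol$eval_config$sensor_noise_sigma,
    success_radius = cfg$success_radius,
    eval_stop_on_success = protocol$eval_config$stop_on_success)
  if (!is.null(seed)) out$seed <- as.integer(seed)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  actions <- action_space(y$m, y$delta_theta_deg)
  mk <- function(stop_on_success) {
    swarm_config(n = y$group_size, k = y$topological_k,
                 init_radius = y$init_radius, speed = y$speed,
                 max_steps = y$max_steps, target = unlist(y$target),
                 target_velocity = unlist(y$target_velocity),
                 sensor_noise_sigma = y$sigma_deg,
                 success_radius = y$success_radius,
                 stop_on_success = stop_on_success)
  }
  list(actions = actions,
       train_config = mk(FALSE),
       eval_config = mk(isTRUE(y$eval_stop_on_success)),
       weights = reward_weights(y$lambda_d, y$lambda_r),
       eta = y$eta,
       gamma = y$gamma,
       h_min = y$h_min,
       episodes = y$episodes,
       eval_episodes = y$eval_episodes,
       seed = y$seed)
}
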