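# Shared fixtures: small deterministic swarm configurations and a cached
# desk-scale trained policy (training is the expensive step; several test
# files interrogate the same converged policy).

.psnav_cache <- new.env(parent = emptyenv())

# Desk-scale protocol used by the behavioural tests: same task as the
# package default desk protocol.
desk_proto <- function() navigation_protocol("desk")

# Train (once per test run) the desk-scale policy used by the emergence,
# interpretability and robustness tests.
trained_desk_policy <- function() {
  if (is.null(.psnav_cache$desk_policy)) {
    proto <- desk_proto()
    fit <- train_policy(proto$episodes, proto$train_config, proto$weights,
                        proto$actions, eta = proto$eta, gamma = proto$gamma,
                        h_min = proto$h_min, seed = 4242L)
    .psnav_cache$desk_policy <- fit$policy
  }
  .psnav_cache$desk_policy
}

# A hand-written ideal navigation rule: ignore neighbors, steer toward the
# target at the sharpest available angle (actions are 0-based).
ideal_rule <- function(actions = action_space()) {
  m <- actions$m
  structure(function(percepts) {
    s_t <- percepts %% 3L
    ifelse(s_t == 1L, (m - 1L) %/% 2L,        # aligned -> straight
           ifelse(s_t == 2L, m - 1L, 0L))     # left -> hardest left, right -> hardest right
  }, angles = actions$angles)
}

# Deterministic swarm state builder for geometry tests.
swarm_state_at <- function(positions, headings, target = c(1000, 0),
                           target_velocity = c(0, 0)) {
  structure(list(positions = rbind(positions),
                 headings = rbind(headings),
                 t = 0L, target = as.numeric(target),
                 target_velocity = as.numeric(target_velocity)),
            class = "ps_swarm")
}

rotate2 <- function(xy, angle_rad) {
  r <- matrix(c(cos(angle_rad), sin(angle_rad),
                -sin(angle_rad), cos(angle_rad)), 2, 2)
  xy %*% t(r)
}
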