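#' Shared long-term policy memory (H-matrix)
#'
#' The long-term memory of the projective-simulation agent: a nonnegative
#' table of experience values `h[s, a]` over percept states and actions.
#' A fresh memory is uniform (all entries 1), which yields a uniform random
#' policy. Row-normalizing the table gives the action probabilities
#' `P(a | s) = h[s, a] / sum_k h[s, k]`. All agents of a swarm share one
#' such memory.
#'
#' Entries are floored at `h_min > 0` after every update so rows always
#' normalize; negative rewards can therefore never drive a weight to zero.
#'
#' @param actions A [action_space()] object.
#' @param h_min Positive floor applied to every entry after updates.
#' @return An object of class `ps_policy`: list with `h` (n_states x m
#'   matrix), `actions`, `h_min`.
#' @examples
#' pol <- policy_memory(action_space(15, 2))
#' all(pol$h == 1)
#' @export
policy_memory <- function(actions = action_space(), h_min = 0.01) {
  stopifnot(inherits(actions, "ps_action_space"), h_min > 0)
  h <- matrix(1, nrow = actions$n_states, ncol = actions$m,
              dimnames = list(state = paste0("s", seq_len(actions$n_states) - 1L),
                              action = paste0("a", seq_len(actions$m) - 1L)))
  structure(list(h = h, actions = actions, h_min = h_min), class = "ps_policy")
}

validate_policy <- function(policy) {
  stopifnot(inherits(policy, "ps_policy"))
  if (any(policy$h < policy$h_min - 1e-12)) {
    stop("policy memory has entries below its floor h_min", call. = FALSE)
  }
  invisible(policy)
}

#' @export
print.ps_policy <- function(x, ...) {
  cat("<ps_policy> ", nrow(x$h), " states x ", ncol(x$h), " actions (",
      parameter_count(nrow(x$h), ncol(x$h)), " parameters), h_min = ",
      x$h_min, "\n", sep = "")
  g <- glance(x)
  cat("  avg entropy ", round(g$avg_entropy, 3), " bits, avg certainty ",
      round(g$avg_certainty, 3), "\n", sep = "")
  invisible(x)
}

#' Action-selection probabilities for one percept state
#'
#' Normalizes the memory row of the given percept: each action's probability
#' is its experience weight divided by the row sum. Scale-invariant in the
#' memory (multiplying a row by a constant changes nothing).
#'
#' @param policy A [policy_memory()] object.
#' @param percept Integer percept index, 0-based (0..n_states-1).
#' @return Numeric probability vector of length `m`, summing to 1.
#' @examples
#' pol <- policy_memory(action_space(3, 7))
#' pol$h[1, ] <- c(1, 1, 2)
#' action_probabilities(pol, 0)  # 0.25 0.25 0.50
#' @export
action_probabilities <- function(policy, percept) {
  stopifnot(inherits(policy, "ps_policy"), length(percept) == 1L,
            percept >= 0, percept <= nrow(policy$h) - 1L)
  row <- policy$h[percept + 1L, ]
  s <- sum(row)
  if (!(s > 0)) stop("memory row has non-positive sum", call. = FALSE)
  unname(row / s)
}

#' Sample an action index from a probability vector
#'
#' Draws one action with the given probabilities, the stochastic random-walk
#' step of the projective-simulation decision. Uses R's global random number
#' stream, so results are reproducible under [set.seed()].
#'
#' @param probabilities Probability vector over actions (sums to 1).
#' @param n Number of independent draws.
#' @return Integer vector of 0-based action indices, length `n`.
#' @export
sample_action <- function(probabilities, n = 1L) {
  stopifnot(is.numeric(probabilities), length(probabilities) >= 1L,
            all(probabilities >= 0),
            abs(sum(probabilities) - 1) < 1e-6)
  cum <- cumsum(probabilities)
  findInterval(stats::runif(n), cum) # 0-based: u < cum[1] -> 0
}

#' Short-term glow (eligibility) memory
#'
#' The per-agent short-term memory marking recently used (state, action)
#' edges. Every step all entries decay geometrically by the factor
#' `1 - eta`, and the edge used this step is incremented by 1. With repeated
#' activation an entry converges to the fixed point `1 / eta`; reward applied
#' through the glow therefore reaches back about `1 / eta` steps.
#'
#' @param actions An [action_space()] object.
#' @param eta Glow decay parameter in (0, 1]. Default 0.1.
#' @return Object of class `ps_glow`: list with `g` (matrix of zeros, same
#'   shape as the policy memory) and `eta`.
#' @export
glow_memory <- function(actions = action_space(), eta = 0.1) {
  stopifnot(inherits(actions, "ps_action_space"), eta > 0, eta <= 1)
  g <- matrix(0, nrow = actions$n_states, ncol = actions$m)
  structure(list(g = g, eta = eta), class = "ps_glow")
}

#' Decay the glow and mark the activated edge
#'
#' Applies one glow step: all entries are multiplied by `1 - eta`, then the
#' activated (percept, action) entry -- if any -- is incremented by 1.
#'
#' @param glow A [glow_memory()] object.
#' @param percept,action 0-based indices of the edge used this step, or both
#'   `NULL` for a step with no activation (pure decay).
#' @return The updated `ps_glow` object.
#' @export
update_glow <- function(glow, percept = NULL, action = NULL) {
  stopifnot(inherits(glow, "ps_glow"))
  glow$g <- glow$g * (1 - glow$eta)
  if (!is.null(percept) || !is.null(action)) {
    stopifnot(!is.null(percept), !is.null(action),
              percept >= 0, percept <= nrow(glow$g) - 1L,
              action >= 0, action <= ncol(glow$g) - 1L)
    glow$g[percept + 1L, action + 1L] <- glow$g[percept + 1L, action + 1L] + 1
  }
  glow
}

#' Reinforce the memory through the glow
#'
#' The learning rule of the long-term memory:
#' `h <- h - gamma * (h - 1) + reward * g`, elementwise, followed by the
#' floor at `h_min`. Edges that glow (were used recently) absorb the reward
#' in proportion to their glow, which propagates credit backward along the
#' action sequence. With the default `gamma = 0` the rule is purely
#' additive; a small positive forgetting rate `gamma` relaxes unused
#' entries toward their initial value 1, keeping the memory bounded so the
#' policy can converge to deterministic rules (the training protocols use
#' this; see the methods vignette).
#'
#' @param policy A [policy_memory()] object.
#' @param glow A [glow_memory()] object of matching shape.
#' @param reward Scalar total reward for this step.
#' @param gamma Forgetting rate in `[0, 1)`.
#' @return The updated `ps_policy`.
#' @export
update_experience <- function(policy, glow, reward, gamma = 0) {
  stopifnot(inherits(policy, "ps_policy"), inherits(glow, "ps_glow"),
            identical(dim(policy$h), dim(glow$g)), is.numeric(reward),
            length(reward) == 1L, gamma >= 0, gamma < 1)
  policy$h <- pmax(policy$h - gamma * (policy$h - 1) + reward * glow$g,
                   policy$h_min)
  policy
}

#' Full action-probability table of a policy
#'
#' Row-normalizes the whole memory into the readable state-action lookup
#' table `P(a | s)` -- the interpretable artifact of the model.
#'
#' @param policy A [policy_memory()] object.
#' @return Object of class `ps_policy_table`: list with `p` (matrix of
#'   probabilities, rows summing to 1) and `actions`.
#' @export
policy_table <- function(policy) {
  stopifnot(inherits(policy, "ps_policy"))
  p <- policy$h / rowSums(policy$h)
  structure(list(p = p, actions = policy$actions), class = "ps_policy_table")
}

as_policy_table <- function(x) {
  if (inherits(x, "ps_policy_table")) x else policy_table(x)
}

#' Average policy entropy in bits
#'
#' Shannon entropy (base 2) of each state's action distribution, averaged
#' uniformly over states, so each of the 9 perceptual configurations counts
#' equally -- conflict states are not washed out by how rarely they occur.
#' 0 bits means every state is deterministic; `log2(m)` means uniform.
#'
#' @param x A `ps_policy` or `ps_policy_table`.
#' @return Scalar entropy in bits.
#' @export
average_entropy <- function(x) {
  p <- as_policy_table(x)$p
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  mean(ent)
}

#' Average policy certainty
#'
#' Mean over states of the maximum action probability. 1 means every state
#' has a deterministic choice; `1/m` means uniform indifference.
#'
#' @inheritParams average_entropy
#' @return Scalar in `[1/m, 1]`.
#' @export
average_certainty <- function(x) {
  p <- as_policy_table(x)$p
  mean(apply(p, 1L, max))
}

#' Extract the per-state decision rules from a policy
#'
#' Reads the policy table row by row and reports, for each percept state, the
#' most probable action and whether the state has effectively converged to a
#' deterministic rule (max probability at or above `determinism_threshold`).
#' Ties in the argmax go to the smaller action index. Cue columns decode the
#' percept: 0 = cue object to the right, 1 = aligned, 2 = to the left.
#'
#' @param x A `ps_policy` or `ps_policy_table`.
#' @param determinism_threshold Probability above which a state counts as
#'   deterministic. Default 0.9.
#' @return A tibble with one row per state: `state`, `neighbor_cue`,
#'   `target_cue`, `action`, `angle_deg`, `probability`, `deterministic`.
#' @export
extract_rules <- function(x, determinism_threshold = 0.9) {
  tab <- as_policy_table(x)
  m <- tab$actions$m
  stopifnot(determinism_threshold > 1 / m, determinism_threshold <= 1)
  best <- unname(apply(tab$p, 1L, which.max))  # ties -> smaller index
  pmax_ <- tab$p[cbind(seq_len(nrow(tab$p)), best)]
  st <- seq_len(nrow(tab$p)) - 1L
  tibble::tibble(
    state = st,
    neighbor_cue = st %/% 3L,
    target_cue = st %% 3L,
    action = best - 1L,
    angle_deg = tab$actions$angles[best],
    probability = unname(pmax_),
    deterministic = unname(pmax_) >= determinism_threshold)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a policy into a long state-action-probability table
#'
#' @param x A `ps_policy`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `neighbor_cue`, `target_cue`,
#'   `action`, `angle_deg`, `h`, `probability`.
#' @export
tidy.ps_policy <- function(x, ...) {
  tab <- policy_table(x)
  n_s <- nrow(x$h); m <- ncol(x$h)
  st <- rep(seq_len(n_s) - 1L, times = m)
  ac <- rep(seq_len(m) - 1L, each = n_s)
  tibble::tibble(
    state = st,
    neighbor_cue = st %/% 3L,
    target_cue = st %% 3L,
    action = ac,
    angle_deg = x$actions$angles[ac + 1L],
    h = as.vector(x$h),
    probability = as.vector(tab$p)) |>
    dplyr::arrange(.data$state, .data$action)
}

#' @export
tidy.ps_policy_table <- function(x, ...) {
  n_s <- nrow(x$p); m <- ncol(x$p)
  st <- rep(seq_len(n_s) - 1L, times = m)
  ac <- rep(seq_len(m) - 1L, each = n_s)
  tibble::tibble(state = st, action = ac,
                 angle_deg = x$actions$angles[ac + 1L],
                 probability = as.vector(x$p)) |>
    dplyr::arrange(.data$state, .data$action)
}

#' One-row summary of a policy
#'
#' @param x A `ps_policy`.
#' @param determinism_threshold Passed to [extract_rules()].
#' @param ... Unused.
#' @return Tibble with `n_states`, `n_actions`, `n_parameters`,
#'   `avg_entropy`, `avg_certainty`, `n_deterministic`.
#' @export
glance.ps_policy <- function(x, determinism_threshold = 0.9, ...) {
  tab <- policy_table(x)
  tibble::tibble(
    n_states = nrow(x$h),
    n_actions = ncol(x$h),
    n_parameters = parameter_count(nrow(x$h), ncol(x$h)),
    avg_entropy = average_entropy(tab),
    avg_certainty = average_certainty(tab),
    n_deterministic = sum(extract_rules(tab, determinism_threshold)$deterministic))
}

#' Write / read a policy probability table as CSV
#'
#' The CSV has one row per percept state and one column per action; the
#' header names columns by their steering angle in degrees.
#'
#' @param x A `ps_policy` or `ps_policy_table`.
#' @param path File path.
#' @return `write_policy_csv` returns `path` invisibly; `read_policy_csv`
#'   returns a `ps_policy_table`.
#' @export
write_policy_csv <- function(x, path) {
  tab <- as_policy_table(x)
  df <- as.data.frame(tab$p)
  names(df) <- paste0("deg_", tab$actions$angles)
  readr::write_csv(tibble::as_tibble(cbind(state = seq_len(nrow(df)) - 1L, df)),
                   path)
  invisible(path)
}

#' @rdname write_policy_csv
#' @param delta_theta Steering unit used to rebuild the action space on read.
#' @export
read_policy_csv <- function(path, delta_theta = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("state" %in% names(df))
  p <- as.matrix(df[setdiff(names(df), "state")])
  angs <- as.numeric(sub("^deg_", "", colnames(p)))
  if (is.null(delta_theta)) {
    delta_theta <- if (ncol(p) > 1) diff(angs)[1] else 1
  }
  structure(list(p = unname(p),
                 actions = action_space(ncol(p), delta_theta,
                                        n_states = nrow(p))),
            class = "ps_policy_table")
}

#' Write extracted rules as JSON
#'
#' @param rules Tibble from [extract_rules()].
#' @param path File path.
#' @export
write_rules_json <- function(rules, path) {
  out <- dplyr::rename(rules, action_index = "action")
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
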