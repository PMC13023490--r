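#' Discrete symmetric steering action space
#'
#' Builds the set of `m` discrete steering angles an agent can choose from.
#' The angles are symmetric about zero, `a_k = (k - (m - 1) / 2) * delta_theta`
#' for `k = 0, ..., m - 1`, so the middle action is straight-ahead (0 degrees),
#' negative angles are right turns and positive angles are left turns. The
#' maximum steering magnitude is `((m - 1) / 2) * delta_theta`.
#'
#' @param m Odd positive integer, number of actions. Default 15.
#' @param delta_theta Basic steering unit in degrees. Default 2.
#' @param n_states Number of discrete percept states the memory is indexed by.
#'   Default 9 (3 neighbor cues x 3 target cues).
#' @return An object of class `ps_action_space`: a list with elements `m`,
#'   `delta_theta`, `angles` (degrees) and `n_states`.
#' @examples
#' acts <- action_space(15, 2)
#' acts$angles          # -14, -12, ..., 0, ..., 12, 14
#' max(abs(acts$angles))  # 14
#' @export
action_space <- function(m = 15L, delta_theta = 2, n_states = 9L) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1, m %% 2 == 1,
            is.numeric(delta_theta), length(delta_theta) == 1L, delta_theta > 0,
            is.numeric(n_states), length(n_states) == 1L, n_states >= 1)
  m <- as.integer(m)
  structure(
    list(m = m,
         delta_theta = as.numeric(delta_theta),
         angles = (seq_len(m) - 1L - (m - 1L) / 2) * delta_theta,
         n_states = as.integer(n_states)),
    class = "ps_action_space")
}

#' @export
print.ps_action_space <- function(x, ...) {
  cat("<ps_action_space> m =", x$m, ", delta_theta =", x$delta_theta,
      "deg, max turn =", max(abs(x$angles)), "deg\n")
  invisible(x)
}

#' Number of free parameters of a tabular policy
#'
#' The tabular memory stores one experience value per (state, action) pair,
#' so its parameter count is simply the product of the two set sizes. For the
#' default 9-state, 15-action model this is 135 numbers -- the entire policy.
#'
#' @param state_count Number of percept states.
#' @param action_count Number of actions.
#' @return Integer product.
#' @examples
#' parameter_count(9, 15)  # 135
#' @export
parameter_count <- function(state_count, action_count) {
  stopifnot(state_count >= 1, action_count >= 1)
  as.integer(state_count) * as.integer(action_count)
}
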