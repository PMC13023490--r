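# The tabular projective-simulation memory: action probabilities, glow,
# experience updates and the interpretability readouts.

test_that("action space is symmetric with a straight middle action", {
  for (setting in list(c(15, 2), c(5, 7), c(29, 1))) {
    acts <- action_space(setting[1], setting[2])
    expect_length(acts$angles, setting[1])
    expect_identical(acts$angles[(setting[1] + 1) / 2], 0)
    expect_equal(acts$angles, -rev(acts$angles))
    expect_equal(max(abs(acts$angles)), (setting[1] - 1) / 2 * setting[2])
  }
  expect_error(action_space(14, 2))   # even m has no straight action
})

test_that("action probabilities are the normalized memory row", {
  pol <- policy_memory(action_space(15, 2))
  expect_equal(action_probabilities(pol, 0), rep(1 / 15, 15))

  pol3 <- policy_memory(action_space(3, 7))
  pol3$h[5, ] <- c(1, 1, 2)
  expect_equal(action_probabilities(pol3, 4), c(0.25, 0.25, 0.5))

  pol$h[1, ] <- c(1e6, rep(1, 14))
  expect_equal(action_probabilities(pol, 0)[1], 1e6 / (1e6 + 14))
  expect_error(action_probabilities(pol, 9))
  expect_error(action_probabilities(pol, -1))
})

test_that("probabilities are invariant to rescaling the memory", {
  pol <- policy_memory(action_space(7, 2))
  set.seed(1)
  pol$h[] <- runif(length(pol$h), 0.5, 4)
  p0 <- policy_table(pol)$p
  for (c_scale in c(1e-3, 2, 1e4)) {
    scaled <- pol
    scaled$h <- pol$h * c_scale
    expect_equal(policy_table(scaled)$p, p0)
  }
  expect_true(all(abs(rowSums(p0) - 1) < 1e-9))
})

test_that("sampling follows the distribution and is seed-reproducible", {
  onehot <- c(rep(0, 7), 1, rep(0, 7))
  expect_identical(unique(sample_action(onehot, 50)), 7L)

  m <- 15
  n <- 1e5
  set.seed(99)
  draws <- sample_action(rep(1 / m, m), n)
  freq <- tabulate(draws + 1L, m) / n
  # joint bound over the m bins (4 sigma per bin keeps the family-wise
  # false-failure rate well under 0.1%)
  band <- 4 * sqrt((1 / m) * (1 - 1 / m) / n)
  expect_true(all(abs(freq - 1 / m) < band + 1e-12))
  expect_gt(chisq.test(tabulate(draws + 1L, m))$p.value, 1e-4)

  set.seed(7); a <- sample_action(rep(1 / m, m), 100)
  set.seed(7); b <- sample_action(rep(1 / m, m), 100)
  expect_identical(a, b)
  expect_error(sample_action(c(0.5, 0.2)))  # not normalized
})

test_that("glow decays everywhere and marks the activated edge", {
  g <- glow_memory(action_space(15, 2), eta = 0.1)
  g1 <- update_glow(g, 3, 5)
  expect_equal(g1$g[4, 6], 1)
  expect_equal(sum(g1$g), 1)

  g2 <- update_glow(g1)            # no activation: pure decay
  expect_equal(g2$g[4, 6], 0.9)

  # repeated activation of one edge converges to the 1/eta fixed point
  for (i in 1:400) g <- update_glow(g, 3, 5)
  expect_equal(g$g[4, 6], 1 / 0.1, tolerance = 1e-8)
})

test_that("glow is bounded by 1/eta under any activation schedule", {
  set.seed(42)
  for (eta in c(0.05, 0.1, 0.5, 1)) {
    g <- glow_memory(action_space(5, 7), eta = eta)
    for (i in 1:300) {
      if (runif(1) < 0.8) {
        g <- update_glow(g, sample(0:8, 1), sample(0:4, 1))
      } else {
        g <- update_glow(g)
      }
      expect_true(all(g$g >= 0))
      expect_true(all(g$g <= 1 / eta + 1e-12))
    }
  }
})

test_that("with eta = 1 the glow is the indicator of the last activation", {
  g <- glow_memory(action_space(5, 7), eta = 1)
  g <- update_glow(g, 2, 3)
  g <- update_glow(g, 7, 0)
  expected <- matrix(0, 9, 5)
  expected[8, 1] <- 1
  expect_equal(g$g, expected)
})

test_that("experience update adds reward-weighted glow with a floor", {
  acts <- action_space(5, 7)
  pol <- policy_memory(acts, h_min = 0.01)
  g <- glow_memory(acts)

  expect_equal(update_experience(pol, g, 0)$h, pol$h)   # zero reward

  g$g[2, 2] <- 1
  expect_equal(update_experience(pol, g, 0.5)$h[2, 2], 1.5)

  g$g[2, 2] <- 2
  expect_equal(update_experience(pol, g, -1)$h[2, 2], 0.01)  # clamped
})

test_that("a positive reward on a glowing edge raises that action's probability", {
  set.seed(3)
  for (rep in 1:20) {
    acts <- action_space(7, 2)
    pol <- policy_memory(acts)
    pol$h[] <- runif(length(pol$h), 0.5, 3)
    s <- sample(0:8, 1); a <- sample(0:6, 1)
    g <- glow_memory(acts)
    g$g[s + 1, a + 1] <- runif(1, 0.1, 10)
    p_before <- action_probabilities(pol, s)[a + 1]
    p_after <- action_probabilities(update_experience(pol, g, 0.7), s)[a + 1]
    expect_gt(p_after, p_before)
  }
})

test_that("entropy and certainty agree on their closed forms and duality", {
  acts <- action_space(15, 2)
  pol <- policy_memory(acts)
  expect_equal(average_entropy(pol), log2(15))
  expect_equal(average_certainty(pol), 1 / 15)

  onehot <- policy_memory(acts)
  onehot$h[] <- 0.01
  onehot$h[cbind(1:9, c(1:9, 1)[1:9])] <- 1e9
  expect_equal(average_entropy(onehot), 0, tolerance = 1e-6)
  expect_equal(average_certainty(onehot), 1, tolerance = 1e-6)

  # a (1/2, 1/2) row contributes exactly one bit
  tab <- policy_table(pol)
  tab$p[1, ] <- c(0.5, 0.5, rep(0, 13))
  expect_equal(-sum(ifelse(tab$p[1, ] > 0,
                           tab$p[1, ] * log2(tab$p[1, ]), 0)), 1)

  # mixed table: 6 one-hot rows + 3 uniform rows
  mix <- policy_table(policy_memory(acts))
  mix$p[1:6, ] <- 0
  mix$p[cbind(1:6, 1:6)] <- 1
  expect_equal(average_certainty(mix), (6 + 3 / 15) / 9)
})

test_that("rule extraction flags deterministic states and breaks ties low", {
  acts <- action_space(15, 2)
  pol <- policy_memory(acts)
  pol$h[3, ] <- 1e-9
  pol$h[3, 10] <- 1               # state 2 -> action 9, near-one-hot
  rules <- extract_rules(pol, determinism_threshold = 0.9)
  expect_equal(nrow(rules), 9)
  r2 <- rules[rules$state == 2, ]
  expect_equal(r2$action, 9L)
  expect_equal(r2$angle_deg, 4)
  expect_true(r2$deterministic)
  expect_equal(r2$neighbor_cue, 0L)
  expect_equal(r2$target_cue, 2L)
  expect_false(any(rules$deterministic[rules$state != 2]))  # uniform rows

  # threshold is compared with >=
  tab <- policy_table(policy_memory(action_space(3, 7)))
  tab$p[1, ] <- c(0.91, 0.05, 0.04)
  expect_true(extract_rules(tab, 0.91)$deterministic[1])
  expect_false(extract_rules(tab, 0.92)$deterministic[1])

  # exact tie between two actions goes to the smaller index
  tab$p[2, ] <- c(0.1, 0.45, 0.45)
  expect_equal(extract_rules(tab, 0.9)$action[2], 1L)
})

test_that("policy round-trips through CSV and rules through JSON", {
  set.seed(11)
  pol <- policy_memory(action_space(15, 2))
  pol$h[] <- runif(length(pol$h), 0.5, 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_policy_csv(pol, tmp)
  back <- read_policy_csv(tmp)
  expect_equal(back$p, unname(policy_table(pol)$p), tolerance = 1e-12)
  expect_equal(back$actions$angles, pol$actions$angles)

  tmpj <- withr::local_tempfile(fileext = ".json")
  write_rules_json(extract_rules(pol), tmpj)
  rj <- jsonlite::read_json(tmpj, simplifyVector = TRUE)
  expect_equal(nrow(rj), 9)
  expect_setequal(names(rj), c("state", "neighbor_cue", "target_cue",
                               "action_index", "angle_deg", "probability",
                               "deterministic"))
})

test_that("tidy and glance expose the policy in long and summary form", {
  pol <- policy_memory(action_space(15, 2))
  td <- tidy(pol)
  expect_equal(nrow(td), 135)
  expect_equal(sum(td$probability), 9)
  g <- glance(pol)
  expect_equal(g$n_parameters, 135L)
  expect_equal(g$avg_entropy, log2(15))
  expect_equal(g$n_deterministic, 0L)
})
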