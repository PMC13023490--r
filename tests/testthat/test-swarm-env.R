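# Environment contracts: initial conditions, rewards, the synchronous step
# and whole-episode behavior.

test_that("initial swarm is disk-uniform with unbiased headings", {
  cfg <- swarm_config(n = 10000, k = 6, init_radius = 300)
  set.seed(314)
  sw <- init_swarm(cfg)
  r2 <- rowSums(sw$positions^2)
  expect_true(all(r2 <= 300^2 + 1e-9))
  # disk-uniform: E[r^2] = R^2 / 2; SE of the mean is ~ R^2/(2*sqrt(n))
  expect_lt(abs(mean(r2) - 300^2 / 2) / (300^2 / 2), 0.03)
  expect_equal(rowSums(sw$headings^2), rep(1, 10000))

  # small-swarm initial polarization is O(1/sqrt(n))
  cfg30 <- swarm_config(n = 30)
  set.seed(1)
  pols <- replicate(200, polarization(init_swarm(cfg30)$headings))
  expect_gt(mean(pols < 0.4), 0.95)

  set.seed(7); a <- init_swarm(cfg30)
  set.seed(7); b <- init_swarm(cfg30)
  expect_identical(a, b)
})

test_that("composite reward matches its hand-evaluated cases", {
  w <- reward_weights(0.5, 0.5)
  far <- c(1e9, 0)
  # one unit step straight at a far target
  r <- compute_reward(c(0, 0), c(1, 0), c(1, 0), far, w)
  expect_equal(r$r_dis, 1, tolerance = 1e-6)
  expect_equal(r$r_dir, 1, tolerance = 1e-9)
  expect_equal(r$r_total, 1, tolerance = 1e-6)
  # one unit step directly away: clipped direction term
  r <- compute_reward(c(0, 0), c(-1, 0), c(-1, 0), far, w)
  expect_equal(r$r_dis, -1, tolerance = 1e-6)
  expect_equal(r$r_dir, 0)
  expect_equal(r$r_total, -0.5, tolerance = 1e-6)
  # perpendicular step toward a very distant target: both terms vanish
  r <- compute_reward(c(0, 0), c(0, 1), c(0, 1), far, w)
  expect_equal(r$r_dis, 0, tolerance = 1e-6)
  expect_equal(r$r_dir, 0, tolerance = 1e-6)
  # |r_dis| never exceeds the step length
  set.seed(5)
  p0 <- matrix(rnorm(40, sd = 50), 20, 2)
  ang <- runif(20, 0, 2 * pi)
  h <- cbind(cos(ang), sin(ang))
  r <- compute_reward(p0, p0 + h, h, c(30, 40), w)
  expect_true(all(abs(r$r_dis) <= 1 + 1e-12))
  expect_true(all(r$r_dir >= 0 & r$r_dir <= 1))
  expect_equal(r$r_total, 0.5 * r$r_dis + 0.5 * r$r_dir)
})

test_that("a lone pursuer closes on the target by exactly its speed", {
  acts <- action_space(15, 2)
  straight <- structure(function(p) rep(7L, length(p)), angles = acts$angles)
  st <- swarm_state_at(rbind(c(0, 0), c(0.5, 0)), rbind(c(1, 0), c(1, 0)),
                       target = c(500, 0))
  cfg <- swarm_config(n = 2, k = 1, speed = 1)
  out <- env_step(st, straight, cfg)
  expect_equal(out$state$positions[1, ], c(1, 0))
  expect_equal(out$info$r_dis[1], 1, tolerance = 1e-9)
})

test_that("a perfectly aligned swarm stays at polarization one under straight rule", {
  acts <- action_space(15, 2)
  straight <- structure(function(p) rep(7L, length(p)), angles = acts$angles)
  set.seed(2)
  pos <- matrix(runif(20, -50, 50), 10, 2)
  st <- swarm_state_at(pos, matrix(rep(c(1, 0), each = 10), 10, 2),
                       target = c(1e6, 0))
  cfg <- swarm_config(n = 10, k = 6)
  for (i in 1:5) {
    out <- env_step(st, straight, cfg)
    st <- out$state
    expect_equal(polarization(st$headings), 1)
  }
})

test_that("percepts and rewards are invariant under global rotation", {
  cfg <- swarm_config(n = 12, k = 4)
  w <- reward_weights(0.5, 0.5)
  pol <- policy_memory()
  set.seed(10)
  for (rep in 1:5) {
    sw <- init_swarm(cfg)
    ang <- runif(1, 0, 2 * pi)
    pc0 <- psnav:::percepts_all(sw$positions, sw$headings, sw$target, cfg$k)
    pc1 <- psnav:::percepts_all(rotate2(sw$positions, ang),
                                rotate2(sw$headings, ang),
                                as.numeric(rotate2(rbind(sw$target), ang)),
                                cfg$k)
    expect_identical(pc0$percept, pc1$percept)
    expect_equal(pc0$theta_neighbor, pc1$theta_neighbor, tolerance = 1e-9)
    expect_equal(pc0$theta_target, pc1$theta_target, tolerance = 1e-9)

    # rewards commute with the rotation as well
    hd2 <- turn(sw$headings, 4)
    r0 <- compute_reward(sw$positions, sw$positions + hd2, hd2, sw$target, w)
    r1 <- compute_reward(rotate2(sw$positions, ang),
                         rotate2(sw$positions + hd2, ang),
                         rotate2(hd2, ang),
                         as.numeric(rotate2(rbind(sw$target), ang)), w)
    expect_equal(r1$r_total, r0$r_total, tolerance = 1e-9)

    # translation of everything including the target changes nothing
    shift <- runif(2, -500, 500)
    pc2 <- psnav:::percepts_all(sweep(sw$positions, 2, -shift),
                                sw$headings, sw$target + shift, cfg$k)
    expect_identical(pc2$percept, pc0$percept)
  }
})

test_that("every agent displaces by exactly the configured speed", {
  cfg <- swarm_config(n = 8, k = 3, speed = 1)
  pol <- policy_memory()
  set.seed(77)
  st <- init_swarm(cfg)
  out <- env_step(st, pol, cfg)
  d <- sqrt(rowSums((out$state$positions - st$positions)^2))
  expect_equal(d, rep(1, 8), tolerance = 1e-12)
})

test_that("an episode without learning leaves the policy bit-identical", {
  pol <- policy_memory()
  pol$h[2, 5] <- 3.7
  cfg <- swarm_config(n = 8, k = 3, target = c(150, 0), max_steps = 60)
  set.seed(5)
  ep <- run_episode(pol, cfg, learn = FALSE)
  expect_identical(ep$policy$h, pol$h)
  expect_identical(nrow(ep$metrics), ep$steps)
})

test_that("episodes are reproducible under a fixed seed", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 10, k = 4, target = c(200, 100), max_steps = 80)
  set.seed(33); a <- run_episode(pol, cfg, learn = TRUE)
  set.seed(33); b <- run_episode(pol, cfg, learn = TRUE)
  expect_identical(a$policy$h, b$policy$h)
  expect_equal(a$metrics, b$metrics)
})

test_that("the compiled and reference engines agree step for step", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 9, k = 4, target = c(120, 80), max_steps = 120,
                      stop_on_success = FALSE)
  set.seed(21); fast <- run_episode(pol, cfg, learn = TRUE, gamma = 1e-4,
                                    engine = "cpp")
  set.seed(21); ref <- run_episode(pol, cfg, learn = TRUE, gamma = 1e-4,
                                   engine = "r")
  expect_identical(fast$policy$h, ref$policy$h)
  expect_equal(fast$metrics, ref$metrics, tolerance = 1e-12)
  expect_identical(fast$steps, ref$steps)

  # and with sensory noise active
  cfg$sensor_noise_sigma <- 25
  set.seed(4); fast <- run_episode(pol, cfg)
  set.seed(4); ref <- run_episode(pol, cfg, engine = "r")
  expect_equal(fast$metrics, ref$metrics, tolerance = 1e-12)
})

test_that("run_episode matches a manual composition of env_step", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 7, k = 3, target = c(90, 40), max_steps = 25,
                      stop_on_success = FALSE)
  set.seed(55)
  st0 <- init_swarm(cfg)
  ep <- run_episode(pol, cfg, learn = TRUE, gamma = 1e-3, state = st0,
                    engine = "r")
  set.seed(55)
  st <- init_swarm(cfg)
  p <- pol; gl <- NULL
  for (i in 1:25) {
    out <- env_step(st, p, cfg, reward_weights(), learn = TRUE, glow = gl,
                    gamma = 1e-3)
    st <- out$state; p <- out$policy; gl <- out$glow
  }
  expect_equal(ep$policy$h, p$h, tolerance = 1e-12)
})

test_that("learning on an episode changes the policy and respects the floor", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 10, k = 4, target = c(300, 0), max_steps = 150)
  set.seed(9)
  ep <- run_episode(pol, cfg, learn = TRUE, gamma = 1e-4)
  expect_false(identical(ep$policy$h, pol$h))
  expect_true(all(ep$policy$h >= pol$h_min))
})

test_that("trajectory recording returns tidy per-agent rows", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 6, k = 2, target = c(100, 0), max_steps = 30,
                      stop_on_success = FALSE)
  set.seed(2)
  ep <- run_episode(pol, cfg, record_trajectory = TRUE, thin = 10)
  expect_equal(unique(ep$trajectory$t), c(10, 20, 30))
  expect_equal(nrow(ep$trajectory), 3 * 6)
  expect_true(all(c("agent_id", "x", "y", "heading_x", "heading_y")
                  %in% names(ep$trajectory)))
  expect_true(all(ep$trajectory$percept %in% 0:8))
  expect_true(all(ep$trajectory$action %in% 0:14))
})

test_that("a moving target is advanced by its velocity each step", {
  pol <- policy_memory()
  cfg <- swarm_config(n = 6, k = 2, target = c(200, 0),
                      target_velocity = c(-0.35, 0.35), max_steps = 40,
                      stop_on_success = FALSE)
  set.seed(3)
  ep <- run_episode(pol, cfg)
  st <- init_swarm(cfg)
  out <- env_step(st, pol, cfg)
  expect_equal(out$state$target, c(200, 0) + c(-0.35, 0.35))
  expect_equal(ep$steps, 40L)
})
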