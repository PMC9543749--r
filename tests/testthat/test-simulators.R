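# Individual-based simulators: conservation, determinism, one-step moments.

test_that("simulators are deterministic given a seed", {
  cfg <- lottery_config(N = 500, s0 = 0.1, tau = 0.3, sigma = 0.4)
  a <- simulate_lottery_discrete(cfg, 50, 30, seed = 5)
  b <- simulate_lottery_discrete(cfg, 50, 30, seed = 5)
  expect_identical(a$n, b$n)
  m1 <- simulate_lottery_moran(cfg, 50, 5, seed = 6)
  m2 <- simulate_lottery_moran(cfg, 50, 5, seed = 6)
  expect_identical(m1$n, m2$n)
  lg <- leslie_gower_config(100, d = 0.5, f = 0.7,
                            recruitment = list(rep(2, 10), rep(2, 10)))
  g1 <- simulate_leslie_gower(lg, 50, 50, seed = 7)
  g2 <- simulate_leslie_gower(lg, 50, 50, seed = 7)
  expect_identical(g1$n, g2$n)
})

test_that("lottery abundances stay in [0, N] and totals are conserved", {
  cfg <- lottery_config(N = 300, s0 = 0, tau = 0.5, sigma = 0.6)
  s <- simulate_lottery_discrete(cfg, 150, 200, seed = 8)
  expect_true(all(s$n >= 0 & s$n <= 300))
  m <- simulate_lottery_moran(cfg, 150, 20, seed = 9)
  expect_true(all(m$n >= 0 & m$n <= 300))
  # Moran elementary events change n by at most 1 between consecutive
  # recordings one event apart
  cfg2 <- lottery_config(N = 100, s0 = 0, tau = 0.5, sigma = 0.3)
  m2 <- simulate_lottery_moran(cfg2, 50, 5, record_interval = 1 / 100,
                               seed = 10)
  expect_true(all(abs(diff(m2$n)) <= 1))
})

test_that("neutral lottery one-step increments have zero mean", {
  cfg <- lottery_config(N = 1000, s0 = 0, tau = 0.2, sigma = 0)
  set.seed(13)
  n0 <- rep(500L, 2e5)
  n1 <- invasibility:::.lottery_step(n0, cfg,
                                     invasibility:::.draw_env(2e5,
                                                              "dichotomous"))
  d <- n1 - n0
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("selected lottery one-step mean matches its closed form", {
  # E[dn | n] = N tau (p - n/N) with p = n e^s0 / (n e^s0 + N - n)
  cfg <- lottery_config(N = 1000, s0 = 0.15, tau = 0.2, sigma = 0)
  set.seed(14)
  n0 <- rep(40L, 1e6)
  n1 <- invasibility:::.lottery_step(n0, cfg,
                                     invasibility:::.draw_env(1e6,
                                                              "dichotomous"))
  d <- n1 - n0
  mom <- lottery_moments_oracle(40, 1000, 0.15, 0, 0.2)
  expect_lt(abs(mean(d) - mom["mean"]), 3 * sd(d) / sqrt(length(d)))
  expect_equal(var(d), unname(mom["var"]), tolerance = 0.02)
  # and the small-n approximation tau (e^s0 - 1) (N - n)/N is close
  approx <- 0.2 * (exp(0.15) - 1) * (1000 - 40) / 1000 * 40
  expect_equal(unname(mom["mean"]), approx, tolerance = 0.01)
})

test_that("discrete lottery rejects dwell times above one generation", {
  expect_error(simulate_lottery_discrete(
    lottery_config(100, tau = 1.5), 10, 10), "Moran")
  expect_error(lottery_config(100, tau = 0), "positive")
})

test_that("neutral relabeling symmetry of the lottery", {
  # swapping the roles of invader and resident mirrors the trajectory
  # distribution: mean increments from n and N - n are opposite
  cfg <- lottery_config(N = 400, s0 = 0, tau = 0.3, sigma = 0.5)
  set.seed(15)
  e <- invasibility:::.draw_env(4e5, "dichotomous")
  n1a <- invasibility:::.lottery_step(rep(120L, 4e5), cfg, e)
  n1b <- invasibility:::.lottery_step(rep(280L, 4e5), cfg, -e)
  expect_lt(abs(mean(n1a - 120) + mean(n1b - 280)),
            4 * sd(n1a) / sqrt(4e5))
})

test_that("Leslie-Gower conserves adult sites and freezes at d = 1", {
  lg <- leslie_gower_config(200, d = 0.4, f = 0.6,
                            recruitment = list(rep(1.5, 7), rep(1.5, 7)))
  # conservation is structural: A2 = N - A1 by construction; check that
  # abundances remain valid through a long run
  s <- simulate_leslie_gower(lg, 100, 300, seed = 16)
  expect_true(all(s$n >= 0 & s$n <= 200))
  lg2 <- leslie_gower_config(200, d = 1, f = 0.6,
                             recruitment = list(rep(1.5, 7), rep(1.5, 7)))
  s2 <- simulate_leslie_gower(lg2, 77, 50, seed = 17)
  expect_true(all(s2$n == 77))
  # exchangeable species: no mean drift
  set.seed(18)
  st <- invasibility:::.lg_step(rep(100L, 2e5), rep(150L, 2e5),
                                rep(150L, 2e5), lg, 1.5, 1.5)
  expect_lt(abs(mean(st$A1) - 100), 3 * sd(st$A1) / sqrt(2e5))
})

test_that("synthetic recruitment series has the requested moments", {
  r <- generate_recruitment_series(c(2, 3), log_var = 0.25, corr = 0.4,
                                   years = 1e5, seed = 19)
  expect_equal(mean(r[, 1]), 2, tolerance = 0.02)
  expect_equal(mean(r[, 2]), 3, tolerance = 0.02)
  expect_equal(var(log(r[, 1])), 0.25, tolerance = 0.02)
  expect_equal(cor(log(r[, 1]), log(r[, 2])), 0.4, tolerance = 0.02)
  # degenerate cases
  r0 <- generate_recruitment_series(c(2, 3), 0, 0, years = 10)
  expect_true(all(r0[, 1] == 2) && all(r0[, 2] == 3))
  r1 <- generate_recruitment_series(c(2, 2), 0.3, 1, years = 50, seed = 20)
  expect_equal(r1[, 1], r1[, 2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(generate_recruitment_series(c(-1, 2), 0.1, 0, 10),
               "positive")
  expect_error(generate_recruitment_series(c(1, 2), 0.1, 1.5, 10), "corr")
})

test_that("Monte-Carlo estimator boundary cases and reproducibility", {
  cfg <- lottery_config(N = 300, s0 = 0, tau = 0.2, sigma = 0.3)
  e1 <- estimate_invasion_mc(lottery_mc_runner(cfg), 5, 5, 100, seed = 21)
  expect_equal(e1$probability, 1)
  expect_equal(e1$ci, c(1, 1))
  e2 <- estimate_invasion_mc(lottery_mc_runner(cfg), 3, 60, 2000, seed = 22)
  e3 <- estimate_invasion_mc(lottery_mc_runner(cfg), 3, 60, 2000, seed = 22)
  expect_identical(e2$probability, e3$probability)
  expect_true(e2$ci[1] >= 0 && e2$ci[2] <= 1 &&
                e2$ci[1] <= e2$probability && e2$probability <= e2$ci[2])
  expect_error(estimate_invasion_mc(lottery_mc_runner(cfg), 0, 60, 10),
               "n0")
})

test_that("storage effect: environmental variance raises invasibility", {
  # at s0 = 0 the lottery models gain positive invasion growth from
  # environmental fluctuations via buffered recruitment
  cfgs <- lottery_config(N = 2000, s0 = 0, tau = 0.5, sigma = 0.5)
  est_s <- estimate_invasion_mc(moran_mc_runner(cfgs), 1, 100, 1e4,
                                seed = 23)
  neutral <- 1 / 100
  expect_gt(est_s$probability, neutral + 3 * est_s$se)
  # discrete-time variant as well
  cfgd <- lottery_config(N = 2000, s0 = 0, tau = 0.5, sigma = 0.5)
  est_d <- estimate_invasion_mc(lottery_mc_runner(cfgd), 1, 100, 1e4,
                                seed = 24)
  expect_gt(est_d$probability, neutral + 3 * est_d$se)
})
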