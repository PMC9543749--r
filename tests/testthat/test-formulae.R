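# Closed-form invasion probabilities: worked examples against independent
# oracles, limiting branches, and invariants.

test_that("diffusion formula matches its worked examples and the BVP oracle", {
  # neutral collapse is exact
  expect_equal(pi_diffusion(10, 200, nspace_params(0, 1, 0.3)), 0.05)
  # boundary condition at n = nf
  expect_equal(pi_diffusion(200, 200, nspace_params(0.02, 1, 0.1)), 1)
  # direct evaluation, frozen from the finite-difference solve of the
  # backward boundary-value problem (fd_bvp_oracle, M = 40000: 0.01128870)
  p <- nspace_params(eps = 0.02, Vd = 1, Ve = 0.1)
  expect_equal(pi_diffusion(1, 200, p), 0.01128870, tolerance = 1e-5)
  ora <- fd_bvp_oracle(200, 0.02, 1, 0.1)
  for (n in c(1, 5, 20, 80, 150))
    expect_equal(pi_diffusion(n, 200, p), ora(n), tolerance = 1e-5)
  # vanishing environmental variance reproduces the fixed-environment form
  expect_equal(pi_diffusion(1, 200, nspace_params(0.05, 1, 1e-10)),
               pi_fixed_env(1, 200, 0.05, 1), tolerance = 1e-6)
  expect_equal(pi_fixed_env(1, 200, 0.05, 1), 0.09516, tolerance = 1e-4)
})

test_that("diffusion formula input validation", {
  p <- nspace_params(0.02, 1, 0.1)
  expect_error(pi_diffusion(300, 200, p), "exceed")
  expect_error(pi_diffusion(-1, 200, p), "nonnegative")
  expect_error(pi_diffusion(0.5, 200, nspace_params(0.02, 0, 0.1)),
               "demographic")
  # Vd = 0 with n >= 1 takes the pure-environmental limit
  expect_equal(pi_diffusion(5, 50, nspace_params(0, 0, 0.1)),
               (5 / 50)^1)
})

test_that("wkb_outer reproduces its examples and solves the jump equation", {
  w <- wkb_outer(zspace_params(E0 = 0.1, Vd = 1, Ve = 0.09))
  expect_equal(w$beta, sqrt(0.1), tolerance = 1e-12)
  expect_equal(w$alpha, 0.65811, tolerance = 1e-5)
  expect_equal(w$q_bar, -2.07098, tolerance = 1e-5)
  expect_equal(w$R, 0.09657, tolerance = 1e-4)
  # q_bar solves 1 = 2 alpha sinh(q beta) + exp(-q beta) (root oracle)
  expect_equal(w$q_bar, q_bar_root_oracle(0.1, 0.09), tolerance = 1e-12)
  # antisymmetry under E0 -> -E0
  w2 <- wkb_outer(zspace_params(E0 = -0.1, Vd = 1, Ve = 0.09))
  expect_equal(w2$q_bar, -w$q_bar, tolerance = 1e-12)
  # symmetric-jump limit
  w0 <- wkb_outer(zspace_params(E0 = 0, Vd = 1, Ve = 0.04))
  expect_equal(w0$beta, 0.2)
  expect_equal(w0$alpha, 0.5)
  expect_equal(w0$q_bar, 0)
  expect_equal(w0$R, 0.04)
  expect_error(wkb_outer(zspace_params(0.1, 0, 0.09)), "Vd")
})

test_that("q_bar satisfies the characteristic equation on random draws", {
  set.seed(42)
  for (i in 1:200) {
    E0 <- stats::runif(1, -0.5, 0.5)
    Ve <- stats::runif(1, 1e-4, 1)
    w <- wkb_outer(zspace_params(E0 = E0, Vd = 1, Ve = Ve))
    resid <- 2 * w$alpha * sinh(w$q_bar * w$beta) + exp(-w$q_bar * w$beta) - 1
    expect_lt(abs(resid), 1e-12)
    # two-destination moment preservation is exact by construction
    expect_equal(2 * (w$alpha - 0.5) * w$beta, E0, tolerance = 1e-12)
    expect_equal(w$beta^2, Ve + E0^2, tolerance = 1e-12)
  }
})

test_that("wkb formula worked examples and boundary conditions", {
  expect_equal(pi_wkb(200, 200, zspace_params(0.05, 1, 0.1)), 1)
  expect_equal(pi_wkb(0, 200, zspace_params(0.05, 1, 0.1)), 0)
  # q_bar -> 0 logarithmic limit, with two-sided convergence at E0 = +/-eps
  expect_equal(pi_wkb(1, 200, zspace_params(0, 1, 1)), log(2) / log(201),
               tolerance = 1e-12)
  up <- pi_wkb(1, 200, zspace_params(1e-8, 1, 1))
  dn <- pi_wkb(1, 200, zspace_params(-1e-8, 1, 1))
  expect_equal(up, log(2) / log(201), tolerance = 1e-6)
  expect_equal(dn, log(2) / log(201), tolerance = 1e-6)
  expect_true(dn < log(2) / log(201) && log(2) / log(201) < up)
  # direct evaluation via the outer intermediates
  expect_equal(pi_wkb(1, 200, zspace_params(0.1, 1, 0.09)), 0.17414,
               tolerance = 1e-4)
  # large-nR limit with q_bar < 0: certain establishment
  z <- zspace_params(0.1, 1, 0.09)
  R <- wkb_outer(z)$R
  expect_lt(abs(pi_wkb(1e4 / R, 2e4 / R, z) - 1), 1e-3)
})

test_that("both formulae converge to the fixed-environment limit", {
  for (g in c(0.001, 0.01, 0.05, 0.2, -0.03)) {
    kim <- pi_fixed_env(1, 200, g, 1)
    expect_equal(pi_wkb(1, 200, zspace_params(g, 1, 1e-10)), kim,
                 tolerance = 1e-6)
    expect_equal(pi_diffusion(1, 200, nspace_params(g, 1, 1e-10)), kim,
                 tolerance = 1e-6)
  }
})

test_that("probabilities are monotone in n, nf and the growth parameter", {
  set.seed(7)
  for (i in 1:50) {
    eps <- stats::runif(1, -0.1, 0.1)
    Vd <- stats::runif(1, 0.2, 2)
    Ve <- stats::runif(1, 1e-3, 0.5)
    np <- nspace_params(eps, Vd, Ve)
    zp <- zspace_params(eps, Vd, Ve)
    ns <- sort(stats::runif(8, 0, 200))
    da <- pi_diffusion(ns, 200, np)
    wk <- pi_wkb(ns, 200, zp)
    expect_true(all(diff(da) >= -1e-12))
    expect_true(all(diff(wk) >= -1e-12))
    expect_true(all(da >= 0 & da <= 1))
    expect_true(all(wk >= 0 & wk <= 1))
    # nonincreasing in nf
    expect_gte(pi_diffusion(5, 100, np), pi_diffusion(5, 150, np))
    expect_gte(pi_wkb(5, 100, zp), pi_wkb(5, 150, zp))
    # nondecreasing in the growth parameter
    np2 <- nspace_params(eps + 0.01, Vd, Ve)
    zp2 <- zspace_params(eps + 0.01, Vd, Ve)
    expect_gte(pi_diffusion(5, 200, np2), pi_diffusion(5, 200, np) - 1e-12)
    expect_gte(pi_wkb(5, 200, zp2), pi_wkb(5, 200, zp) - 1e-12)
  }
})

test_that("neutral diffusion probability equals n/nf to machine precision", {
  set.seed(8)
  for (i in 1:100) {
    Vd <- stats::runif(1, 0.1, 5)
    Ve <- stats::runif(1, 1e-6, 2)
    n <- stats::runif(1, 0, 150)
    expect_equal(pi_diffusion(n, 150, nspace_params(0, Vd, Ve)), n / 150,
                 tolerance = 1e-12)
  }
})

test_that("wkb and diffusion agree in the weak-noise overlap regime", {
  # the two spaces describe the same process through different moments:
  # to second order E0 = eps - (Ve + eps^2)/2 (mean log growth lies below
  # mean relative growth by half the variance); under that correspondence
  # q_bar = -2 E0/Ve equals the diffusion exponent Q = 1 - 2 eps/Ve and
  # the two formulae coincide at weak noise
  set.seed(9)
  for (i in 1:40) {
    eps <- stats::runif(1, -0.01, 0.01)
    Ve <- stats::runif(1, 1e-4, 0.01)
    E0 <- eps - (Ve + eps^2) / 2
    a <- pi_diffusion(1, 200, nspace_params(eps, 1, Ve))
    b <- pi_wkb(1, 200, zspace_params(E0, 1, Ve))
    expect_equal(a, b, tolerance = 0.02)
  }
})

test_that("interpolated exponent bridges the inner and outer regimes", {
  z <- zspace_params(E0 = 0.05, Vd = 1, Ve = 0.2)
  w <- wkb_outer(z)
  n_small <- 1e-6 * z$Vd / abs(z$E0)
  n_large <- 1e6 * z$Vd / abs(z$E0)
  expect_equal(wkb_q_interp(n_small, z), -2 * z$E0 * n_small / z$Vd,
               tolerance = 1e-5)
  expect_equal(wkb_q_interp(n_large, z), w$q_bar, tolerance = 1e-5)
})

test_that("fixed-environment and quenched formulae behave", {
  expect_equal(pi_fixed_env(5, 50, 0), 0.1)
  expect_equal(pi_fixed_env(200, 200, 0.03), 1)
  expect_equal(pi_quenched(1, 200, 0.05, 1, Vd = 1),
               pi_fixed_env(1, 200, 0.05, 1))
  two <- pi_quenched(1, 200, c(0.05, -0.05), Vd = 1)
  expect_equal(two, mean(c(pi_fixed_env(1, 200, 0.05),
                           pi_fixed_env(1, 200, -0.05))))
  # neutral limit of a symmetric mixture
  s <- 1e-9
  expect_equal(pi_quenched(1, 200, c(s, -s)), 1 / 200, tolerance = 1e-6)
  expect_error(pi_quenched(1, 200, numeric(0)), "at least one")
  expect_error(pi_quenched(1, 200, c(0.1, 0.2), weights = c(0.7, 0.7)),
               "sum to 1")
})

test_that("extinction threshold and natural target abundance", {
  expect_equal(extinction_threshold(nspace_params(0, 1, 1)), 1)
  expect_equal(extinction_threshold(nspace_params(0, 1, 0.04)), 25)
  expect_equal(extinction_threshold(nspace_params(0, 0, 0.1)), 0)
  expect_warning(res <- extinction_threshold(nspace_params(0, 1, 0)),
                 "no finite")
  expect_identical(res, Inf)
  expect_equal(natural_target_abundance(
    structure(list(q_bar = -1, R = 1), class = "wkb_intermediates")),
    exp(1))
  w <- wkb_outer(zspace_params(0.1, 1, 0.09))
  expect_equal(natural_target_abundance(w), 16.78, tolerance = 1e-3)
  expect_error(natural_target_abundance(
    structure(list(q_bar = 0.5, R = 1), class = "wkb_intermediates")),
    "positive mean growth")
})
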