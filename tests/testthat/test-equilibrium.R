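test_that("ligand-depletion bound fraction matches limits and the mass-balance oracle", {
  # no titrant, nothing bound
  expect_equal(fraction_bound_ligand_depletion(5e-8, 25e-9, 0), 0)
  # stoichiometric limit: kd -> 0 with b = a_star saturates
  expect_equal(fraction_bound_ligand_depletion(0, 25e-9, 25e-9), 1)
  # frozen value computed with the root-finding oracle
  expect_equal(fraction_bound_ligand_depletion(100e-9, 25e-9, 100e-9),
               0.4688711, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:50) {
    kd <- 10^runif(1, -9, -5)
    a <- 10^runif(1, -9, -6)
    b <- 10^runif(1, -10, -5)
    expect_equal(fraction_bound_ligand_depletion(kd, a, b),
                 oracle_fraction_bound(kd, a, b), tolerance = 1e-9)
  }
})

test_that("bound fraction is monotone in titrant and in affinity", {
  set.seed(12)
  for (i in 1:30) {
    a <- 10^runif(1, -9, -6)
    b <- sort(10^runif(8, -10, -5))
    kd1 <- 10^runif(1, -9, -5)
    kd2 <- kd1 * runif(1, 1.5, 100)
    f1 <- fraction_bound_ligand_depletion(kd1, a, b)
    expect_true(all(diff(f1) >= -1e-12))        # nondecreasing in b
    f2 <- fraction_bound_ligand_depletion(kd2, a, b)
    expect_true(all(f2 <= f1 + 1e-12))          # nonincreasing in kd
    expect_true(all(f1 >= 0 & f1 <= 1))
  }
})

test_that("bound fraction rejects invalid concentrations", {
  expect_error(fraction_bound_ligand_depletion(1e-8, 0, 1e-8), "a_star")
  expect_error(fraction_bound_ligand_depletion(1e-8, -1e-9, 1e-8), "a_star")
  expect_error(fraction_bound_ligand_depletion(1e-8, 1e-8, -1e-9), "b must")
})

test_that("two-state signal model evaluates and guards its domain", {
  expect_equal(signal_from_fraction(1, 0.5, 0), 1)
  expect_equal(signal_from_fraction(1, 0.5, 1), 1.5)
  expect_equal(signal_from_fraction(1, 0.5, 0.469), 1.2345)
  expect_error(signal_from_fraction(1, 0.5, 1.2), "fraction")
  expect_error(signal_from_fraction(1, 0.5, -0.1), "fraction")
})

test_that("fit_kd recovers parameters exactly from noiseless data", {
  ts <- gen_titration(kd = 50e-9, a_star = 25e-9, noise_sd = 0)
  fit <- fit_kd(ts)
  expect_identical(fit$status, "ok")
  expect_equal(fit$kd, 50e-9, tolerance = 1e-6)
  expect_equal(fit$f0, 1, tolerance = 1e-6)
  expect_equal(fit$fmax, 0.5, tolerance = 1e-6)
})

test_that("fit_kd reports n.c. when the titration does not approach saturation", {
  # maximum titrant at 0.1 x kd: no curvature, plateau unconstrained
  ts <- gen_titration(kd = 1e-6, a_star = 10e-9,
                      b_grid = seq(1e-9, 1e-7, length.out = 8),
                      noise_sd = 0.003, seed = 7)
  fit <- fit_kd(ts)
  expect_identical(fit$status, "n.c.")
  expect_true(is.na(fit$kd))
})

test_that("fit_kd agrees with a brute-force grid-search oracle on noisy data", {
  ts <- gen_titration(kd = 8e-8, a_star = 25e-9, noise_sd = 0.005, seed = 42)
  fit <- fit_kd(ts)
  grid <- oracle_grid_fit(ts,
                          kd_grid = 8e-8 * exp(seq(log(0.5), log(2), length.out = 141)),
                          f0_grid = seq(0.99, 1.01, length.out = 41),
                          fmax_grid = seq(0.45, 0.55, length.out = 41))
  # fit must sit within one grid step (1% kd spacing) of the grid optimum
  expect_equal(fit$kd, grid$kd, tolerance = 0.011)
  expect_lte(fit$rss, grid$rss + 1e-12)
})

test_that("fit_kd input validation", {
  expect_error(fit_kd(titration_series(1e-8, c(1e-9, 2e-9, 4e-9, 8e-9),
                                       c(1, 1.1, 1.2, 1.3))),
               "at least 5")
})

test_that("median recovered Kd over 100 noisy titrations is within 15%", {
  kd_true <- 5e-8
  kds <- vapply(1:100, function(s) {
    fit_kd(gen_titration(kd_true, a_star = 25e-9, seed = s))$kd
  }, numeric(1))
  expect_lt(abs(median(kds, na.rm = TRUE) / kd_true - 1), 0.15)
})

test_that("coupled equilibrium solver conserves mass and hits its limits", {
  # no-binding limit: all constants huge -> free species equal totals
  sch <- equilibrium_scheme(1e6, 1e6, 1e6, c_total = 1e-6, d_total = 1e-6)
  sol <- solve_coupled_equilibrium(sch)
  expect_equal(sol$c, 1e-6, tolerance = 1e-6)
  expect_equal(sol$d, 1e-6, tolerance = 1e-6)
  expect_lt(sol$cd + sol$cd2 + sol$t, 1e-15)

  # negligible tetramerization and second site -> closed-form quadratic
  sch2 <- equilibrium_scheme(k1 = 2.6e-8, k2 = 1e6, ktet = 1e6,
                             c_total = 1e-8, d_total = 5e-8)
  sol2 <- solve_coupled_equilibrium(sch2)
  cd_closed <- 1e-8 * fraction_bound_ligand_depletion(2.6e-8, 1e-8, 5e-8)
  expect_equal(sol2$cd, cd_closed, tolerance = 1e-9)

  # conservation on random valid inputs
  set.seed(13)
  for (i in 1:25) {
    sch3 <- equilibrium_scheme(10^runif(1, -9, -5), 10^runif(1, -9, -5),
                               10^runif(1, -7, -3),
                               c_total = 10^runif(1, -9, -5),
                               d_total = 10^runif(1, -9, -5))
    sol3 <- solve_coupled_equilibrium(sch3)
    expect_lt(sol3$residual, 1e-9)
    expect_true(all(unlist(sol3[c("c", "d", "t", "cd", "cd2")]) >= 0))
  }
})

test_that("equilibrium scheme validates constants and totals", {
  expect_error(equilibrium_scheme(0, 1, 1, 1e-6, 1e-6), "positive")
  expect_error(equilibrium_scheme(1, 1, 1, -1e-6, 1e-6), "nonnegative")
})
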