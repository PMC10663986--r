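test_that("cox partial likelihood matches hand-computed values", {
  # a single event is its own risk set: r - log(e^r) = 0
  expect_equal(cox_nll(3.7, 1, 10), 0, tolerance = 1e-12)
  # two events, equal risks: -[(0 - log 2) + (0 - log 1)] = log 2
  expect_equal(cox_nll(c(0, 0), c(1, 1), c(1, 2)), log(2), tolerance = 1e-12)
  # shift invariance
  d <- random_survival_data(8, seed = 1)
  expect_equal(cox_nll(d$risks + 5.3, d$events, d$durations),
               cox_nll(d$risks, d$events, d$durations), tolerance = 1e-9)
  # permutation equivariance
  p <- sample(8)
  expect_equal(cox_nll(d$risks[p], d$events[p], d$durations[p]),
               cox_nll(d$risks, d$events, d$durations), tolerance = 1e-10)
  expect_error(cox_nll(c(1, 2), c(0, 0), c(1, 2)), "no events")
})

test_that("vectorized cox loss equals the naive double-loop oracle", {
  for (s in 1:40) {
    d <- random_survival_data(sample(2:8, 1), seed = s)
    expect_equal(cox_nll(d$risks, d$events, d$durations),
                 naive_cox_nll(d$risks, d$events, d$durations),
                 tolerance = 1e-10)
  }
})

test_that("cox gradient matches finite differences", {
  d <- random_survival_data(7, seed = 11)
  g <- pathsurv:::cox_nll_grad(d$risks, d$events, d$durations)$grad
  eps <- 1e-6
  for (i in seq_along(d$risks)) {
    up <- d$risks; up[i] <- up[i] + eps
    dn <- d$risks; dn[i] <- dn[i] - eps
    fd <- (cox_nll(up, d$events, d$durations) -
             cox_nll(dn, d$events, d$durations)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("interval fraction handles interior, boundary and clamped times", {
  g <- time_grid(c(0, 10, 20))
  fr <- interval_fraction(15, g)
  expect_equal(fr$kappa, 2L)
  expect_equal(fr$rho, 0.5)
  # left boundary of an interval has rho = 0
  expect_equal(interval_fraction(10, g)$kappa, 2L)
  expect_equal(interval_fraction(10, g)$rho, 0)
  expect_equal(interval_fraction(0, g), list(kappa = 1L, rho = 0))
  # the final boundary belongs to the last interval with rho = 1
  expect_equal(interval_fraction(20, g), list(kappa = 2L, rho = 1))
  expect_warning(out <- interval_fraction(25, g), "clamped")
  expect_equal(out, list(kappa = 2L, rho = 1))
})

test_that("discrete-time loss matches hand-computed fixtures", {
  # single censored sample, mass (0.5, 0.5) observed in bin 1:
  # loss_L = -log S(T_1) = -log 0.5; no comparable pair so rank term is 0
  for (alpha in c(0.3, 1)) {
    expect_equal(deephit_loss(matrix(c(0.5, 0.5), 1), events = 0, bins = 1,
                              alpha = alpha, sigma = 0.1),
                 alpha * (-log(0.5)), tolerance = 1e-10)
  }
  # two samples, hand evaluation:
  # s1 event in bin 2 -> -log 0.3; s2 censored in bin 3 -> -log 0.4
  # pair (s1, s2): exp((S1(T2) - S2(T2)) / 0.5) = exp((0.1 - 0.7) / 0.5)
  masses <- rbind(c(0.6, 0.3, 0.05, 0.05),
                  c(0.1, 0.2, 0.3, 0.4))
  expected <- 0.4 * (-log(0.3) - log(0.4)) + 0.6 * exp(-1.2)
  expect_equal(deephit_loss(masses, events = c(1, 0), bins = c(2, 3),
                            alpha = 0.4, sigma = 0.5),
               expected, tolerance = 1e-10)
  # sigma -> infinity: each comparable-pair term tends to exp(0) = 1
  expect_equal(deephit_loss(masses, events = c(1, 0), bins = c(2, 3),
                            alpha = 0, sigma = 1e12), 1, tolerance = 1e-9)
  expect_error(deephit_loss(rbind(c(0.6, 0.6)), 1, 1, 0.5, 0.1), "sum to 1")
})

test_that("likelihood part decreases as mass moves onto the true bin", {
  base <- c(0.25, 0.25, 0.25, 0.25)
  better <- c(0.1, 0.7, 0.1, 0.1)
  l1 <- deephit_loss(matrix(base, 1), 1, 2, alpha = 1, sigma = 0.1)
  l2 <- deephit_loss(matrix(better, 1), 1, 2, alpha = 1, sigma = 0.1)
  expect_lt(l2, l1)
})

test_that("piecewise-constant hazard loss matches hand-computed fixtures", {
  # one event exactly at Tfinal on a unit grid with eta = 1:
  # -[log 1 - 1 * 1 * 1] = 1
  g1 <- time_grid(c(0, 1))
  expect_equal(pc_hazard_loss(matrix(1, 1, 1), 1, 1, g1), 1,
               tolerance = 1e-12)
  # censored sample at T0 contributes 0
  expect_equal(pc_hazard_loss(matrix(2, 1, 1), 0, 0, g1), 0,
               tolerance = 1e-12)
  # two-sample fixture on grid (0, 1, 3), hand evaluation:
  # s1 event at t=2 (kappa 2, rho 0.5): log(1.5) - 1.5*0.5*2 - 0.5*1
  # s2 censored at t=1 (kappa 2, rho 0): -2.0*1
  g2 <- time_grid(c(0, 1, 3))
  etas <- rbind(c(0.5, 1.5), c(2.0, 1.0))
  expected <- -((log(1.5) - 1.5 - 0.5) + (-2)) / 2
  expect_equal(pc_hazard_loss(etas, c(1, 0), c(2, 1), g2), expected,
               tolerance = 1e-10)
  # rate x duration invariance for censored samples: doubling widths and
  # halving rates leaves the exposure unchanged
  g3 <- time_grid(c(0, 2, 6))
  expect_equal(pc_hazard_loss(matrix(c(2, 1), 1) / 2, 0, 2, g3),
               pc_hazard_loss(matrix(c(2, 1), 1), 0, 1, g2),
               tolerance = 1e-12)
})

test_that("weighted cross entropy is exact on closed-form cases", {
  # perfect prediction is ~0 after clipping
  expect_lt(weighted_bce(c(1, 0, 1), c(1, 0, 1)), 1e-10)
  # uninformative predictor: log 2
  expect_equal(weighted_bce(rep(0.5, 4), c(0, 1, 0, 1)), log(2),
               tolerance = 1e-12)
  # class weight w is replication: weights (1, 3) equals tripling positives
  p <- c(0.2, 0.7, 0.9, 0.4)
  y <- c(0, 1, 1, 0)
  wsum <- weighted_bce(p, y, c(1, 3)) * length(p)
  rep_idx <- c(which(y == 0), rep(which(y == 1), each = 3))
  rsum <- weighted_bce(p[rep_idx], y[rep_idx], c(1, 1)) * length(rep_idx)
  expect_equal(wsum, rsum, tolerance = 1e-12)
})
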