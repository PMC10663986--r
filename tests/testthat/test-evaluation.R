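test_that("breslow baseline has the closed-form jumps and properties", {
  # all risks zero, one event among n at time t1: single jump of 1/n
  n <- 8
  bl <- breslow_baseline(rep(0, n), c(1, rep(0, n - 1)),
                         c(2, seq(3, length.out = n - 1)))
  expect_equal(bl$times, 2)
  expect_equal(bl$cumhaz, 1 / n)
  expect_equal(cumhaz_at(bl, 1.9), 0)
  expect_equal(cumhaz_at(bl, 100), 1 / n)
  # nondecreasing for arbitrary data; doubling e^h halves every jump
  d <- random_survival_data(40, seed = 5)
  b1 <- breslow_baseline(d$risks, d$events, d$durations)
  expect_true(all(diff(b1$cumhaz) >= 0))
  b2 <- breslow_baseline(d$risks + log(2), d$events, d$durations)
  expect_equal(b2$cumhaz, b1$cumhaz / 2, tolerance = 1e-12)
})

test_that("survival curves obey the family-specific identities", {
  g <- time_grid(c(0, 1, 2, 3))
  # all mass in the first bin: S = 0 from T1 onwards
  dh <- deephit_survival_curves(matrix(c(1, 0, 0), 1), g)
  expect_equal(unname(dh$S), matrix(c(0, 0, 0), 1))
  # zero hazard: S identically 1
  pc <- pc_hazard_survival_curves(matrix(0, 1, 3), g)
  expect_equal(unname(pc$S), matrix(1, 1, 3))
  # a zero-risk sample's curve is exp(-Lambda0)
  d <- random_survival_data(30, seed = 7)
  bl <- breslow_baseline(d$risks, d$events, d$durations)
  cc <- cox_survival_curves(c(0, d$risks), bl)
  expect_equal(cc$S[1, ], exp(-bl$cumhaz), tolerance = 1e-12)
  # curves are nonincreasing
  expect_true(all(apply(cc$S, 1, function(x) all(diff(x) <= 1e-12))))
})

test_that("harrell index equals brute-force enumeration on random data", {
  for (s in 1:20) {
    d <- random_survival_data(sample(5:60, 1), seed = 100 + s)
    expect_equal(harrell_cindex(d$risks, d$events, d$durations),
                 naive_harrell(d$risks, d$events, d$durations))
  }
})

test_that("harrell index honors the tie and ordering conventions", {
  # risks anti-ordered with durations, no censoring: perfect concordance
  t <- c(5, 1, 3, 2, 4)
  expect_equal(harrell_cindex(-t, rep(1, 5), t), 1)
  expect_equal(harrell_cindex(t, rep(1, 5), t), 0)
  # constant risks: 0.5 by the tie convention
  expect_equal(harrell_cindex(rep(2, 5), rep(1, 5), t), 0.5)
  # complement symmetry on tie-free data
  d <- random_survival_data(50, seed = 3, tie_prob = 0)
  expect_equal(harrell_cindex(-d$risks, d$events, d$durations),
               1 - harrell_cindex(d$risks, d$events, d$durations),
               tolerance = 1e-12)
  expect_error(harrell_cindex(1, 0, 5), "comparable")
})

test_that("random risks on uncensored data concentrate near 0.5", {
  set.seed(42)
  t <- rexp(1000)
  r <- rnorm(1000)
  expect_lt(abs(harrell_cindex(r, rep(1, 1000), t) - 0.5), 0.03)
})

test_that("antolini index reduces to harrell under a shared baseline", {
  for (s in 1:5) {
    d <- random_survival_data(60, seed = 200 + s, tie_prob = 0)
    bl <- breslow_baseline(d$risks, d$events, d$durations)
    times <- sort(unique(d$durations[d$events == 1]))
    curves <- cox_survival_curves(d$risks, bl, times)
    expect_equal(antolini_cindex(curves, d$events, d$durations),
                 harrell_cindex(d$risks, d$events, d$durations),
                 tolerance = 1e-12)
  }
  # identical curves for everyone: 0.5
  flat <- survival_curve_matrix(c(1, 2), matrix(0.6, 4, 2))
  expect_equal(antolini_cindex(flat, c(1, 1, 0, 1), c(1, 2, 2, 3)), 0.5)
})

test_that("crossing curves separate the time-dependent index from harrell", {
  # three uncensored samples; A dies first, B second, C last.
  # A's curve drops early (riskiest early); B's curve is flat-high early
  # but crosses below C's later. Scored at the event times, the
  # time-dependent index sees the crossing that a single risk score cannot.
  times <- c(1, 2, 3)
  S <- rbind(c(0.10, 0.05, 0.02),   # A, dies at t=1
             c(0.90, 0.50, 0.40),   # B, dies at t=2
             c(0.60, 0.55, 0.50))   # C, dies at t=3
  curves <- survival_curve_matrix(times, S)
  events <- c(1, 1, 1)
  durations <- c(1, 2, 3)
  ant <- antolini_cindex(curves, events, durations)
  # pairs: (A,B) S_A(1)<S_B(1) ok; (A,C) ok; (B,C) S_B(2)=0.50 < 0.55 ok
  expect_equal(ant, 1)
  # a single risk score from the early ordering (A > C > B) disagrees
  risks_early <- -S[, 1]
  expect_lt(harrell_cindex(risks_early, events, durations), ant)
})

test_that("classification metrics match closed forms and pROC", {
  p <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  m <- classification_metrics(p, y)
  expect_equal(m$auroc, 0.75)
  # perfect separation and constant scores
  expect_equal(classification_metrics(c(0.1, 0.2, 0.8, 0.9),
                                      c(0, 0, 1, 1))$auroc, 1)
  expect_equal(classification_metrics(rep(0.5, 4), c(0, 1, 0, 1))$auroc, 0.5)
  expect_error(classification_metrics(p, c(1, 1, 1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(9)
  probs <- runif(200)
  labs <- rbinom(200, 1, plogis(3 * probs - 1.5))
  expect_equal(classification_metrics(probs, labs)$auroc,
               as.numeric(pROC::auc(pROC::roc(labs, probs, quiet = TRUE))),
               tolerance = 1e-10)
})
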