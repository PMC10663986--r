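test_that("exact shapley has the linear-model closed form", {
  set.seed(4)
  w <- c(2, -1, 0.5, 0, 3)
  f <- function(M) drop(M %*% w)
  bg <- matrix(rnorm(40 * 5), 40, 5)
  x <- rnorm(5)
  phi <- exact_shapley(f, x, bg)
  expect_equal(phi, w * (x - colMeans(bg)), tolerance = 1e-10)
  # a constant function attributes nothing
  expect_equal(exact_shapley(function(M) rep(7, nrow(M)), x, bg),
               rep(0, 5), tolerance = 1e-12)
  expect_error(exact_shapley(f, rnorm(20), matrix(rnorm(40), 2, 20)),
               "max_features")
})

test_that("shapley axioms hold on random small networks", {
  for (s in 1:5) {
    set.seed(s)
    d <- 6
    W1 <- matrix(rnorm(d * 8), d, 8)
    w2 <- rnorm(8)
    f <- function(M) drop(pmax(M %*% W1, 0) %*% w2)
    x <- rnorm(d)
    bg <- matrix(rnorm(20 * d), 20, d)
    phi <- exact_shapley(f, x, bg)
    # efficiency
    expect_equal(sum(phi), f(matrix(x, 1)) - mean(f(bg)), tolerance = 1e-10)
    # null feature: a disconnected input gets zero
    W1n <- W1; W1n[3, ] <- 0
    fn <- function(M) drop(pmax(M %*% W1n, 0) %*% w2)
    expect_equal(exact_shapley(fn, x, bg)[3], 0, tolerance = 1e-12)
    # symmetry: duplicated features with identical roles and values
    cvec <- rnorm(d - 2)
    g <- function(M) {
      (M[, 1] + M[, 2])^2 + drop(M[, -(1:2), drop = FALSE] %*% cvec)
    }
    xs <- x; xs[2] <- xs[1]
    bgs <- bg; bgs[, 2] <- bgs[, 1]
    phis <- exact_shapley(g, xs, bgs)
    expect_equal(phis[1], phis[2], tolerance = 1e-10)
  }
})

test_that("sampled shapley is exact with exhaustive permutations and converges", {
  set.seed(11)
  d <- 3
  W1 <- matrix(rnorm(d * 5), d, 5)
  w2 <- rnorm(5)
  f <- function(M) drop(pmax(M %*% W1, 0) %*% w2)
  x <- rnorm(d)
  bg <- matrix(rnorm(15 * d), 15, d)
  exact <- exact_shapley(f, x, bg)
  # with enough draws of only 3! = 6 orders the estimate matches closely
  est <- sampled_shapley(f, x, bg, n_permutations = 3000, seed = 2)
  expect_equal(est, exact, tolerance = 0.02)
  # determinism
  expect_identical(sampled_shapley(f, x, bg, 50, seed = 9),
                   sampled_shapley(f, x, bg, 50, seed = 9))
  # error decreases with the permutation budget (in expectation; averaged
  # over repeats at three budgets)
  err <- vapply(c(5, 50, 500), function(np) {
    mean(vapply(1:5, function(r) {
      max(abs(sampled_shapley(f, x, bg, np, seed = 100 + r) - exact))
    }, numeric(1)))
  }, numeric(1))
  expect_true(err[3] < err[1])
})

test_that("model importance zeroes out disconnected metabolites", {
  pm <- toy_pm()
  cfg <- risk_model_config(input_dim = 3, depth = 2, pathway_informed = TRUE,
                           normalize = FALSE)
  m <- build_risk_model(cfg, pm)
  # disconnect lactate entirely (its mask row is 1,0,0,1 -> zero the weights)
  m$weights[[1]]$W[3, ] <- 0
  m$fitted <- TRUE
  set.seed(2)
  X <- matrix(rlnorm(30), 10, 3, dimnames = list(NULL, pm$metabolite_names))
  rep <- metabolite_importance(m, X, X)
  expect_equal(unname(rep$importance["lactate"]), 0, tolerance = 1e-12)
  expect_true(all(rep$importance >= 0))
  expect_setequal(rep$ranking, 1:3)
})

test_that("single-pathway model puts all pathway credit on that pathway", {
  pm <- pathway_matrix(matrix(c(1, 1, 0), 3, 1), paste0("m", 1:3), "only")
  cfg <- risk_model_config(input_dim = 3, depth = 2, pathway_informed = TRUE,
                           normalize = FALSE)
  m <- build_risk_model(cfg, pm)
  m$fitted <- TRUE
  set.seed(3)
  X <- matrix(rlnorm(15), 5, 3, dimnames = list(NULL, pm$metabolite_names))
  rep <- pathway_importance(m, X, X)
  # one-feature shapley is the efficiency identity per sample
  out <- drop(pathsurv:::subnetwork_forward(m, pathway_activations(m, X)))
  bgm <- mean(out)
  expect_equal(unname(rep$attributions[, 1]), out - bgm, tolerance = 1e-10)
})

test_that("contribution flows are nonnegative and sum to pathway importance", {
  pm <- toy_pm()
  co <- simulate_cohort(simulation_config(n = 80, pm = pm,
                                          active_pathways = c(1, 3),
                                          pathway_effects = c(1.5, -1),
                                          seed = 9))
  cfg <- risk_model_config(input_dim = 3, depth = 3, pathway_informed = TRUE,
                           max_epochs = 60, seed = 2)
  m <- fit_risk_model(build_risk_model(cfg, pm), co$data)
  X <- co$data$features[1:20, ]
  bg <- co$data$features[21:60, ]
  mrep <- metabolite_importance(m, X, bg, seed = 4)
  prep <- pathway_importance(m, X, bg, seed = 4)
  flows <- contribution_flows(m, mrep, prep)
  expect_true(all(flows$flow >= 0))
  sums <- tapply(flows$flow, flows$pathway, sum)
  expect_equal(as.numeric(sums[prep$feature_names]),
               unname(prep$importance), tolerance = 1e-8)
  # every flow follows a mask edge
  for (r in seq_len(nrow(flows))) {
    i <- match(flows$metabolite[r], pm$metabolite_names)
    j <- match(flows$pathway[r], pm$pathway_names)
    expect_equal(pm$matrix[i, j], 1)
  }
})
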