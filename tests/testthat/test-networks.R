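test_that("masked model has the expected nonzero parameter count", {
  pm <- example_pathway_matrix()
  cfg <- risk_model_config(input_dim = 37, depth = 3, pathway_informed = TRUE)
  m <- build_risk_model(cfg, pm)
  # 468 masked weights + 138 biases + (138*64 + 64) + (64 + 1)
  expect_equal(n_parameters(m), 468L + 138L + 138L * 64L + 64L + 64L + 1L)
  expect_equal(m$dims, c(37L, 138L, 64L, 1L))
  # masked positions are exactly zero at initialization
  expect_true(all(m$weights[[1]]$W[pm$matrix == 0] == 0))
  # depth 2 removes the hidden layer; depth 4 repeats it
  expect_equal(build_risk_model(risk_model_config(37, 2, TRUE), pm)$dims,
               c(37L, 138L, 1L))
  expect_equal(build_risk_model(risk_model_config(37, 4, TRUE), pm)$dims,
               c(37L, 138L, 64L, 64L, 1L))
})

test_that("forward pass obeys trivial identities", {
  pm <- toy_pm()
  cfg <- risk_model_config(input_dim = 3, depth = 2, pathway_informed = TRUE,
                           normalize = FALSE)
  m <- build_risk_model(cfg, pm)
  X <- matrix(rlnorm(15), 5, 3,
              dimnames = list(NULL, pm$metabolite_names))
  # zero weights give zero risks
  m0 <- m
  for (l in seq_along(m0$weights)) {
    m0$weights[[l]]$W[] <- 0
    m0$weights[[l]]$b[] <- 0
  }
  expect_equal(forward_risk(m0, X), rep(0, 5))
  # an all-zero mask leaves only the bias: activations are ReLU(b)
  zero_pm <- pathway_matrix(matrix(0, 3, 4), pm$metabolite_names,
                            pm$pathway_names)
  mz <- build_risk_model(cfg, zero_pm)
  mz$weights[[1]]$b <- c(-1, 0.5, 2, -3)
  pa <- pathway_activations(mz, X)
  expect_equal(unname(pa), matrix(rep(c(0, 0.5, 2, 0), each = 5), 5, 4))
  # row permutation equivariance
  p <- c(3, 1, 5, 2, 4)
  expect_equal(forward_risk(m, X[p, ]), forward_risk(m, X)[p])
  expect_error(forward_risk(m, X[, 1:2]), "columns")
  expect_error(forward_risk(m, X * NA), "finite")
})

test_that("classification head returns sigmoid probabilities", {
  cfg <- risk_model_config(input_dim = 2, depth = 2,
                           head = "classification", normalize = FALSE)
  m <- build_risk_model(cfg)
  for (l in seq_along(m$weights)) {
    m$weights[[l]]$W[] <- 0
    m$weights[[l]]$b[] <- 0
  }
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(forward_risk(m, X), rep(0.5, 4))
})

test_that("training never touches masked weights and keeps PA nonnegative", {
  pm <- example_pathway_matrix()
  co <- simulate_cohort(simulation_config(n = 80, pm = pm, seed = 21))
  cfg <- risk_model_config(input_dim = 37, depth = 3, pathway_informed = TRUE,
                           max_epochs = 100, seed = 5)
  m <- fit_risk_model(build_risk_model(cfg, pm), co$data)
  expect_equal(m$epochs_trained, 100L)
  expect_true(all(m$weights[[1]]$W[pm$matrix == 0] == 0))
  pa <- pathway_activations(m, co$data$features)
  expect_true(all(pa >= 0))
  # dense model refuses pathway activations
  dm <- build_risk_model(risk_model_config(input_dim = 37, depth = 3))
  expect_error(pathway_activations(dm, co$data$features),
               "pathway-informed")
})

test_that("training is reproducible given the seed", {
  pm <- toy_pm()
  co <- simulate_cohort(simulation_config(n = 60, pm = pm,
                                          active_pathways = 1:2,
                                          pathway_effects = c(1, -1),
                                          seed = 2))
  cfg <- risk_model_config(input_dim = 3, depth = 3, pathway_informed = TRUE,
                           dropout_rate = 0.5, max_epochs = 30, seed = 8)
  m1 <- fit_risk_model(build_risk_model(cfg, pm), co$data)
  m2 <- fit_risk_model(build_risk_model(cfg, pm), co$data)
  expect_identical(m1$weights, m2$weights)
})

test_that("checkpoints round-trip through save/load", {
  pm <- toy_pm()
  cfg <- risk_model_config(input_dim = 3, depth = 2, pathway_informed = TRUE)
  m <- build_risk_model(cfg, pm)
  path <- tempfile(fileext = ".rds")
  save_risk_model(m, path)
  back <- load_risk_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$config, m$config)
})

test_that("classical cox fit recovers null covariates and ignores duplication", {
  pm <- pathway_matrix(diag(3), paste0("m", 1:3), paste0("p", 1:3))
  co <- simulate_cohort(simulation_config(
    n = 600, pm = pm, active_pathways = 1:3, pathway_effects = c(1, -1, 0),
    noise_sd = 0, seed = 31))
  Z <- co$pathway_scores
  beta <- fit_cox_ph(Z, co$data$events, co$data$durations)
  expect_lt(abs(beta[3]), 0.12)
  expect_gt(beta[1], 0.7)
  # duplicating every sample rescales the likelihood but not its argmax
  beta2 <- fit_cox_ph(rbind(Z, Z), rep(co$data$events, 2),
                      rep(co$data$durations, 2))
  expect_equal(unname(beta2), unname(beta), tolerance = 1e-4)
  expect_error(fit_cox_ph(cbind(Z, const = 1), co$data$events,
                          co$data$durations), "constant")
})
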