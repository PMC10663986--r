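# Pathway-informed sparse networks and dense baselines, trained full-batch
# with Adam and early stopping. The first layer of a pathway-informed model
# is a dense weight matrix multiplied elementwise by the binary incidence
# mask, so a connection exists only where a metabolite belongs to a pathway;
# gradients at masked positions are identically zero, hence those weights
# stay exactly 0 throughout training.

#' Configuration of a risk model
#'
#' @param input_dim number of input metabolites P.
#' @param depth number of trainable layers (1-4). Depth 3 is: first (pathway
#'   or dense) layer, one hidden layer, output head. Depth 2 removes the
#'   hidden layer, depth 4 repeats it; depth 1 is a bare linear model (used
#'   to validate the Cox-loss trainer against a classical Cox fit).
#' @param pathway_informed mask the first layer with an incidence matrix?
#' @param hidden_width width of the hidden layer(s); default 64.
#' @param first_width width of the first layer for dense models (default
#'   `hidden_width`; set to the number of pathways for the width-matched
#'   dense ablation). Ignored when `pathway_informed`.
#' @param loss one of "cox", "deephit", "pc_hazard", "bce".
#' @param head "survival" or "classification" (classification implies "bce").
#' @param n_intervals number m of time bins / hazard pieces for the
#'   discrete-time and piecewise-constant losses.
#' @param deephit_alpha,deephit_sigma combination weight and ranking scale of
#'   the discrete-time loss.
#' @param dropout_rate dropout after the first hidden activation (training
#'   only); used by the dropout ablation.
#' @param learning_rate,max_epochs,patience full-batch Adam step size,
#'   epoch cap, and early-stopping patience (epochs without validation
#'   improvement).
#' @param normalize z-score features with training-fold statistics?
#' @param seed integer seed for weight initialization and dropout.
#' @return object of class `risk_model_config`.
#' @export
risk_model_config <- function(input_dim,
                              depth = 3L,
                              pathway_informed = FALSE,
                              hidden_width = 64L,
                              first_width = NULL,
                              loss = c("cox", "deephit", "pc_hazard", "bce"),
                              head = c("survival", "classification"),
                              n_intervals = 10L,
                              deephit_alpha = 0.8,
                              deephit_sigma = 0.5,
                              dropout_rate = 0,
                              learning_rate = 0.01,
                              max_epochs = 500L,
                              patience = 10L,
                              normalize = TRUE,
                              seed = 1L) {
  loss <- match.arg(loss)
  head <- match.arg(head)
  if (head == "classification") loss <- "bce"
  if (loss == "bce") head <- "classification"
  depth <- as.integer(depth)
  if (!depth %in% 1:4) stop("depth must be 1, 2, 3 or 4")
  if (pathway_informed && depth < 2L) {
    stop("a pathway-informed model needs depth >= 2")
  }
  if (hidden_width < 1L) stop("hidden_width must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  structure(list(
    input_dim = as.integer(input_dim), depth = depth,
    pathway_informed = isTRUE(pathway_informed),
    hidden_width = as.integer(hidden_width),
    first_width = if (!is.null(first_width)) as.integer(first_width),
    loss = loss, head = head, n_intervals = as.integer(n_intervals),
    deephit_alpha = deephit_alpha, deephit_sigma = deephit_sigma,
    dropout_rate = dropout_rate, learning_rate = learning_rate,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    normalize = isTRUE(normalize), seed = as.integer(seed)
  ), class = "risk_model_config")
}

n_outputs <- function(cfg) {
  if (cfg$loss %in% c("cox", "bce")) 1L else cfg$n_intervals
}

layer_dims <- function(cfg, pm = NULL) {
  p <- cfg$input_dim
  if (cfg$depth == 1L) return(c(p, n_outputs(cfg)))
  first <- if (cfg$pathway_informed) {
    length(pm$pathway_names)
  } else {
    cfg$first_width %||% cfg$hidden_width
  }
  c(p, first, rep(cfg$hidden_width, cfg$depth - 2L), n_outputs(cfg))
}

#' Build (initialize) a risk model
#'
#' Weights use He-style uniform fan-in initialization
#' (U(-sqrt(6 / fan_in), sqrt(6 / fan_in))), biases start at zero, and the
#' first-layer weight matrix of a pathway-informed model is multiplied by
#' the incidence mask so masked positions are exactly zero from the start.
#'
#' @param cfg a [risk_model_config()].
#' @param pm a [pathway_matrix()]; required when `cfg$pathway_informed`, its
#'   row order must match the model's input features.
#' @return object of class `risk_model` (unfitted).
#' @export
build_risk_model <- function(cfg, pm = NULL) {
  stopifnot(inherits(cfg, "risk_model_config"))
  mask <- NULL
  if (cfg$pathway_informed) {
    if (is.null(pm)) stop("pathway-informed model requires a pathway_matrix")
    stopifnot(inherits(pm, "pathway_matrix"))
    if (nrow(pm$matrix) != cfg$input_dim) {
      stop("pathway matrix has ", nrow(pm$matrix),
           " metabolite rows but input_dim is ", cfg$input_dim)
    }
    mask <- pm$matrix
  }
  dims <- layer_dims(cfg, pm)
  weights <- with_seed(cfg$seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      lim <- sqrt(6 / fan_in)
      W <- matrix(stats::runif(fan_in * dims[l + 1L], -lim, lim),
                  fan_in, dims[l + 1L])
      if (l == 1L && !is.null(mask)) W <- W * mask
      list(W = W, b = numeric(dims[l + 1L]))
    })
  })
  structure(list(config = cfg, weights = weights, mask = mask,
                 pathway_names = if (cfg$pathway_informed) pm$pathway_names,
                 metabolite_names = if (cfg$pathway_informed) {
                   pm$metabolite_names
                 },
                 dims = dims, norm = NULL, grid = NULL, baseline = NULL,
                 class_weights = NULL, fitted = FALSE, epochs_trained = 0L),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<risk_model> depth %d | %s first layer | loss %s | %s\n",
              cfg$depth,
              if (cfg$pathway_informed) "pathway-masked" else "dense",
              cfg$loss, if (x$fitted) {
                sprintf("fitted (%d epochs)", x$epochs_trained)
              } else "unfitted"))
  cat("  layer dims:", paste(x$dims, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of trainable (non-masked) parameters
#' @param model a `risk_model`.
#' @export
n_parameters <- function(model) {
  tot <- 0L
  for (l in seq_along(model$weights)) {
    W <- model$weights[[l]]$W
    nw <- if (l == 1L && !is.null(model$mask)) sum(model$mask) else length(W)
    tot <- tot + nw + length(model$weights[[l]]$b)
  }
  as.integer(tot)
}

apply_norm <- function(model, X) {
  if (is.null(model$norm)) return(X)
  sweep(sweep(X, 2L, model$norm$center, "-"), 2L, model$norm$scale, "/")
}

# Forward pass on (already normalized) X. Returns output and per-layer
# activations for backprop. Dropout (inverted) is applied after the first
# hidden activation only, when training = TRUE.
nn_forward <- function(model, X, training = FALSE) {
  L <- length(model$weights)
  acts <- vector("list", L + 1L)
  zs <- vector("list", L)
  drop_mask <- NULL
  acts[[1L]] <- X
  A <- X
  rate <- model$config$dropout_rate
  for (l in seq_len(L)) {
    W <- model$weights[[l]]$W
    if (l == 1L && !is.null(model$mask)) W <- W * model$mask
    Z <- A %*% W
    Z <- sweep(Z, 2L, model$weights[[l]]$b, "+")
    zs[[l]] <- Z
    if (l < L) {
      A <- relu(Z)
      if (l == 1L && training && rate > 0) {
        drop_mask <- matrix(stats::rbinom(length(A), 1L, 1 - rate) / (1 - rate),
                            nrow(A), ncol(A))
        A <- A * drop_mask
      }
      acts[[l + 1L]] <- A
    } else {
      acts[[l + 1L]] <- Z
      A <- Z
    }
  }
  list(out = A, acts = acts, zs = zs, drop_mask = drop_mask)
}

# Backward pass: dout is dLoss/d(linear output). Returns per-layer gradients.
nn_backward <- function(model, fw, dout) {
  L <- length(model$weights)
  grads <- vector("list", L)
  delta <- dout
  for (l in L:1) {
    A_prev <- fw$acts[[l]]
    dW <- crossprod(A_prev, delta)
    if (l == 1L && !is.null(model$mask)) dW <- dW * model$mask
    grads[[l]] <- list(W = dW, b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(model$weights[[l]]$W)) * (fw$zs[[l - 1L]] > 0)
      if (l - 1L == 1L && !is.null(fw$drop_mask)) {
        delta <- delta * fw$drop_mask
      }
    }
  }
  grads
}

# Loss value + gradient w.r.t. the network's linear outputs, on the
# optimizer's scale (averaged for learning-rate stability; the exported
# loss functions keep the literature's forms).
nn_loss_grad <- function(model, out, labels) {
  cfg <- model$config
  switch(cfg$loss,
    cox = {
      lg <- cox_nll_grad(drop(out), labels$events, labels$durations)
      s <- 1 / max(1, sum(labels$events))
      list(value = lg$value * s, dout = matrix(lg$grad * s, ncol = 1L))
    },
    deephit = {
      masses <- row_softmax(out)
      lg <- deephit_loss_grad(masses, labels$events, labels$bins,
                              cfg$deephit_alpha, cfg$deephit_sigma)
      s <- 1 / nrow(out)
      gm <- lg$grad_masses
      dlogit <- masses * (gm - rowSums(gm * masses))
      list(value = lg$value * s, dout = dlogit * s)
    },
    pc_hazard = {
      etas <- softplus(out)
      lg <- pc_hazard_loss_grad(etas, labels$events, labels$durations,
                                model$train_grid)
      list(value = lg$value, dout = lg$grad * sigmoid(out))
    },
    bce = {
      p <- sigmoid(drop(out))
      w <- model$class_weights %||% c(1, 1)
      value <- weighted_bce(p, labels$malignancy, w)
      wv <- ifelse(labels$malignancy == 1, w[2L], w[1L])
      list(value = value,
           dout = matrix(wv * (p - labels$malignancy) / length(p), ncol = 1L))
    })
}

make_labels <- function(model, ds) {
  lab <- list(events = ds$events, durations = ds$durations,
              malignancy = ds$malignancy)
  if (model$config$loss == "deephit") {
    lab$bins <- suppressWarnings(bin_index(ds$durations, model$grid))
  }
  if (model$config$loss == "pc_hazard") {
    # clamp beyond-horizon times once, silently (documented behavior), and
    # rescale to the unit-width training grid: the network learns hazard
    # rates per grid interval, which conditions the loss independently of
    # the duration units (days vs years); per-day rates are restored by
    # forward_risk.
    b <- model$grid$boundaries
    lab$durations <- pmin(pmax(ds$durations, b[1L]), b[length(b)]) /
      model$time_scale
  }
  if (model$config$loss == "bce" && is.null(ds$malignancy)) {
    stop("classification model requires malignancy labels")
  }
  lab
}

#' Fit a risk model by full-batch Adam with early stopping
#'
#' Feature normalization statistics, the time grid (for the discrete-time
#' and piecewise-constant losses), class weights (for classification, set
#' inversely proportional to class frequency) and the Breslow baseline
#' hazard (for Cox-loss survival models) are all computed on the training
#' set only. When a validation set is given, training stops after
#' `patience` epochs without improvement of the validation loss and the
#' best-validation weights are restored; there is no re-training on
#' train + validation afterwards.
#'
#' @param model an unfitted `risk_model` from [build_risk_model()].
#' @param train a [survival_dataset()] used for gradient steps.
#' @param val optional [survival_dataset()] for early stopping.
#' @return the fitted `risk_model`.
#' @export
fit_risk_model <- function(model, train, val = NULL) {
  stopifnot(inherits(model, "risk_model"), inherits(train, "survival_dataset"))
  cfg <- model$config
  if (!is.null(model$mask) &&
      !identical(model$metabolite_names, train$metabolite_names)) {
    bad <- union(setdiff(model$metabolite_names, train$metabolite_names),
                 setdiff(train$metabolite_names, model$metabolite_names))
    if (length(bad) > 0L) {
      stop("mask/feature name mismatch: ", paste(bad, collapse = ", "))
    }
    stop("mask rows and feature columns are ordered differently")
  }
  X <- train$features
  if (cfg$normalize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    model$norm <- list(center = center, scale = scale)
  }
  Xs <- apply_norm(model, X)
  if (cfg$loss %in% c("deephit", "pc_hazard")) {
    model$grid <- uniform_time_grid(train$durations, cfg$n_intervals)
    # uniform grid: one interval = one unit on the internal training axis
    model$time_scale <- model$grid$widths[1L]
    model$train_grid <- time_grid(model$grid$boundaries / model$time_scale)
  }
  if (cfg$loss == "bce") {
    if (is.null(train$malignancy)) stop("training data lack malignancy labels")
    n <- length(train$malignancy); n1 <- sum(train$malignancy)
    if (n1 == 0 || n1 == n) stop("training data contain a single class")
    model$class_weights <- c(n / (2 * (n - n1)), n / (2 * n1))
  }
  labels <- make_labels(model, train)
  val_x <- NULL; val_labels <- NULL
  if (!is.null(val)) {
    val_x <- apply_norm(model, val$features)
    val_labels <- make_labels(model, val)
    if (cfg$loss == "cox" && sum(val$events) < 1) {
      val_x <- NULL  # validation loss undefined; fall back to full training
    }
  }

  # Adam state
  mom <- lapply(model$weights, function(w) {
    list(mW = 0 * w$W, vW = 0 * w$W, mb = 0 * w$b, vb = 0 * w$b)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- cfg$learning_rate
  best <- list(loss = Inf, weights = model$weights, epoch = 0L)
  wait <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      fw <- nn_forward(model, Xs, training = TRUE)
      lg <- nn_loss_grad(model, fw$out, labels)
      grads <- nn_backward(model, fw, lg$dout)
      t_ <- epoch
      for (l in seq_along(model$weights)) {
        g <- grads[[l]]
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * g$W
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * g$W^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * g$b
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * g$b^2
        mhW <- mom[[l]]$mW / (1 - b1^t_)
        vhW <- mom[[l]]$vW / (1 - b2^t_)
        mhb <- mom[[l]]$mb / (1 - b1^t_)
        vhb <- mom[[l]]$vb / (1 - b2^t_)
        model$weights[[l]]$W <- model$weights[[l]]$W -
          lr * mhW / (sqrt(vhW) + eps)
        model$weights[[l]]$b <- model$weights[[l]]$b -
          lr * mhb / (sqrt(vhb) + eps)
        if (l == 1L && !is.null(model$mask)) {
          model$weights[[l]]$W <- model$weights[[l]]$W * model$mask
        }
      }
      model$epochs_trained <- epoch
      if (!is.null(val_x)) {
        vfw <- nn_forward(model, val_x, training = FALSE)
        vloss <- nn_loss_grad(model, vfw$out, val_labels)$value
        if (is.finite(vloss) && vloss < best$loss - 1e-9) {
          best <- list(loss = vloss, weights = model$weights, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
  })
  if (!is.null(val_x) && is.finite(best$loss)) {
    model$weights <- best$weights
    model$epochs_trained <- best$epoch
  }
  model$fitted <- TRUE
  if (cfg$loss == "cox" && cfg$head == "survival") {
    risks <- drop(nn_forward(model, Xs)$out)
    model$baseline <- breslow_baseline(risks, train$events, train$durations)
  }
  model
}

#' Model outputs on new data
#'
#' Applies the stored normalization and returns, depending on the model's
#' loss: a risk-score vector ("cox"), an N x m matrix of per-bin probability
#' masses ("deephit", softmax), an N x m matrix of nonnegative hazard-rate
#' constants ("pc_hazard", softplus) or a probability vector ("bce",
#' sigmoid). Deterministic given the weights (dropout is inactive).
#'
#' @param model a `risk_model`.
#' @param X numeric matrix with P columns.
#' @export
forward_risk <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  if (ncol(X) != model$config$input_dim) {
    stop("input has ", ncol(X), " columns; model expects ",
         model$config$input_dim)
  }
  out <- nn_forward(model, apply_norm(model, X))$out
  switch(model$config$loss,
         cox = drop(out),
         deephit = row_softmax(out),
         # per-interval unit rates back to the grid's original time units
         pc_hazard = softplus(out) / (model$time_scale %||% 1),
         bce = drop(sigmoid(out)))
}

#' Pathway-layer activations
#'
#' The post-ReLU outputs of the masked first layer, one column per pathway
#' (nonnegative by construction).
#'
#' @param model a pathway-informed `risk_model`.
#' @param X numeric matrix with P columns.
#' @return N x Q matrix with pathway names as columns.
#' @export
pathway_activations <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(model$mask)) {
    stop("pathway activations are only defined for pathway-informed models")
  }
  X <- as.matrix(X)
  Xs <- apply_norm(model, X)
  W <- model$weights[[1L]]$W * model$mask
  A <- relu(sweep(Xs %*% W, 2L, model$weights[[1L]]$b, "+"))
  colnames(A) <- model$pathway_names
  A
}

# Forward through layers 2..L given pathway activations (used by the
# pathway-level attribution).
subnetwork_forward <- function(model, PA) {
  L <- length(model$weights)
  A <- as.matrix(PA)
  for (l in 2:L) {
    Z <- sweep(A %*% model$weights[[l]]$W, 2L, model$weights[[l]]$b, "+")
    A <- if (l < L) relu(Z) else Z
  }
  A
}

#' Save / load a fitted model
#'
#' The checkpoint is a single RDS archive holding a versioned schema with
#' weights, mask, normalization statistics, config and seed.
#'
#' @param model a `risk_model`.
#' @param path file path.
#' @export
save_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  saveRDS(list(schema = "pathsurv-risk-model/1", model = model), path)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "pathsurv-risk-model/1")) {
    stop("unrecognized checkpoint schema")
  }
  obj$model
}

#' Classical linear Cox proportional-hazards fit
#'
#' Fits h(x) = beta' x by maximizing the Breslow-tied partial likelihood
#' (Newton iterations via [survival::coxph()]). On non-convergence or
#' separation-like divergence the fit is retried with a small ridge penalty
#' and a warning.
#'
#' @param X numeric covariate matrix (no constant columns).
#' @param events binary event indicators (at least one event).
#' @param durations observed times.
#' @return named numeric coefficient vector beta.
#' @export
fit_cox_ph <- function(X, events, durations) {
  X <- as.matrix(X)
  if (sum(events) < 1) stop("at least one event is required")
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant covariate column(s): ",
         paste(colnames(X)[apply(X, 2L, stats::sd) == 0], collapse = ", "))
  }
  y <- survival::Surv(durations, events)
  fit <- tryCatch(
    survival::coxph(y ~ X, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100,
                                                      eps = 1e-10)),
    warning = function(w) w, error = function(e) e)
  if (inherits(fit, "warning") || inherits(fit, "error") ||
      any(!is.finite(stats::coef(fit)))) {
    warning("Cox fit did not converge cleanly; refitting with a small ridge")
    fit <- survival::coxph(y ~ survival::ridge(X, theta = 1e-4),
                           ties = "breslow")
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  beta
}
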