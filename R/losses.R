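# Training objectives: Cox negative log partial likelihood, discrete-time
# (DeepHit-style) likelihood + ranking loss, piecewise-constant-hazard
# likelihood, and class-weighted binary cross entropy. Each public loss
# returns the value in the form printed in the survival literature; the
# *_grad internals additionally return analytic gradients used by the
# full-batch trainer.

#' Time grid of interval boundaries
#'
#' Ordered boundaries T0 < T1 < ... < Tfinal shared by the discrete-time
#' model's bins and the piecewise-constant-hazard pieces. A grid with
#' boundaries of length m + 1 has m intervals.
#'
#' @param boundaries strictly increasing nonnegative numeric vector.
#' @return object of class `time_grid` with fields `boundaries`, `m`,
#'   `widths`.
#' @export
time_grid <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) stop("a time grid needs at least 2 boundaries")
  if (any(!is.finite(boundaries)) || any(boundaries < 0)) {
    stop("boundaries must be finite and nonnegative")
  }
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries,
                 m = length(boundaries) - 1L,
                 widths = diff(boundaries)),
            class = "time_grid")
}

#' Uniform time grid covering observed durations
#'
#' @param durations observed times; the grid spans [0, max(durations)].
#' @param m number of equal-width intervals.
#' @export
uniform_time_grid <- function(durations, m) {
  upper <- max(durations)
  if (upper <= 0) stop("durations must contain a positive time")
  time_grid(seq(0, upper, length.out = m + 1L))
}

#' Interval index and interval fraction of a time on a grid
#'
#' For time t in interval kappa = k (the interval whose left boundary is the
#' largest boundary <= t), the fraction rho = (t - T_{k-1}) / (T_k - T_{k-1})
#' in [0, 1]. A time equal to a left boundary has rho = 0 in that interval;
#' t = Tfinal has kappa = m and rho = 1. Times outside the grid are clamped
#' to the nearest boundary with a warning (new data may exceed the training
#' horizon).
#'
#' @param t nonnegative time(s).
#' @param grid a [time_grid()].
#' @return list with integer vector `kappa` and numeric vector `rho`.
#' @export
interval_fraction <- function(t, grid) {
  stopifnot(inherits(grid, "time_grid"))
  b <- grid$boundaries
  m <- grid$m
  t <- as.numeric(t)
  if (any(t < b[1L]) || any(t > b[m + 1L])) {
    warning("time(s) outside the grid clamped to the nearest boundary")
    t <- pmin(pmax(t, b[1L]), b[m + 1L])
  }
  kappa <- findInterval(t, b)
  kappa[kappa > m] <- m  # t == Tfinal belongs to the last interval
  rho <- (t - b[kappa]) / grid$widths[kappa]
  list(kappa = as.integer(kappa), rho = rho)
}

#' Discrete bin index of event times on a grid
#'
#' @inheritParams interval_fraction
#' @return integer vector of interval indices in 1..m.
#' @export
bin_index <- function(t, grid) interval_fraction(t, grid)$kappa

# ---- Cox partial likelihood ------------------------------------------------

# Value and gradient of the Cox negative log partial likelihood.
# Risk set: R(i) = {j : durations[j] >= durations[i]} (self-inclusive);
# ties handled by the Breslow approximation (tied events share the same
# risk-set denominator). Log-sum-exp stabilized; O(n log n).
cox_nll_grad <- function(risks, events, durations) {
  n <- length(risks)
  stopifnot(length(events) == n, length(durations) == n)
  if (sum(events) < 1) stop("Cox partial likelihood undefined with no events")
  ord <- order(durations)
  r <- risks[ord]; e <- events[ord]; d <- durations[ord]
  mx <- max(r)
  # suffix log-sum-exp: lse[k] = log sum_{j >= k} exp(r_j)
  lse <- log(rev(cumsum(rev(exp(r - mx))))) + mx
  new_grp <- !duplicated(d)
  grp <- cumsum(new_grp)                     # tie-group id, ascending time
  start <- which(new_grp)                    # first index of each group
  end <- c(start[-1L] - 1L, n)               # last index of each group
  log_denom <- lse[start[grp]]               # risk set = suffix from group start
  value <- -sum(e * (r - log_denom))
  # grad_k = -e_k + exp(r_k) * sum_{events i : d_i <= d_k} 1 / denom_i
  cum <- cumsum(e * exp(-log_denom))
  grad_sorted <- -e + exp(r) * cum[end[grp]]
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  list(value = value, grad = grad)
}

#' Cox negative log partial likelihood
#'
#' Breslow-tied negative log partial likelihood of risk scores:
#' \deqn{-\sum_{i: e_i = 1} \left[h_i - \log \sum_{j: t_j \ge t_i} e^{h_j}\right]}
#' with the standard self-inclusive risk set. The value is invariant to
#' adding a constant to all risks.
#'
#' @param risks numeric vector of predicted risk scores.
#' @param events binary event indicators (at least one event).
#' @param durations observed times.
#' @return nonnegative scalar.
#' @export
cox_nll <- function(risks, events, durations) {
  cox_nll_grad(risks, events, durations)$value
}

# ---- DeepHit-style discrete-time loss --------------------------------------

# Value and gradient (w.r.t. the probability masses) of the combined
# discrete-time loss: alpha * loss_L + (1 - alpha) * loss_rank.
deephit_loss_grad <- function(masses, events, bins, alpha, sigma,
                              eps = 1e-15) {
  masses <- as.matrix(masses)
  n <- nrow(masses); m <- ncol(masses)
  stopifnot(length(events) == n, length(bins) == n)
  if (any(bins < 1L | bins > m)) stop("bin indices must lie in 1..m")
  if (any(masses < -1e-9) || any(abs(rowSums(masses) - 1) > 1e-6)) {
    stop("hazard masses must be nonnegative and sum to 1 per sample")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  cum <- t(apply(masses, 1L, cumsum))
  S <- 1 - cum                               # S[i, j] = S(T_j | i)
  ii <- cbind(seq_len(n), bins)
  mass_at <- masses[ii]
  S_at <- S[ii]
  loss_L <- -sum(events * log(pmax(mass_at, eps)) +
                   (1 - events) * log(pmax(S_at, eps)))
  gmass <- matrix(0, n, m)
  ev <- which(events == 1)
  gmass[ii[events == 1, , drop = FALSE]] <-
    -1 / pmax(mass_at[events == 1], eps)
  for (i in which(events == 0)) {
    gmass[i, seq_len(bins[i])] <- 1 / pmax(S_at[i], eps)
  }
  # ranking loss over comparable pairs: i an event, bin_j > bin_i
  loss_rank <- 0
  grank <- matrix(0, n, m)
  for (i in ev) {
    js <- which(bins > bins[i])
    if (length(js) == 0L) next
    terms <- exp((S_at[i] - S[js, bins[i]]) / sigma)
    loss_rank <- loss_rank + sum(terms)
    # dS_i/dmass[i, k <= bin_i] = -1; dS_j/dmass[j, k <= bin_i] = -1
    grank[i, seq_len(bins[i])] <- grank[i, seq_len(bins[i])] -
      sum(terms) / sigma
    for (a in seq_along(js)) {
      j <- js[a]
      grank[j, seq_len(bins[i])] <- grank[j, seq_len(bins[i])] +
        terms[a] / sigma
    }
  }
  list(value = alpha * loss_L + (1 - alpha) * loss_rank,
       loss_L = loss_L, loss_rank = loss_rank,
       grad_masses = alpha * gmass + (1 - alpha) * grank)
}

#' Discrete-time survival loss (likelihood + ranking)
#'
#' The combined discrete-time loss `alpha * loss_L + (1 - alpha) *
#' loss_rank`. `loss_L` is the negative log-likelihood of the per-bin
#' probability masses: an event in bin k contributes -log h_k, a censoring
#' in bin k contributes -log S(T_k) with S(T_j) = 1 - sum_{l <= j} h_l.
#' `loss_rank` sums exp((S_i(T_i) - S_j(T_i)) / sigma) over comparable pairs
#' (i an event, j with a strictly later bin), rewarding models that assign
#' the earlier event the lower survival at its own event time.
#'
#' @param masses N x m matrix of per-bin probability masses (rows sum to 1).
#' @param events binary event indicators.
#' @param bins integer bin index of each sample's observed time (1..m).
#' @param alpha weight in [0, 1] combining the two losses.
#' @param sigma positive scale of the ranking kernel.
#' @return scalar loss value.
#' @export
deephit_loss <- function(masses, events, bins, alpha = 0.5, sigma = 0.1) {
  deephit_loss_grad(masses, events, bins, alpha, sigma)$value
}

# ---- piecewise-constant-hazard loss ----------------------------------------

# Value and gradient (w.r.t. eta) of the piecewise-constant-hazard mean
# negative log likelihood. etas are hazard-rate constants per interval.
pc_hazard_loss_grad <- function(etas, events, durations, grid, eps = 1e-12) {
  stopifnot(inherits(grid, "time_grid"))
  etas <- as.matrix(etas)
  n <- nrow(etas); m <- ncol(etas)
  stopifnot(m == grid$m, length(events) == n, length(durations) == n)
  if (any(etas < 0)) stop("hazard constants must be nonnegative")
  fr <- interval_fraction(durations, grid)
  kap <- fr$kappa; rho <- fr$rho
  w <- grid$widths
  ii <- cbind(seq_len(n), kap)
  eta_at <- pmax(etas[ii], eps)
  # prior_i = sum_{j < kappa_i} eta_ij * dT_j (full intervals before the one
  # containing t)
  cum_exposure <- t(apply(sweep(etas, 2L, w, "*"), 1L, cumsum))
  if (m == 1L) cum_exposure <- matrix(cum_exposure, ncol = 1L)
  prior <- ifelse(kap > 1L,
                  cum_exposure[cbind(seq_len(n), pmax(kap - 1L, 1L))], 0)
  ll <- events * log(eta_at) - etas[ii] * rho * w[kap] - prior
  value <- -mean(ll)
  grad <- matrix(0, n, m)
  # d(-ll_i)/d eta[i, kappa_i] = -(e_i / eta - rho_i w_kappa)
  grad[ii] <- -(events / eta_at - rho * w[kap])
  # d(-ll_i)/d eta[i, j < kappa_i] = w_j
  for (i in seq_len(n)) {
    if (kap[i] > 1L) {
      j <- seq_len(kap[i] - 1L)
      grad[i, j] <- grad[i, j] + w[j]
    }
  }
  list(value = value, grad = grad / n)
}

#' Piecewise-constant-hazard survival loss
#'
#' Mean negative log likelihood under a piecewise-constant hazard: for
#' sample i with observed time t in interval k = kappa(t) and fraction
#' rho(t), the contribution is
#' \deqn{-[e_i \log \eta_{ik} - \eta_{ik} \rho(t) \Delta T_k -
#'        \sum_{j<k} \eta_{ij} \Delta T_j]}
#' where eta are per-sample nonnegative hazard-rate constants and the last
#' two terms are the cumulative hazard exposure up to t.
#'
#' @param etas N x m matrix of nonnegative hazard-rate constants.
#' @param events binary event indicators.
#' @param durations observed times (within the grid; clamped otherwise).
#' @param grid a [time_grid()].
#' @return scalar loss value (mean over samples).
#' @export
pc_hazard_loss <- function(etas, events, durations, grid) {
  pc_hazard_loss_grad(etas, events, durations, grid)$value
}

# ---- class-weighted binary cross entropy -----------------------------------

#' Class-weighted binary cross entropy
#'
#' Mean of `w[y_i] * (-y_i log p_i - (1 - y_i) log(1 - p_i))`, with
#' probabilities clipped to [eps, 1 - eps]. Weighting a class by w is
#' equivalent to replicating its samples w times.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary labels.
#' @param class_weights length-2 positive vector `c(w0, w1)` for the
#'   negative and positive class.
#' @param eps clipping bound.
#' @return nonnegative scalar.
#' @export
weighted_bce <- function(probs, labels, class_weights = c(1, 1),
                         eps = 1e-12) {
  stopifnot(length(probs) == length(labels), length(class_weights) == 2L,
            all(class_weights > 0))
  p <- pmin(pmax(probs, eps), 1 - eps)
  w <- ifelse(labels == 1, class_weights[2L], class_weights[1L])
  mean(w * (-labels * log(p) - (1 - labels) * log(1 - p)))
}
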