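# Survival and classification metrics: Breslow baseline cumulative hazard,
# survival-curve construction for each model family, Harrell and
# time-dependent (Antolini) concordance, AUROC/AUPRC.

#' Breslow baseline cumulative hazard
#'
#' Nonparametric step estimate of the baseline cumulative hazard given
#' fitted risk scores: at each distinct event time t_i with d_i events,
#' the jump is d_i / sum_{j in R(i)} exp(h_j) with the self-inclusive risk
#' set R(i) = \{j : t_j >= t_i\}. Right-continuous, nondecreasing, zero
#' before the first event.
#'
#' @param risks fitted risk scores h.
#' @param events binary event indicators (at least one event).
#' @param durations observed times.
#' @return object of class `breslow_baseline` with `times` (distinct event
#'   times) and `cumhaz` (cumulative hazard at those times).
#' @export
breslow_baseline <- function(risks, events, durations) {
  if (sum(events) < 1) stop("at least one event is required")
  n <- length(risks)
  ord <- order(durations)
  r <- risks[ord]; e <- events[ord]; d <- durations[ord]
  mx <- max(r)
  suffix <- rev(cumsum(rev(exp(r - mx))))  # sum_{j >= k} exp(r_j - mx)
  new_grp <- !duplicated(d)
  grp <- cumsum(new_grp)
  start <- which(new_grp)
  denom <- suffix[start] * exp(mx)          # risk-set denominator per time
  d_events <- unname(vapply(split(e, grp), sum, numeric(1)))
  keep <- d_events > 0
  times <- unname(d[start][keep])
  jumps <- d_events[keep] / unname(denom[keep])
  structure(list(times = times, cumhaz = cumsum(jumps)),
            class = "breslow_baseline")
}

#' Evaluate a cumulative-hazard step function
#' @param baseline a [breslow_baseline()].
#' @param t times at which to evaluate (vectorized).
#' @return cumulative hazard, right-continuous in t and 0 before the first
#'   event time.
#' @export
cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$times)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Survival-curve matrix
#'
#' @param times ordered evaluation times.
#' @param S N x T matrix of survival probabilities, nonincreasing in time.
#' @export
survival_curve_matrix <- function(times, S) {
  S <- as.matrix(S)
  stopifnot(length(times) == ncol(S), !is.unsorted(times))
  if (any(S < -1e-9 | S > 1 + 1e-9)) stop("survival probabilities outside [0, 1]")
  if (any(matrixStats_rowDiffs_pos(S))) {
    stop("survival curves must be nonincreasing in time")
  }
  structure(list(times = as.numeric(times), S = S),
            class = "survival_curve_matrix")
}

# any increasing step along rows? (tolerance for float noise)
matrixStats_rowDiffs_pos <- function(S) {
  if (ncol(S) < 2L) return(FALSE)
  apply(S, 1L, function(x) any(diff(x) > 1e-9))
}

# step lookup: value of each curve at time t (right-continuous; 1 before the
# first evaluation time)
curves_at <- function(curves, t) {
  idx <- findInterval(t, curves$times)
  if (idx == 0L) return(rep(1, nrow(curves$S)))
  curves$S[, idx]
}

#' Survival curves for each model family
#'
#' * Cox-type: S(t | x) = exp(-Lambda0(t) * exp(h(x))) composing the risk
#'   score with a Breslow baseline.
#' * Discrete-time masses: S(T_j) = 1 - sum_{k <= j} h_k, evaluated at the
#'   grid's right boundaries.
#' * Piecewise-constant hazard: S(t) = exp(-(sum_{j < kappa} eta_j dT_j +
#'   eta_kappa rho dT_kappa)).
#'
#' @param risks risk-score vector (Cox-type).
#' @param baseline a [breslow_baseline()].
#' @param times evaluation times (default: the baseline's event times or the
#'   grid's right boundaries).
#' @return a [survival_curve_matrix()].
#' @export
cox_survival_curves <- function(risks, baseline, times = baseline$times) {
  L <- cumhaz_at(baseline, times)
  S <- exp(-outer(exp(risks), L))
  survival_curve_matrix(times, S)
}

#' @rdname cox_survival_curves
#' @param masses N x m matrix of per-bin probability masses.
#' @param grid a [time_grid()].
#' @export
deephit_survival_curves <- function(masses, grid) {
  masses <- as.matrix(masses)
  stopifnot(ncol(masses) == grid$m)
  S <- 1 - t(apply(masses, 1L, cumsum))
  if (grid$m == 1L) S <- matrix(S, ncol = 1L)
  S <- pmin(pmax(S, 0), 1)
  survival_curve_matrix(grid$boundaries[-1L], S)
}

#' @rdname cox_survival_curves
#' @param etas N x m matrix of nonnegative hazard-rate constants.
#' @export
pc_hazard_survival_curves <- function(etas, grid,
                                      times = grid$boundaries[-1L]) {
  etas <- as.matrix(etas)
  stopifnot(ncol(etas) == grid$m)
  fr <- suppressWarnings(interval_fraction(times, grid))
  w <- grid$widths
  cum <- t(apply(sweep(etas, 2L, w, "*"), 1L, cumsum))
  if (grid$m == 1L) cum <- matrix(cum, ncol = 1L)
  H <- vapply(seq_along(times), function(j) {
    k <- fr$kappa[j]
    prior <- if (k > 1L) cum[, k - 1L] else 0
    prior + etas[, k] * fr$rho[j] * w[k]
  }, numeric(nrow(etas)))
  if (nrow(etas) == 1L) H <- matrix(H, nrow = 1L)
  survival_curve_matrix(times, exp(-H))
}

#' Survival curves from a fitted model
#'
#' Dispatches on the model's loss; Cox-loss models use the Breslow baseline
#' estimated on their training fold.
#'
#' @param model a fitted `risk_model` with survival head.
#' @param X input matrix.
#' @param times optional evaluation times.
#' @export
survival_curves <- function(model, X, times = NULL) {
  stopifnot(inherits(model, "risk_model"), model$fitted)
  out <- forward_risk(model, X)
  switch(model$config$loss,
    cox = {
      if (is.null(model$baseline)) stop("model has no stored baseline hazard")
      cox_survival_curves(out, model$baseline,
                          times %||% model$baseline$times)
    },
    deephit = deephit_survival_curves(out, model$grid),
    pc_hazard = pc_hazard_survival_curves(out, model$grid,
                                          times %||%
                                            model$grid$boundaries[-1L]),
    stop("survival curves are undefined for a classification model"))
}

# Comparable pairs under right censoring: (i, j) with t_i < t_j and i an
# event; ties in duration where both are events count with weight 0.5 (the
# pair is counted once). Returns total pairs and concordant weight given a
# pairwise score function.
concordance_core <- function(score_i_vs_j, events, durations) {
  n <- length(durations)
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    later <- durations > durations[i]
    tied <- durations == durations[i] & events == 1 &
      seq_len(n) > i  # count each both-event tie once
    cmp <- which(later)
    if (length(cmp) > 0L) {
      den <- den + length(cmp)
      num <- num + sum(score_i_vs_j(i, cmp))
    }
    if (any(tied)) {
      den <- den + sum(tied)
      num <- num + 0.5 * sum(tied)
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Harrell concordance index
#'
#' Fraction of comparable pairs (i an event with t_i < t_j) in which the
#' earlier-event sample has the higher risk score; ties in risk count 0.5,
#' and duration ties where both samples are events count 0.5.
#'
#' @param risks risk scores.
#' @param events binary event indicators.
#' @param durations observed times.
#' @return value in [0, 1].
#' @export
harrell_cindex <- function(risks, events, durations) {
  concordance_core(function(i, js) {
    ifelse(risks[i] > risks[js], 1, ifelse(risks[i] == risks[js], 0.5, 0))
  }, events, durations)
}

#' Time-dependent (Antolini) concordance index
#'
#' Scores each comparable pair by the predicted survival at the earlier
#' (event) time: the pair (i event, t_i < t_j) is concordant when
#' S_i(t_i) < S_j(t_i). Ties count 0.5. When all curves share a baseline
#' hazard (proportional-hazards family), this reduces exactly to the
#' Harrell index on the risk scores.
#'
#' @param curves a [survival_curve_matrix()] evaluated at (at least) all
#'   event times.
#' @param events binary event indicators.
#' @param durations observed times.
#' @return value in [0, 1].
#' @export
antolini_cindex <- function(curves, events, durations) {
  stopifnot(inherits(curves, "survival_curve_matrix"))
  concordance_core(function(i, js) {
    s <- curves_at(curves, durations[i])
    ifelse(s[i] < s[js], 1, ifelse(s[i] == s[js], 0.5, 0))
  }, events, durations)
}

#' Binary classification metrics
#'
#' AUROC by the rank (Mann-Whitney) statistic, equivalent to trapezoidal
#' integration of the ROC curve with tied scores counted 0.5; AUPRC by
#' step integration of the precision-recall curve (average precision).
#'
#' @param probs predicted scores/probabilities.
#' @param labels binary labels (both classes present).
#' @return list with `auroc` and `auprc`.
#' @export
classification_metrics <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probs)
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # average precision over descending-score thresholds, ties grouped
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]; s <- probs[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, auprc = auprc)
}
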