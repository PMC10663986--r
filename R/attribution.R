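# Shapley-value attribution for model predictions: exact enumeration for
# small dimension, permutation sampling at scale, and importance reports
# for input metabolites and pathway-layer activations.
#
# The value function is interventional: v(S) = mean over background rows b
# of f(x with features outside S replaced by b). This makes the efficiency
# axiom exact: sum(phi) = f(x) - mean_b f(b).

# Build the coalition value vector for all 2^d subsets in one batched call.
# scoring_fn must accept a numeric matrix (rows = points) and return one
# score per row.
coalition_values <- function(scoring_fn, x, background) {
  d <- length(x)
  nb <- nrow(background)
  nsub <- bitwShiftL(1L, d)
  # subset membership matrix: nsub x d (bit i-1 of the row index)
  member <- vapply(seq_len(d), function(i) {
    bitwAnd(bitwShiftR(seq_len(nsub) - 1L, i - 1L), 1L) == 1L
  }, logical(nsub))
  if (d == 1L) member <- matrix(member, ncol = 1L)
  # nb background rows replicated per subset; switch each present feature's
  # column to x (one pass per feature, not per subset)
  big <- background[rep(seq_len(nb), times = nsub), , drop = FALSE]
  for (i in seq_len(d)) {
    big[rep(member[, i], each = nb), i] <- x[i]
  }
  scores <- scoring_fn(big)
  v <- colMeans(matrix(scores, nb, nsub))
  list(v = v, member = member)
}

#' Exact Shapley values by coalition enumeration
#'
#' Classic Shapley values of `scoring_fn` at `x`, with absent features
#' imputed from the background distribution (each coalition's value is the
#' mean score over background rows with the coalition's features fixed at
#' `x`). Satisfies efficiency (`sum(phi) = f(x) - mean_b f(b)`), symmetry
#' and the null-feature axiom. Cost is 2^d coalition evaluations; use
#' [sampled_shapley()] beyond `max_features` dimensions.
#'
#' @param scoring_fn function taking a numeric matrix (rows = points, d
#'   columns) and returning one scalar score per row.
#' @param x numeric vector of length d to explain.
#' @param background numeric matrix (B x d) of reference points.
#' @param max_features refuse exact enumeration beyond this dimension.
#' @return numeric attribution vector of length d.
#' @export
exact_shapley <- function(scoring_fn, x, background, max_features = 12L) {
  x <- as.numeric(x)
  d <- length(x)
  background <- as.matrix(background)
  stopifnot(ncol(background) == d)
  if (d > max_features) {
    stop("dimension ", d, " exceeds max_features = ", max_features,
         "; use sampled_shapley()")
  }
  cv <- coalition_values(scoring_fn, x, background)
  sizes <- rowSums(cv$member)
  # weight for adding feature i to subset S (i not in S): |S|! (d-|S|-1)! / d!
  wt <- exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - (0:(d - 1))) -
              lfactorial(d))
  phi <- numeric(d)
  bits <- bitwShiftL(1L, seq_len(d) - 1L)
  for (i in seq_len(d)) {
    without <- which(!cv$member[, i])
    with_i <- without + bits[i]
    phi[i] <- sum(wt[sizes[without] + 1L] * (cv$v[with_i] - cv$v[without]))
  }
  phi
}

#' Permutation-sampling Shapley estimate
#'
#' Unbiased Monte Carlo estimate of the Shapley values: for each sampled
#' feature order, features are switched from background to `x` one at a
#' time and the marginal score changes are attributed. Deterministic given
#' `seed`; the estimate converges to [exact_shapley()] as
#' `n_permutations` grows.
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled feature orders (>= 1).
#' @param seed integer seed.
#' @return numeric attribution vector of length d.
#' @export
sampled_shapley <- function(scoring_fn, x, background, n_permutations = 200L,
                            seed = 1L) {
  x <- as.numeric(x)
  d <- length(x)
  background <- as.matrix(background)
  stopifnot(ncol(background) == d, n_permutations >= 1)
  nb <- nrow(background)
  phi <- numeric(d)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(d)
      # points: background, then cumulative insertion of x along ord;
      # (d + 1) * nb rows, scored in one call
      big <- matrix(0, (d + 1L) * nb, d)
      blk <- background
      big[seq_len(nb), ] <- blk
      for (step in seq_len(d)) {
        blk[, ord[step]] <- x[ord[step]]
        big[(step * nb + 1L):((step + 1L) * nb), ] <- blk
      }
      scores <- scoring_fn(big)
      v <- vapply(0:d, function(s) {
        mean(scores[(s * nb + 1L):((s + 1L) * nb)])
      }, numeric(1))
      phi[ord] <- phi[ord] + diff(v)
    }
  })
  phi / n_permutations
}

new_attribution_report <- function(feature_names, attributions, x, bg_mean) {
  attributions <- as.matrix(attributions)
  colnames(attributions) <- feature_names
  importance <- colMeans(abs(attributions))
  structure(list(feature_names = feature_names,
                 attributions = attributions,
                 importance = importance,
                 ranking = order(importance, decreasing = TRUE),
                 x = x, background_mean = bg_mean),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, n = 10L, ...) {
  cat(sprintf("<attribution_report> %d features x %d samples\n",
              length(x$feature_names), nrow(x$attributions)))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  cat("  top features (mean |Shapley|):\n")
  for (i in top) {
    cat(sprintf("   %-45s %.4g\n", x$feature_names[i], x$importance[i]))
  }
  invisible(x)
}

model_scalar_scorer <- function(model) {
  loss <- model$config$loss
  if (!loss %in% c("cox", "bce")) {
    stop("attribution needs a scalar output; supported heads: ",
         "Cox-loss survival risk and classification probability")
  }
  function(M) forward_risk(model, M)
}

#' Per-metabolite Shapley importance of a fitted model
#'
#' Attributes the model's scalar output (Cox risk score or class
#' probability) to the P input metabolites for every row of `X`, using
#' exact enumeration when P is small and permutation sampling otherwise.
#' Importance is the mean absolute attribution across the evaluated
#' samples, so effects of opposite sign do not cancel.
#'
#' @param model a fitted `risk_model` with a scalar output.
#' @param X samples to explain (N x P).
#' @param background reference samples (e.g. the training fold).
#' @param n_permutations permutation budget per sample (sampling path).
#' @param max_exact use exact enumeration when P <= this.
#' @param seed integer seed.
#' @return an `attribution_report` over metabolites.
#' @export
metabolite_importance <- function(model, X, background,
                                  n_permutations = 50L, max_exact = 12L,
                                  seed = 1L) {
  stopifnot(inherits(model, "risk_model"), model$fitted)
  X <- as.matrix(X); background <- as.matrix(background)
  f <- model_scalar_scorer(model)
  d <- ncol(X)
  raw <- vapply(seq_len(nrow(X)), function(i) {
    if (d <= max_exact) {
      exact_shapley(f, X[i, ], background, max_features = max_exact)
    } else {
      sampled_shapley(f, X[i, ], background, n_permutations,
                      seed = seed + i)
    }
  }, numeric(d))
  attr_mat <- matrix(raw, ncol = d, byrow = TRUE)
  names <- colnames(X) %||% paste0("m", seq_len(d))
  new_attribution_report(names, attr_mat, X, colMeans(background))
}

#' Per-pathway Shapley importance of a pathway-informed model
#'
#' Treats each sample's pathway activations as the input of the
#' sub-network mapping activations to the output, with background
#' activations from the background samples, and attributes the scalar
#' output to the Q pathway units.
#'
#' @inheritParams metabolite_importance
#' @return an `attribution_report` over pathways.
#' @export
pathway_importance <- function(model, X, background, n_permutations = 50L,
                               max_exact = 12L, seed = 1L) {
  stopifnot(inherits(model, "risk_model"), model$fitted)
  if (is.null(model$mask)) {
    stop("pathway importance is only defined for pathway-informed models")
  }
  if (!model$config$loss %in% c("cox", "bce")) {
    stop("attribution needs a scalar output; supported heads: ",
         "Cox-loss survival risk and classification probability")
  }
  PA <- pathway_activations(model, X)
  PB <- pathway_activations(model, background)
  f <- if (model$config$loss == "bce") {
    function(A) drop(sigmoid(subnetwork_forward(model, A)))
  } else {
    function(A) drop(subnetwork_forward(model, A))
  }
  d <- ncol(PA)
  raw <- vapply(seq_len(nrow(PA)), function(i) {
    if (d <= max_exact) {
      exact_shapley(f, PA[i, ], PB, max_features = max_exact)
    } else {
      sampled_shapley(f, PA[i, ], PB, n_permutations, seed = seed + i)
    }
  }, numeric(d))
  attr_mat <- matrix(raw, ncol = d, byrow = TRUE)
  new_attribution_report(model$pathway_names, attr_mat, PA, colMeans(PB))
}

#' Metabolite-to-pathway contribution flows
#'
#' For every mask edge (metabolite m, pathway q), a nonnegative flow weight
#' apportioning pathway q's importance among its member metabolites. The
#' share of m in q is the mean (over the explained samples) absolute linear
#' Shapley contribution of m to q's pre-activation,
#' |W[m, q] * (x_m - background mean_m)| on the normalized scale; shares
#' are normalized so each pathway's incoming flows sum to its importance.
#' Pathways whose shares are all zero split their importance equally among
#' member edges.
#'
#' @param model a fitted pathway-informed `risk_model`.
#' @param metabolite_report report from [metabolite_importance()] (provides
#'   the explained samples and background).
#' @param pathway_report report from [pathway_importance()] on the same
#'   samples.
#' @return data.frame with columns metabolite, pathway, flow.
#' @export
contribution_flows <- function(model, metabolite_report, pathway_report) {
  stopifnot(inherits(model, "risk_model"), !is.null(model$mask))
  stopifnot(inherits(metabolite_report, "attribution_report"),
            inherits(pathway_report, "attribution_report"))
  X <- metabolite_report$x
  if (nrow(X) != nrow(pathway_report$attributions)) {
    stop("reports were computed on different sample sets")
  }
  Xs <- apply_norm(model, X)
  bg_raw <- matrix(metabolite_report$background_mean, 1L)
  bg_s <- drop(apply_norm(model, bg_raw))
  W <- model$weights[[1L]]$W * model$mask
  dev <- sweep(Xs, 2L, bg_s, "-")               # N x P deviations
  imp <- pathway_report$importance
  out <- list()
  for (q in seq_len(ncol(W))) {
    members <- which(model$mask[, q] == 1)
    if (length(members) == 0L) next
    share <- colMeans(abs(dev[, members, drop = FALSE] *
                            matrix(W[members, q], nrow(dev), length(members),
                                   byrow = TRUE)))
    tot <- sum(share)
    flow <- if (tot > 0) {
      imp[q] * share / tot
    } else {
      rep(imp[q] / length(members), length(members))
    }
    out[[length(out) + 1L]] <- data.frame(
      metabolite = model$metabolite_names[members],
      pathway = model$pathway_names[q],
      flow = unname(flow))
  }
  do.call(rbind, out)
}
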