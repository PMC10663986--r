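# Independent oracles and fixture builders shared across the suite. These
# deliberately use naive double-loop formulations so they stay independent
# of the vectorized implementations they check.

# Naive Cox negative log partial likelihood: double loop, self-inclusive
# risk set (t_j >= t_i), Breslow ties.
naive_cox_nll <- function(risks, events, durations) {
  total <- 0
  for (i in seq_along(risks)) {
    if (events[i] != 1) next
    denom <- 0
    for (j in seq_along(risks)) {
      if (durations[j] >= durations[i]) denom <- denom + exp(risks[j])
    }
    total <- total - (risks[i] - log(denom))
  }
  total
}

# Brute-force Harrell concordance: explicit pair enumeration with the same
# comparability convention (i an event with t_i < t_j; both-event duration
# ties count once with weight 0.5; risk ties weight 0.5).
naive_harrell <- function(risks, events, durations) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (events[i] == 1 && durations[i] < durations[j]) {
        den <- den + 1
        if (risks[i] > risks[j]) num <- num + 1
        else if (risks[i] == risks[j]) num <- num + 0.5
      } else if (i < j && events[i] == 1 && events[j] == 1 &&
                 durations[i] == durations[j]) {
        den <- den + 1
        num <- num + 0.5
      }
    }
  }
  num / den
}

# Random censored survival data for oracle comparisons.
random_survival_data <- function(n, seed, tie_prob = 0.2) {
  set.seed(seed)
  durations <- if (runif(1) < tie_prob) {
    sample(1:max(2, n %/% 2), n, replace = TRUE)  # force some ties
  } else {
    round(rexp(n, 0.1), 3)
  }
  events <- rbinom(n, 1, 0.7)
  if (sum(events) == 0) events[sample(n, 1)] <- 1
  list(risks = rnorm(n), events = events, durations = durations)
}

# Small toy incidence matrix
toy_pm <- function() {
  pathway_matrix(rbind(c(1, 1, 0, 1),
                       c(0, 1, 1, 0),
                       c(1, 0, 0, 1)),
                 c("glutamate", "alanine", "lactate"),
                 c("p1", "p2", "p3", "p4"))
}

# Disjoint-block mapping: Q pathways of 3 metabolites each, no overlap;
# pathway scores are then mutually independent, so a planted causal set is
# identifiable ground truth.
block_pm <- function(q = 12L, members = 3L) {
  p <- q * members
  mat <- matrix(0, p, q)
  for (k in seq_len(q)) mat[members * (k - 1L) + seq_len(members), k] <- 1
  pathway_matrix(mat, paste0("m", seq_len(p)), paste0("p", seq_len(q)))
}

# Write a small dataset to temp CSV files; returns the two paths.
write_toy_files <- function(dir = tempfile()) {
  dir.create(dir)
  fp <- file.path(dir, "features.csv")
  lp <- file.path(dir, "labels.csv")
  writeLines(c("sample_id,glutamate,alanine",
               "s1,1.5,0.25",
               "s2,2.25,0.5",
               "s3,0.75,1.125"), fp)
  writeLines(c("sample_id,event,duration_days,malignancy,patient_id",
               "s2,0,120,1,p2",
               "s1,1,30.5,1,p1",
               "s3,1,400,0,p3"), lp)
  list(features = fp, labels = lp)
}
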