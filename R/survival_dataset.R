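#' Survival dataset of metabolite concentrations with outcome labels
#'
#' Bundles an N x P feature matrix of metabolite concentrations with
#' per-sample survival labels: the event indicator (1 = deceased,
#' 0 = censored), the time to event or last follow-up in days, an optional
#' binary malignancy label (1 = aggressive, 0 = benign) and patient
#' identifiers used for patient-disjoint cross-validation splits.
#'
#' @param features numeric matrix (N x P) with column names = metabolite names.
#' @param events binary vector of length N; 1 = deceased, 0 = censored.
#' @param durations nonnegative numeric vector of length N (days).
#' @param malignancy optional binary vector of length N; 1 = aggressive.
#' @param patient_ids optional identifiers (default: the sample ids); samples
#'   with the same patient id are never split across folds.
#' @param sample_ids optional sample identifiers (default: rownames of
#'   `features`, or "S1"..."SN").
#' @return object of class `survival_dataset`.
#' @export
survival_dataset <- function(features, events, durations, malignancy = NULL,
                             patient_ids = NULL, sample_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (is.null(colnames(features))) {
    stop("features must have metabolite names as column names")
  }
  if (anyDuplicated(colnames(features))) stop("metabolite names must be unique")
  if (!all(is.finite(features))) stop("features must be finite")
  events <- as.numeric(events)
  durations <- as.numeric(durations)
  if (length(events) != n || length(durations) != n) {
    stop("events and durations must have length N = nrow(features)")
  }
  if (!is_binary01(events)) stop("events must be 0 (censored) or 1 (deceased)")
  if (any(!is.finite(durations)) || any(durations < 0)) {
    bad <- which(!is.finite(durations) | durations < 0)
    stop("negative or non-finite duration for sample(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(malignancy)) {
    malignancy <- as.numeric(malignancy)
    if (length(malignancy) != n) stop("malignancy must have length N")
    if (!is_binary01(malignancy)) stop("malignancy must be 0 or 1")
  }
  sample_ids <- as.character(sample_ids %||% rownames(features) %||%
                               paste0("S", seq_len(n)))
  if (length(sample_ids) != n) stop("sample_ids must have length N")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  patient_ids <- as.character(patient_ids %||% sample_ids)
  if (length(patient_ids) != n) stop("patient_ids must have length N")
  rownames(features) <- sample_ids
  structure(
    list(features = features,
         metabolite_names = colnames(features),
         events = events,
         durations = durations,
         malignancy = malignancy,
         patient_ids = patient_ids,
         sample_ids = sample_ids),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d samples x %d metabolites | %d events (%.1f%%), %d censored\n",
    nrow(x$features), ncol(x$features), sum(x$events),
    100 * mean(x$events), sum(x$events == 0)))
  if (!is.null(x$malignancy)) {
    cat(sprintf("  malignancy: %d aggressive / %d benign\n",
                sum(x$malignancy), sum(x$malignancy == 0)))
  }
  invisible(x)
}

#' Number of samples
#' @param ds a [survival_dataset()].
#' @export
n_samples <- function(ds) length(ds$sample_ids)

#' Subset a survival dataset by sample index
#' @param ds a [survival_dataset()].
#' @param idx integer or logical index over samples.
#' @return a [survival_dataset()] with the selected samples, in order.
#' @export
subset_dataset <- function(ds, idx) {
  survival_dataset(ds$features[idx, , drop = FALSE],
                   ds$events[idx], ds$durations[idx],
                   malignancy = if (!is.null(ds$malignancy)) ds$malignancy[idx],
                   patient_ids = ds$patient_ids[idx],
                   sample_ids = ds$sample_ids[idx])
}

#' Read a dataset from delimited feature and label files
#'
#' Both files are delimited text (comma or tab, auto-detected) with a header
#' row and the sample id in the first column. The features file has one
#' column per metabolite. The labels file must contain columns `sample_id`,
#' `event` and `duration_days`, and may contain `malignancy` and
#' `patient_id`. The two files are joined by sample id (not by row order);
#' the feature file's row order is preserved in the result.
#'
#' @param features_path path to the features file.
#' @param labels_path path to the labels file.
#' @return a [survival_dataset()].
#' @export
read_dataset <- function(features_path, labels_path) {
  for (p in c(features_path, labels_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  feat <- utils::read.table(features_path, sep = detect_delim(features_path),
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  lab <- utils::read.table(labels_path, sep = detect_delim(labels_path),
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(feat) < 2L) stop("features file needs an id column plus metabolites")
  ids <- as.character(feat[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in features: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  need <- c("sample_id", "event", "duration_days")
  miss <- setdiff(need, names(lab))
  if (length(miss) > 0L) {
    stop("labels file lacks column(s): ", paste(miss, collapse = ", "))
  }
  lab_ids <- as.character(lab$sample_id)
  if (anyDuplicated(lab_ids)) {
    stop("duplicate sample id in labels: ",
         paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
  }
  missing_ids <- setdiff(ids, lab_ids)
  if (length(missing_ids) > 0L) {
    stop("sample id(s) missing from labels: ",
         paste(missing_ids, collapse = ", "))
  }
  m <- match(ids, lab_ids)
  X <- as.matrix(feat[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  survival_dataset(
    X, lab$event[m], lab$duration_days[m],
    malignancy = if ("malignancy" %in% names(lab)) lab$malignancy[m],
    patient_ids = if ("patient_id" %in% names(lab)) {
      as.character(lab$patient_id[m])
    },
    sample_ids = ids
  )
}

#' Write a dataset to delimited feature and label files
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces doubles exactly.
#'
#' @param ds a [survival_dataset()].
#' @param features_path,labels_path output paths.
#' @param sep field delimiter ("," or "\t").
#' @export
write_dataset <- function(ds, features_path, labels_path, sep = ",") {
  feat <- data.frame(sample_id = ds$sample_ids, ds$features,
                     check.names = FALSE)
  write_delim_full(feat, features_path, sep = sep)
  lab <- data.frame(sample_id = ds$sample_ids,
                    event = ds$events,
                    duration_days = ds$durations,
                    check.names = FALSE)
  if (!is.null(ds$malignancy)) lab$malignancy <- ds$malignancy
  lab$patient_id <- ds$patient_ids
  write_delim_full(lab, labels_path, sep = sep)
  invisible(ds)
}

#' Patient-disjoint repeated k-fold assignments
#'
#' Patients (not samples) are shuffled and dealt into k folds, so samples
#' sharing a patient id always land in the same fold. For each repeat r and
#' test fold i, the validation fold is (i + 1) mod k and the remaining k - 2
#' folds are the training set, giving `repeats * k` (iteration, role)
#' assignments. Folds are drawn uniformly over patients with no event-rate
#' stratification.
#'
#' @param ds a [survival_dataset()].
#' @param k number of folds (>= 2).
#' @param repeats number of repetitions with different shuffles.
#' @param seed integer; repeat r uses seed + r - 1, so the full assignment
#'   list is deterministic given `seed`.
#' @return list of class `fold_assignment` objects, one per (repeat, fold):
#'   each has `repeat_index`, `test_fold`, `iteration`, `seed`, `fold_of`
#'   (fold index per sample, 1..k) and `role` (train/validation/test per
#'   sample).
#' @export
make_folds <- function(ds, k = 5L, repeats = 3L, seed = 1L) {
  stopifnot(inherits(ds, "survival_dataset"))
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2L) stop("k must be >= 2")
  patients <- unique(ds$patient_ids)
  if (length(patients) < k) {
    stop("fewer patients (", length(patients), ") than folds (", k, ")")
  }
  out <- vector("list", repeats * k)
  for (r in seq_len(repeats)) {
    rep_seed <- as.integer(seed) + r - 1L
    shuffled <- with_seed(rep_seed, sample(patients))
    # deal shuffled patients round-robin into k folds
    patient_fold <- ((seq_along(shuffled) - 1L) %% k) + 1L
    fold_of <- patient_fold[match(ds$patient_ids, shuffled)]
    for (i in seq_len(k)) {
      val <- (i %% k) + 1L  # fold (i + 1) mod k, 1-based
      role <- rep("train", n_samples(ds))
      role[fold_of == i] <- "test"
      role[fold_of == val] <- "validation"
      out[[(r - 1L) * k + i]] <- structure(
        list(repeat_index = r, test_fold = i, validation_fold = val,
             iteration = (r - 1L) * k + i, seed = rep_seed,
             fold_of = fold_of, role = role),
        class = "fold_assignment")
    }
  }
  out
}
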