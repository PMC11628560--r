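#' Names of the assembled fragmentomic feature vector
#'
#' Fixed order: profile Spearman correlation (1), new-peak count (1),
#' per-window positive areas (255), negative areas (255), Euclidean
#' distances (255), median fragment size (1), end-base preferences (4),
#' 4-mer motif proportions (256) and the motif diversity score (1) —
#' 1,029 named features.
#'
#' @param n_windows number of genome windows (default 255).
#' @return character vector of feature names.
#' @export
feature_names <- function(n_windows = 255L) {
  wfmt <- function(p) sprintf("%s_%03d", p, seq_len(n_windows))
  c("profile_correlation", "new_peak_count",
    wfmt("pos_area"), wfmt("neg_area"), wfmt("euclid"),
    "median_fragment_size",
    paste0("pref_", c("A", "C", "G", "T")),
    paste0("motif_", all_kmers(4L)),
    "mds")
}

#' Assemble the fragmentomic feature vector of one sample
#'
#' Combines the per-site fragmentation profile, peak calls relative to the
#' reference profile, window areas and distances, median fragment size,
#' end-base preferences, the 256-motif spectrum and the MDS into the fixed
#' 1,029-feature vector consumed by the classifiers. All profile-derived
#' components are computed against the same reference profile.
#'
#' @param profile a `SiteProfile` from [site_profile()].
#' @param endfeat end-feature list from [end_features()].
#' @param reference_profile_z z-scaled reference profile from
#'   [reference_profile()].
#' @param reference_peaks peak set of the reference profile; computed from
#'   `reference_profile_z` when missing.
#' @param n_windows number of windows (default 255).
#' @param min_width,min_distance peak parameters (defaults 5 and 20 bp).
#' @return named numeric vector of length `2 + 3*n_windows + 262`.
#' @export
assemble_features <- function(profile, endfeat, reference_profile_z,
                              reference_peaks = NULL, n_windows = 255L,
                              min_width = 5L, min_distance = 20L) {
  z <- profile$fsd_z
  L <- length(z)
  stopifnot(length(reference_profile_z) == L)
  if (is.null(reference_peaks))
    reference_peaks <- call_peaks(reference_profile_z, min_width = min_width)
  win <- mt_windows(L, n_windows)
  pk <- call_peaks(z, min_width = min_width)
  np <- new_peaks(pk, reference_peaks, L, min_distance = min_distance)
  ar <- window_areas(z, win)
  di <- window_distances(z, reference_profile_z, win)
  v <- c(profile_correlation(z, reference_profile_z),
         np$count,
         ar$pos_area, ar$neg_area, di$euclid_dist,
         profile$median_fragment_size,
         unname(endfeat$preference[c("A", "C", "G", "T")]),
         unname(endfeat$spectrum$proportions),
         endfeat$mds)
  names(v) <- feature_names(n_windows)
  if (anyNA(v)) stop("missing value in assembled feature vector")
  v
}

#' Extract the feature vector of one sample from raw fragments
#'
#' One-stop wrapper: builds the [site_profile()] and [end_features()] of a
#' sample and assembles the full feature vector against a reference
#' profile.
#'
#' @param fs a [FragmentSet].
#' @param ref matching [MtReference].
#' @param reference_profile_z z-scaled reference profile.
#' @param reference_peaks optional precomputed reference peak set.
#' @param gc_track optional precomputed GC track (avoids recomputation
#'   across samples).
#' @param ... passed to [assemble_features()].
#' @return named numeric feature vector.
#' @export
extract_features <- function(fs, ref, reference_profile_z,
                             reference_peaks = NULL, gc_track = NULL, ...) {
  prof <- site_profile(fs, ref, gc_track = gc_track)
  ef <- end_features(fs, ref)
  assemble_features(prof, ef, reference_profile_z,
                    reference_peaks = reference_peaks, ...)
}

#' Feature matrix of a cohort
#'
#' @param cohort list of [FragmentSet]s.
#' @param ref matching [MtReference].
#' @param reference_profile_z z-scaled reference profile.
#' @param ... passed to [extract_features()].
#' @return list with `features` (samples x 1,029 matrix) and `meta`
#'   (data.frame with `sample_id`, `group`, `cancer_type`, `batch`).
#' @export
feature_matrix <- function(cohort, ref, reference_profile_z, ...) {
  gc_track <- gc_fraction_track(ref)
  ref_peaks <- call_peaks(reference_profile_z)
  rows <- lapply(cohort, function(fs)
    extract_features(fs, ref, reference_profile_z,
                     reference_peaks = ref_peaks, gc_track = gc_track, ...))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, function(fs) fs$sample_id, character(1))
  meta <- data.frame(
    sample_id = rownames(X),
    group = vapply(cohort, function(fs) fs$group_label, character(1)),
    cancer_type = vapply(cohort, function(fs) fs$cancer_type, character(1)),
    batch = vapply(cohort, function(fs) fs$batch_id, character(1)),
    stringsAsFactors = FALSE)
  list(features = X, meta = meta)
}

# stratified k-fold assignment, seeded
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a binary cancer-detection model
#'
#' Random forest (500 trees, 6 candidate features per split) separating
#' malignant-tumor (MT) samples from one control group (HC, INF or BT).
#' Out-of-fold MEFI scores are produced by seeded stratified tenfold
#' cross-validation on the training cohort; the returned forest is refit on
#' the full cohort, and the Youden cutoff is fixed on the out-of-fold
#' scores.
#'
#' @param features samples x features matrix (rows named by sample).
#' @param labels character/factor vector: `"MT"` or the control label.
#' @param control_group control label (default `"HC"`).
#' @param seed RNG seed controlling folds and forests.
#' @param ntree,mtry forest parameters (defaults 500 and 6).
#' @param k number of CV folds (default 10).
#' @return object of class `DetectionModel`: list with `forest`,
#'   `control_group`, `cv_scores` (out-of-fold MEFI score per sample),
#'   `cv_eval` (an `EvalReport`), `youden_cutoff`, `fold`, `seed`.
#' @export
train_detection <- function(features, labels, control_group = "HC",
                            seed = 1L, ntree = 500L, mtry = 6L, k = 10L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (!all(labels %in% c("MT", control_group)))
    stop("labels must be 'MT' or '", control_group, "'")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  y <- factor(labels, levels = c(control_group, "MT"))
  fold <- stratified_folds(labels, k, seed)
  cv_scores <- numeric(length(labels))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    set.seed(seed + f)
    rf <- randomForest::randomForest(features[!test, , drop = FALSE],
                                     y[!test], ntree = ntree, mtry = mtry)
    cv_scores[test] <- predict(rf, features[test, , drop = FALSE],
                               type = "prob")[, "MT"]
  }
  set.seed(seed)
  forest <- randomForest::randomForest(features, y, ntree = ntree,
                                       mtry = mtry)
  cv_eval <- evaluate(cv_scores, labels, positive = "MT")
  structure(list(forest = forest, control_group = control_group,
                 cv_scores = cv_scores, cv_eval = cv_eval,
                 youden_cutoff = cv_eval$cutoff, fold = fold, seed = seed,
                 ntree = ntree, mtry = mtry),
            class = "DetectionModel")
}

#' @export
print.DetectionModel <- function(x, ...) {
  cat("DetectionModel (MT vs ", x$control_group, "): ", x$ntree,
      " trees, mtry ", x$mtry, "\n  training CV AUC ",
      round(x$cv_eval$auc, 4), ", Youden cutoff ",
      round(x$youden_cutoff, 4), "\n", sep = "")
  invisible(x)
}

#' MEFI score of samples under a detection model
#'
#' The malignancy probability assigned by the trained forest (the MEFI
#' score); classification uses the model's Youden cutoff.
#'
#' @param model a `DetectionModel`.
#' @param features samples x features matrix with the training feature
#'   names.
#' @return numeric vector of scores in [0, 1].
#' @export
mefi_score <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  miss <- setdiff(rownames(model$forest$importance), colnames(features))
  if (length(miss)) stop("features lack model columns, e.g. ", miss[1L])
  predict(model$forest, features, type = "prob")[, "MT"]
}

# empirical AUC by the rank (Mann-Whitney) formula, ties by average rank
auc_rank <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# candidate cutoffs: midpoints between consecutive unique scores + extremes
youden_cutoff <- function(scores, is_pos) {
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cand, function(c) mean(scores[is_pos] > c), numeric(1))
  spec <- vapply(cand, function(c) mean(scores[!is_pos] <= c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]   # ties toward higher specificity
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Evaluate classification scores against labels
#'
#' Empirical ROC AUC (rank/Mann-Whitney form) with a DeLong 95% CI,
#' the Youden-index cutoff (ties broken toward higher specificity),
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` at the cutoff
#' with Clopper-Pearson 95% CIs, and the 2x2 confusion matrix.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels.
#' @param positive label of the positive class (default `"MT"`).
#' @param cutoff `"youden"` (default) or a numeric cutoff; classification
#'   is positive when `score > cutoff`.
#' @return object of class `EvalReport`: list with `auc`, `auc_ci`,
#'   `cutoff`, `sensitivity`, `sensitivity_ci`, `specificity`,
#'   `specificity_ci`, `confusion` (2x2 table, rows = truth), `n_pos`,
#'   `n_neg`.
#' @export
evaluate <- function(scores, labels, positive = "MT", cutoff = "youden") {
  labels <- as.character(labels)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  auc <- auc_rank(scores, is_pos)
  auc_ci <- tryCatch(suppressWarnings({
    r <- pROC::roc(response = is_pos, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1L, 3L)]
  }), error = function(e) c(NA_real_, NA_real_))
  if (identical(cutoff, "youden")) {
    yc <- youden_cutoff(scores, is_pos)
    cut <- yc$cutoff
  } else {
    cut <- as.numeric(cutoff)
  }
  pred_pos <- scores > cut
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  ci <- function(x, n) if (n > 0)
    as.numeric(stats::binom.test(x, n)$conf.int) else c(NA_real_, NA_real_)
  conf <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                 dimnames = list(truth = c("negative", "positive"),
                                 predicted = c("negative", "positive")))
  structure(list(auc = auc, auc_ci = auc_ci, cutoff = cut,
                 sensitivity = sens, sensitivity_ci = ci(tp, tp + fn),
                 specificity = spec, specificity_ci = ci(tn, tn + fp),
                 confusion = conf, n_pos = sum(is_pos),
                 n_neg = sum(!is_pos)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "EvalReport: AUC %.4f (95%% CI %.4f-%.4f), cutoff %.4f\n  sensitivity %.4f (%.4f-%.4f), specificity %.4f (%.4f-%.4f)\n",
    x$auc, x$auc_ci[1L], x$auc_ci[2L], x$cutoff, x$sensitivity,
    x$sensitivity_ci[1L], x$sensitivity_ci[2L], x$specificity,
    x$specificity_ci[1L], x$specificity_ci[2L]))
  invisible(x)
}

#' High-specificity gate for tissue-of-origin modelling
#'
#' Sets the smallest score threshold achieving at least the target
#' specificity (default 99.5%) on the control scores — the
#' `ceiling(target * n)`-th order statistic — and selects the MT-labelled
#' samples scoring strictly above it.
#'
#' @param scores numeric scores of all samples.
#' @param labels class labels.
#' @param control_group control label (default `"HC"`).
#' @param target_specificity default 0.995.
#' @return list with `threshold`, `selected` (logical: MT samples above
#'   the threshold), `n_controls_above`.
#' @export
too_gate <- function(scores, labels, control_group = "HC",
                     target_specificity = 0.995) {
  labels <- as.character(labels)
  ctrl <- sort(scores[labels == control_group])
  if (!length(ctrl)) stop("no control scores to set the threshold")
  if (target_specificity <= 0 || target_specificity > 1)
    stop("target_specificity must be in (0, 1]")
  kth <- ceiling(target_specificity * length(ctrl))
  thr <- ctrl[kth]
  selected <- labels == "MT" & scores > thr
  list(threshold = thr, selected = selected,
       n_controls_above = sum(scores[labels == control_group] > thr))
}

#' Train the tissue-of-origin classifier
#'
#' Multiclass random forest over the same fragmentomic features and forest
#' parameters as the detection models, trained on the gated MT samples'
#' cancer-type labels.
#'
#' @param features gated MT samples x features matrix.
#' @param types cancer-type labels.
#' @param seed RNG seed.
#' @param ntree,mtry forest parameters (defaults 500 and 6).
#' @return object of class `TooModel`.
#' @export
train_too <- function(features, types, seed = 1L, ntree = 500L, mtry = 6L) {
  types <- as.character(types)
  tab <- table(types)
  if (length(tab) < 2L) stop("need at least 2 cancer types")
  if (any(tab < 2L))
    stop("cancer type with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  y <- factor(types)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  forest <- randomForest::randomForest(features, y, ntree = ntree,
                                       mtry = mtry)
  structure(list(forest = forest, classes = levels(y), seed = seed,
                 ntree = ntree, mtry = mtry),
            class = "TooModel")
}

#' Predict tissue of origin
#'
#' Class probabilities, top-1 and top-2 predictions, and — when true
#' labels are supplied — top-1/top-2 accuracy and the confusion matrix
#' (rows = true class).
#'
#' @param model a `TooModel`.
#' @param features samples x features matrix.
#' @param types optional true cancer-type labels.
#' @return list with `prob` (samples x classes), `top1`, `top2` (two-column
#'   matrix), and, given `types`, `top1_accuracy`, `top2_accuracy`,
#'   `confusion`.
#' @export
predict_too <- function(model, features, types = NULL) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  prob <- predict(model$forest, features, type = "prob")
  ord <- t(apply(prob, 1L, order, decreasing = TRUE))
  top1 <- colnames(prob)[ord[, 1L]]
  top2 <- cbind(top1, colnames(prob)[ord[, 2L]])
  colnames(top2) <- c("first", "second")
  out <- list(prob = prob, top1 = top1, top2 = top2)
  if (!is.null(types)) {
    types <- as.character(types)
    out$top1_accuracy <- mean(top1 == types)
    out$top2_accuracy <- mean(types == top2[, 1L] | types == top2[, 2L])
    out$confusion <- table(truth = factor(types, levels = colnames(prob)),
                           predicted = factor(top1, levels = colnames(prob)))
  }
  out
}

#' Leave-one-batch-out evaluation
#'
#' For each batch, trains a detection model on all other batches and
#' evaluates it on the held-out batch; batches containing one class only
#' yield scores but no AUC (with a warning). Also reports the pooled AUC
#' over all out-of-batch scores.
#'
#' @param features samples x features matrix.
#' @param labels class labels (`"MT"` or control).
#' @param batch_ids batch identifier per sample (at least 2 batches).
#' @param control_group control label (default `"HC"`).
#' @param seed,ntree,mtry forest parameters.
#' @return list with `per_batch` (named list of `EvalReport` or score
#'   vectors), `pooled` (`EvalReport` over all held-out scores), `scores`.
#' @export
leave_one_batch_out <- function(features, labels, batch_ids,
                                control_group = "HC", seed = 1L,
                                ntree = 500L, mtry = 6L) {
  labels <- as.character(labels)
  batch_ids <- as.character(batch_ids)
  batches <- unique(batch_ids)
  if (length(batches) < 2L) stop("need at least 2 batches")
  y <- factor(labels, levels = c(control_group, "MT"))
  scores <- rep(NA_real_, length(labels))
  per_batch <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (b in batches) {
    test <- batch_ids == b
    if (length(unique(labels[!test])) < 2L) {
      warning("training set for batch ", b,
              " contains one class only; batch skipped")
      per_batch[[b]] <- list(scores = NULL)
      next
    }
    set.seed(seed)
    rf <- randomForest::randomForest(features[!test, , drop = FALSE],
                                     y[!test], ntree = ntree, mtry = mtry)
    sc <- predict(rf, features[test, , drop = FALSE], type = "prob")[, "MT"]
    scores[test] <- sc
    if (length(unique(labels[test])) < 2L) {
      warning("batch ", b, " contains one class only; AUC skipped")
      per_batch[[b]] <- list(scores = sc)
    } else {
      per_batch[[b]] <- evaluate(sc, labels[test])
    }
  }
  ok <- !is.na(scores)
  if (length(unique(labels[ok])) < 2L)
    stop("no held-out scores with both classes; cannot pool")
  list(per_batch = per_batch, pooled = evaluate(scores[ok], labels[ok]),
       scores = scores)
}
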