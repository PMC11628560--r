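# planted-signal feature matrix: cheap stand-in for full extraction when
# testing the modelling machinery itself
planted_features <- function(n_per_class, shift = 2, seed = 1,
                             classes = c("HC", "MT")) {
  set.seed(seed)
  labs <- rep(classes, n_per_class)
  X <- matrix(rnorm(length(labs) * 40), length(labs), 40,
              dimnames = list(NULL, paste0("f", 1:40)))
  for (k in seq_along(classes))
    X[labs == classes[k], 1:5] <- X[labs == classes[k], 1:5] +
      shift * (k - 1)
  rownames(X) <- paste0("s", seq_along(labs))
  list(X = X, labels = labs)
}

test_that("the assembled feature vector has the documented layout", {
  nm <- feature_names()
  expect_length(nm, 1029L)
  expect_equal(nm[1:2], c("profile_correlation", "new_peak_count"))
  expect_equal(sum(startsWith(nm, "pos_area_")), 255L)
  expect_equal(sum(startsWith(nm, "motif_")), 256L)
  expect_equal(nm[1029], "mds")
})

test_that("a sample identical to the reference profile is null", {
  ref <- toy_reference(2000, seed = 10)
  set.seed(30)
  fs <- FragmentSet(sample.int(2000L, 3000L, replace = TRUE),
                    pmax(20L, round(rnorm(3000, 100, 25))), L = 2000L)
  prof <- site_profile(fs, ref)
  ef <- end_features(fs, ref)
  rz <- prof$fsd_z
  v <- assemble_features(prof, ef, rz, n_windows = 20L)
  expect_length(v, 2L + 3L * 20L + 262L)
  expect_equal(unname(v["profile_correlation"]), 1)
  expect_equal(unname(v["new_peak_count"]), 0)
  expect_true(all(v[startsWith(names(v), "euclid_")] == 0))
  # determinism: identical inputs give identical vectors
  v2 <- assemble_features(prof, ef, rz, n_windows = 20L)
  expect_identical(v, v2)
  expect_error(assemble_features(prof, ef, rz[-1], n_windows = 20L))
})

test_that("empirical AUC matches the brute-force pairwise oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 1)          # induce ties
    lab <- sample(c("MT", "HC"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(evaluate(sc, lab)$auc, oracle_auc(sc, lab == "MT"))
  }
  expect_equal(evaluate(rep(0.5, 10), rep(c("MT", "HC"), 5))$auc, 0.5)
})

test_that("evaluation report has coherent cutoff and error rates", {
  ev <- evaluate(c(0.1, 0.2, 0.8, 0.9), c("HC", "HC", "MT", "MT"))
  expect_equal(ev$auc, 1)
  expect_gt(ev$cutoff, 0.2); expect_lt(ev$cutoff, 0.8)
  expect_equal(ev$sensitivity, 1); expect_equal(ev$specificity, 1)
  expect_equal(sum(ev$confusion), 4)
  expect_equal(unname(diag(ev$confusion)), c(2, 2))
  expect_true(ev$sensitivity_ci[1] < 1 && ev$auc_ci[2] <= 1)
  # raising the cutoff never increases sensitivity
  set.seed(32)
  sc <- runif(50); lab <- sample(c("MT", "HC"), 50, replace = TRUE)
  sens <- vapply(seq(0, 1, 0.05), function(ct)
    evaluate(sc, lab, cutoff = ct)$sensitivity, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
  expect_error(evaluate(sc, rep("MT", 50)), "both classes")
})

test_that("detection training is seeded, stratified and scored out of fold", {
  pf <- planted_features(c(30, 30), shift = 2, seed = 3)
  m1 <- train_detection(pf$X, pf$labels, seed = 4, ntree = 100L, mtry = 3L)
  m2 <- train_detection(pf$X, pf$labels, seed = 4, ntree = 100L, mtry = 3L)
  expect_identical(m1$cv_scores, m2$cv_scores)
  expect_identical(predict(m1$forest, pf$X, type = "prob"),
                   predict(m2$forest, pf$X, type = "prob"))
  expect_gt(m1$cv_eval$auc, 0.9)
  expect_true(all(m1$cv_scores >= 0 & m1$cv_scores <= 1))
  # every fold contains both classes
  expect_true(all(table(m1$fold, pf$labels) > 0))
  sc <- mefi_score(m1, pf$X)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(train_detection(pf$X, rep("MT", 60)), "both classes")
  expect_error(mefi_score(m1, pf$X[, 1:10]), "lack")
})

test_that("the specificity gate is an order statistic on control scores", {
  set.seed(33)
  sc <- c(runif(200), runif(40, 0.8, 1))
  lab <- c(rep("HC", 200), rep("MT", 40))
  g <- too_gate(sc, lab, target_specificity = 0.995)
  expect_lte(g$n_controls_above, 1L)     # ceiling(0.995 * 200) = 199th
  expect_equal(g$threshold, sort(sc[lab == "HC"])[199])
  g1 <- too_gate(sc, lab, target_specificity = 1)
  expect_equal(g1$n_controls_above, 0L)
  # perfect separation selects every case
  g2 <- too_gate(c(rep(0, 10), rep(1, 5)),
                 c(rep("HC", 10), rep("MT", 5)))
  expect_equal(sum(g2$selected), 5L)
})

test_that("tissue-of-origin predictions nest top-1 within top-2", {
  pf <- planted_features(c(15, 15, 15), shift = 1.5, seed = 5,
                         classes = c("HCC", "CRC", "NSCLC"))
  m <- train_too(pf$X, pf$labels, seed = 6, ntree = 100L, mtry = 3L)
  pr <- predict_too(m, pf$X, pf$labels)
  expect_gte(pr$top2_accuracy, pr$top1_accuracy)
  expect_equal(sum(diag(pr$confusion)) / sum(pr$confusion),
               pr$top1_accuracy)
  expect_equal(rownames(pr$confusion), colnames(pr$prob))
  expect_error(train_too(pf$X, rep("HCC", 45)), "2 cancer types")
  expect_error(train_too(pf$X[1:16, ], c(rep("HCC", 15), "CRC")),
               "fewer than 2")
})

test_that("leave-one-batch-out evaluates held-out batches", {
  pf <- planted_features(c(40, 40), shift = 2, seed = 7)
  batches <- rep(c("b1", "b2"), 40)
  lob <- leave_one_batch_out(pf$X, pf$labels, batches, seed = 8,
                             ntree = 100L, mtry = 3L)
  expect_gt(lob$pooled$auc, 0.85)
  expect_gt(lob$per_batch$b1$auc, 0.8)
  expect_lt(abs(lob$per_batch$b1$auc - lob$per_batch$b2$auc), 0.15)
  expect_error(leave_one_batch_out(pf$X, pf$labels, rep("b1", 80)),
               "2 batches")
  # label-confounded batches leave no trainable split at all
  conf <- ifelse(pf$labels == "MT", "bm", "bh")
  expect_error(
    suppressWarnings(leave_one_batch_out(pf$X, pf$labels, conf, seed = 8,
                                         ntree = 50L, mtry = 3L)),
    "cannot pool")
  # a held-out batch with one class yields scores but no AUC
  mixed <- c(rep("b1", 30), rep("b2", 30), rep("b3", 20))
  lob3 <- suppressWarnings(
    leave_one_batch_out(pf$X[1:80, ], pf$labels[1:80], mixed, seed = 8,
                        ntree = 50L, mtry = 3L))
  expect_null(lob3$per_batch$b3$auc)
  expect_length(lob3$per_batch$b3$scores, 20L)
})
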