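test_that("six-to-five stage merge follows the published rule", {
  expect_identical(merge_six_to_five(1:6), c(1L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(merge_six_to_five(c(2, 2, 3)), c(1L, 1L, 2L))
  expect_error(merge_six_to_five(0), "1..6")
  expect_error(merge_six_to_five(7), "1..6")
  # merged class 1 pools the CS1 and CS2 counts
  labs <- rep(1:6, published_class_profile())
  merged <- merge_six_to_five(labs)
  expect_equal(sum(merged == 1), 154 + 187)
  expect_equal(as.vector(table(merged)),
               c(154 + 187, 174, 159, 167, 177))
})

test_that("stratified folds partition, balance, and reproduce under a seed", {
  # a 761-image manifest (the published training-set size), 6 classes
  counts <- c(115, 140, 130, 119, 125, 132)
  stopifnot(sum(counts) == 761)
  manifest <- tibble::tibble(
    source_id = sprintf("im%03d", 1:761),
    label = rep(1:6, counts)
  )
  plan <- make_folds(manifest, k = 5, seed = 7)
  sizes <- as.vector(table(plan$fold))
  expect_identical(sort(sizes, decreasing = TRUE), c(153L, 152L, 152L, 152L, 152L))
  # partition: every id exactly once
  expect_identical(sort(plan$source_id), sort(manifest$source_id))
  # stratification: per-fold class counts within 1 of n_c / k
  for (cl in 1:6) {
    per <- table(factor(plan$fold[plan$label == cl], 1:5))
    expect_lte(max(per) - min(per), 1)
    expect_lte(max(abs(per - counts[cl] / 5)), 1)
  }
  # same seed, same plan; different seed, different plan
  expect_identical(make_folds(manifest, k = 5, seed = 7), plan)
  expect_false(identical(make_folds(manifest, k = 5, seed = 8)$fold, plan$fold))
  # class smaller than k is refused
  tiny <- tibble::tibble(source_id = letters[1:7], label = c(1, 1, 1, 1, 2, 2, 2))
  expect_error(make_folds(tiny, k = 4), "at least k")
})

test_that("fold_split augments only the training side", {
  set.seed(2)
  data <- tibble::tibble(
    source_id = sprintf("s%02d", 1:30),
    label = rep(1:6, each = 5),
    pixels = replicate(30, matrix(runif(77 * 35), 77, 35), simplify = FALSE)
  )
  plan <- make_folds(data, k = 5, seed = 3)
  sp <- fold_split(data, plan, fold = 2)
  expect_equal(nrow(sp$validation), 6)
  expect_equal(nrow(sp$train), 24 * 11)
  expect_false(any(sp$train$parent_id %in% sp$validation$source_id))
  expect_false("is_augmented" %in% names(sp$validation))
  expect_no_error(assert_not_augmented(sp$validation))
  expect_error(assert_not_augmented(sp$train), "augmented")
  # no augmentation on request
  expect_equal(nrow(fold_split(data, plan, 2, augment = FALSE)$train), 24)
})

test_that("evaluation metrics match hand computation and printed arithmetic", {
  # F1 from the published class-I precision/recall
  expect_equal(round(f1_score(0.899, 0.913), 3), 0.906)
  # a small fully hand-checkable case
  truth <- c(1, 1, 2, 2, 3, 3)
  prob <- rbind(
    c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2),  # class 1 correct twice
    c(0.6, 0.3, 0.1), c(0.1, 0.8, 0.1),  # class 2: one miss to class 1
    c(0.1, 0.1, 0.8), c(0.2, 0.5, 0.3)   # class 3: one miss to class 2
  )
  rep <- evaluate_predictions(truth, prob)
  expect_equal(rep$confusion,
               matrix(c(2, 0, 0, 1, 1, 0, 0, 1, 1), 3, byrow = TRUE,
                      dimnames = dimnames(rep$confusion)))
  expect_equal(rep$accuracy, 4 / 6)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion),
               tolerance = 1e-12)
  expect_equal(rep$per_class$precision, c(2 / 3, 1 / 2, 1))
  expect_equal(rep$per_class$recall, c(1, 1 / 2, 1 / 2))
  # argmax ties break toward the lower class index
  tie <- evaluate_predictions(2, matrix(c(0.4, 0.4, 0.2), 1))
  expect_equal(tie$confusion["2", "1"], 1)
  # perfect classifier: identity confusion, accuracy 1, AUC all 1
  perfect <- evaluate_predictions(1:3, diag(3))
  expect_equal(perfect$confusion, diag(3), ignore_attr = TRUE)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$auc), rep(1, 3))
  expect_error(evaluate_predictions(c(1, 4), matrix(0.5, 2, 3)), "out of range")
})

test_that("hand-built one-vs-rest ROC/AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(99)
  n <- 120
  truth <- sample(1:3, n, replace = TRUE)
  raw <- matrix(runif(3 * n), n, 3) + 0.5 * diag(3)[truth, ]  # informative
  prob <- raw / rowSums(raw)
  rep <- evaluate_predictions(truth, prob)
  for (cl in 1:3) {
    ref <- suppressMessages(
      pROC::auc(pROC::roc(response = as.integer(truth == cl),
                          predictor = prob[, cl], direction = "<"))
    )
    expect_equal(unname(rep$auc[cl]), as.numeric(ref), tolerance = 1e-10)
  }
  # broom-style accessors
  td <- tidy(rep)
  expect_true(all(c("class", "precision", "recall", "f1", "auc") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$accuracy, rep$accuracy)
})

test_that("random scores give chance-level AUC under the ROC implementation", {
  set.seed(123)
  n <- 1000
  truth <- sample(1:2, n, replace = TRUE)
  prob <- matrix(runif(2 * n), n, 2)
  prob <- prob / rowSums(prob)
  rep <- evaluate_predictions(truth, prob)
  expect_lt(max(abs(rep$auc - 0.5)), 0.05)
})

test_that("report averaging is elementwise and linear", {
  r1 <- evaluate_predictions(c(1, 1, 2, 2), diag(2)[c(1, 1, 2, 2), ])
  r2 <- evaluate_predictions(c(1, 1, 2, 2), diag(2)[c(2, 2, 1, 1), ])
  avg <- average_reports(list(r1, r2))
  expect_equal(avg$confusion, matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(avg$accuracy, 0.5)
  # k identical reports average to themselves
  same <- average_reports(list(r1, r1, r1))
  expect_equal(same$confusion, r1$confusion)
  expect_equal(same$accuracy, r1$accuracy)
  expect_equal(same$auc, r1$auc)
  # averaged row sums equal the mean of input row sums
  expect_equal(rowSums(avg$confusion),
               (rowSums(r1$confusion) + rowSums(r2$confusion)) / 2)
  r3 <- evaluate_predictions(1:3, diag(3))
  expect_error(average_reports(list(r1, r3)), "different class sets")
})

test_that("subset significance reports brute-force moments and sane p-values", {
  # oracle comparison on arbitrary numbers
  a <- c(0.70, 0.75, 0.72, 0.80, 0.71, 0.77, 0.74)
  b <- c(0.78, 0.82, 0.79, 0.85, 0.80, 0.83, 0.81)
  res <- subset_significance(a, b)
  expect_equal(res$mean_without, sum(a) / length(a))
  expect_equal(res$sd_without, sqrt(sum((a - mean(a))^2) / (length(a) - 1)))
  expect_equal(res$mean_with, sum(b) / length(b))
  expect_equal(res$sd_with, sqrt(sum((b - mean(b))^2) / (length(b) - 1)))
  expect_equal(res$p_value,
               t.test(b, a, alternative = "greater")$p.value)
  expect_lt(res$p_value, 0.01)
  # identical lists: p = 0.5 under the one-sided convention
  expect_equal(subset_significance(a, a)$p_value,
               t.test(a, a, alternative = "greater")$p.value)
  expect_equal(subset_significance(rep(0.8, 7), rep(0.8, 7))$p_value, 0.5)
  # extreme separation with zero variance
  expect_lt(subset_significance(rep(0, 7), rep(1, 7))$p_value, 1e-6)
  # the published subset summary: reproduce the stats, report the p-value
  expect_error(subset_significance(a, b[1:3]))
  # normal-overlap mode
  res2 <- subset_significance(a, b, method = "normal_overlap")
  expect_equal(res2$p_value, pnorm(mean(b), mean(a), sd(a), lower.tail = FALSE))
})

test_that("density-preserving subsets mirror the class distribution", {
  labels <- rep(1:6, published_class_profile())[1:280]
  labels <- sample(rep(1:6, c(50, 55, 45, 40, 45, 45)))
  subs <- density_subsets(labels, n_subsets = 7, subset_size = 30, seed = 4)
  expect_length(subs, 7)
  expect_true(all(lengths(subs) == 30))
  # disjoint
  expect_equal(anyDuplicated(unlist(subs)), 0)
  # each subset's class histogram is within 1 of the scaled global histogram
  glob <- table(labels) / length(labels) * 30
  for (s in subs) {
    expect_lte(max(abs(table(factor(labels[s], 1:6)) - glob)), 1.5)
  }
  expect_error(density_subsets(labels, 7, 50), "not enough")
})
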