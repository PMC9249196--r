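#' Merge the six-stage labels into the five-stage scheme
#'
#' CS1 and CS2 merge into CVMS I; every later stage shifts down by one
#' (CS3 -> CVMS II, ..., CS6 -> CVMS V).
#'
#' @param label integer vector of stages in 1..6.
#' @return Integer vector of merged stages in 1..5.
#' @export
#' @examples
#' merge_six_to_five(1:6)  # 1 1 2 3 4 5
merge_six_to_five <- function(label) {
  if (!is.numeric(label) || any(is.na(label)) || any(!label %in% 1:6)) {
    stop("labels must be integers in 1..6")
  }
  c(1L, 1L, 2L, 3L, 4L, 5L)[as.integer(label)]
}

#' Stratified k-fold plan over non-augmented source images
#'
#' Partitions the source images into `k` folds, stratified by class with
#' largest-remainder allocation: each fold receives `floor(n_c / k)` images of
#' class `c`, and the remainders go to the currently least-loaded folds, so
#' per-fold class counts differ by at most one image from exact proportion
#' and overall fold sizes differ by at most one. Augmented images are
#' refused: the protocol splits *before* augmentation, and augmentation is
#' applied afterwards to the training portion only (see [fold_split()]).
#'
#' @param manifest tibble with `source_id` and `label` (and optionally
#'   `is_augmented`, which must be all `FALSE`).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return A `fold_plan`: tibble `source_id`, `label`, `fold` with attributes
#'   `k` and `seed`.
#' @export
make_folds <- function(manifest, k = 5, seed = 1) {
  stopifnot(all(c("source_id", "label") %in% names(manifest)), k >= 2)
  if ("is_augmented" %in% names(manifest) && any(manifest$is_augmented)) {
    stop("make_folds() must be given non-augmented source images only")
  }
  if (anyDuplicated(manifest$source_id)) stop("duplicate source_id")
  tab <- table(manifest$label)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " members; class ",
         names(tab)[which.min(tab)], " has ", min(tab))
  }
  set.seed(seed)
  fold <- integer(nrow(manifest))
  load <- integer(k)
  for (cl in sort(unique(manifest$label))) {
    idx <- sample(which(manifest$label == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    extra <- n_c %% k
    per_fold <- rep(base, k)
    if (extra > 0) {
      recipients <- order(load, seq_len(k))[seq_len(extra)]
      per_fold[recipients] <- per_fold[recipients] + 1L
    }
    fold[idx] <- rep(seq_len(k), per_fold)
    load <- load + per_fold
  }
  structure(
    tibble::tibble(source_id = manifest$source_id, label = manifest$label,
                   fold = fold),
    k = k, seed = seed, class = c("fold_plan", class(tibble::tibble()))
  )
}

#' Split one fold into training and validation sets, augmenting the training
#' portion only
#'
#' Implements the split-before-augmentation protocol: the validation set is
#' the held-out fold, untouched; the remaining k-1 folds form the training
#' set, optionally expanded elevenfold by [augment_dataset()]. No augmented
#' image can ever appear in the validation set by construction.
#'
#' @param data tibble with `source_id`, `label`, `pixels`.
#' @param plan a `fold_plan` from [make_folds()].
#' @param fold which fold to hold out.
#' @param augment whether to augment the training portion.
#' @return `list(train = tibble, validation = tibble)`.
#' @export
fold_split <- function(data, plan, fold, augment = TRUE) {
  stopifnot(inherits(plan, "fold_plan"), fold %in% plan$fold)
  val_ids <- plan$source_id[plan$fold == fold]
  train <- data[!data$source_id %in% val_ids, , drop = FALSE]
  validation <- data[data$source_id %in% val_ids, , drop = FALSE]
  if (augment) train <- augment_dataset(train)
  list(train = train, validation = validation)
}

#' Guard: refuse augmented images at scoring time
#'
#' Augmentation is applied after the fold split and only to training data;
#' any row flagged `is_augmented` reaching evaluation indicates test-set
#' contamination and raises an error.
#'
#' @param data tibble, possibly carrying an `is_augmented` column.
#' @return `data`, invisibly, if clean.
#' @export
assert_not_augmented <- function(data) {
  if ("is_augmented" %in% names(data) && any(data$is_augmented)) {
    stop("augmented images must not be scored (split-before-augmentation)")
  }
  invisible(data)
}

roc_curve <- function(score, positive) {
  thr <- sort(unique(c(0, 1, score)), decreasing = TRUE)
  thr <- c(Inf, thr)
  P <- sum(positive)
  N <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(score >= t & positive) / max(P, 1), 0)
  fpr <- vapply(thr, function(t) sum(score >= t & !positive) / max(N, 1), 0)
  tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
}

#' Score class-probability predictions against true labels
#'
#' Builds the confusion matrix from argmax predictions (ties broken toward
#' the lower class index), per-class precision / recall / F1, overall
#' accuracy, and one-vs-rest ROC curves with trapezoidal AUC: for each class,
#' that class is relabeled positive and the union of the others negative, and
#' the class-probability column is thresholded at every observed probability
#' (plus 0 and 1).
#'
#' @param truth integer labels in `1..ncol(prob)`.
#' @param prob matrix of class probabilities, one row per observation.
#' @return An `eval_report`: list with `confusion` (rows = truth), `accuracy`,
#'   `per_class` tibble, `roc` tibble (`class`, `threshold`, `fpr`, `tpr`),
#'   `auc` named vector, `n`.
#' @export
evaluate_predictions <- function(truth, prob) {
  prob <- as.matrix(prob)
  n_classes <- ncol(prob)
  stopifnot(length(truth) == nrow(prob), length(truth) > 0)
  if (any(!truth %in% seq_len(n_classes))) {
    stop("labels out of range for a ", n_classes, "-class problem")
  }
  pred <- apply(prob, 1, which.max)  # which.max takes the lowest index on ties
  lev <- seq_len(n_classes)
  confusion <- table(factor(truth, lev), factor(pred, lev))
  confusion <- matrix(as.numeric(confusion), n_classes, n_classes,
                      dimnames = list(truth = lev, predicted = lev))
  roc <- purrr::map_dfr(lev, function(cl) {
    dplyr::mutate(roc_curve(prob[, cl], truth == cl), class = cl,
                  .before = 1)
  })
  auc <- vapply(lev, function(cl) {
    r <- roc[roc$class == cl, ]
    trapezoid_auc(r$fpr, r$tpr)
  }, 0)
  rep <- eval_report_from_confusion(confusion)
  rep$roc <- roc
  rep$auc <- setNames(auc, lev)
  rep
}

# metrics derivable from a (possibly fractional, averaged) confusion matrix
eval_report_from_confusion <- function(confusion) {
  tp <- unname(diag(confusion))
  fp <- unname(colSums(confusion)) - tp
  fn <- unname(rowSums(confusion)) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- f1_score(precision, recall)
  structure(
    list(
      confusion = confusion,
      accuracy = sum(tp) / sum(confusion),
      per_class = tibble::tibble(
        class = seq_len(nrow(confusion)),
        n = unname(rowSums(confusion)),
        precision = precision, recall = recall, f1 = f1
      ),
      roc = NULL, auc = NULL, n = sum(confusion)
    ),
    class = "eval_report"
  )
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall numeric vectors.
#' @return `2 * precision * recall / (precision + recall)`, `NA` where
#'   undefined.
#' @export
f1_score <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n = ", x$n, ", accuracy = ",
      sprintf("%.4f", x$accuracy), "\n", sep = "")
  cat("confusion (rows = truth):\n")
  print(round(x$confusion, 2))
  print(x$per_class, n = nrow(x$per_class))
  if (!is.null(x$auc)) {
    cat("one-vs-rest AUC:", sprintf("%.3f", x$auc), "\n")
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$auc)) out$auc <- unname(x$auc)
  out
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = x$accuracy,
    macro_f1 = mean(x$per_class$f1, na.rm = TRUE),
    mean_auc = if (is.null(x$auc)) NA_real_ else mean(x$auc)
  )
}

#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report carries no ROC curves")
  auc_lab <- sprintf("class %d (AUC %.3f)", seq_along(object$auc), object$auc)
  df <- dplyr::mutate(object$roc, class = factor(auc_lab[.data$class]))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "One-vs-rest ROC", colour = NULL)
}

#' Average k per-fold evaluation reports
#'
#' Elementwise mean of the confusion matrices (entries become fractional);
#' accuracy and the per-class metrics are recomputed from the averaged
#' matrix; AUCs are averaged across reports. Per-threshold ROC point lists
#' are not averaged and are dropped.
#'
#' @param reports list of `eval_report`s over the same class set.
#' @return An `eval_report`.
#' @export
average_reports <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "eval_report")))
  dims <- vapply(reports, function(r) nrow(r$confusion), 0)
  if (length(unique(dims)) != 1) stop("reports have different class sets")
  mean_conf <- Reduce(`+`, lapply(reports, `[[`, "confusion")) / length(reports)
  out <- eval_report_from_confusion(mean_conf)
  aucs <- lapply(reports, `[[`, "auc")
  if (!any(vapply(aucs, is.null, TRUE))) {
    out$auc <- Reduce(`+`, aucs) / length(aucs)
  }
  out
}

#' Class-density-preserving test subsets
#'
#' Partitions scored images into `n_subsets` disjoint subsets of
#' `subset_size`, allocating per-class quotas by largest remainder so each
#' subset mirrors the overall class density — the apparatus for the
#' subset-based significance procedure.
#'
#' @param labels integer class labels.
#' @param n_subsets number of subsets.
#' @param subset_size images per subset; `n_subsets * subset_size` must not
#'   exceed `length(labels)`.
#' @param seed shuffle seed.
#' @return List of `n_subsets` integer index vectors into `labels`.
#' @export
density_subsets <- function(labels, n_subsets = 7, subset_size = 30, seed = 1) {
  n <- length(labels)
  if (n_subsets * subset_size > n) stop("not enough images for the subsets")
  # largest-remainder class quotas for one subset
  dens <- table(labels) / n
  quota <- floor(dens * subset_size)
  rem <- subset_size - sum(quota)
  if (rem > 0) {
    frac <- dens * subset_size - quota
    bump <- order(-frac)[seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  if (any(n_subsets * quota > table(labels))) {
    stop("not enough images in some class for density-preserving subsets")
  }
  set.seed(seed)
  pool <- lapply(split(seq_len(n), labels), sample)
  purrr::map(seq_len(n_subsets), function(s) {
    unlist(purrr::imap(pool, function(idx, cl) {
      q <- quota[[cl]]
      if (q == 0) integer(0) else idx[((s - 1) * q + 1):(s * q)]
    }), use.names = FALSE)
  })
}

#' Compare per-subset accuracies with and without directional filters
#'
#' Given matched lists of subset accuracies under the null configuration
#' (e.g. random-initialized first layer) and the alternative (directional
#' initialization), reports sample means and standard deviations of both and
#' a one-sided p-value for the alternative "with-filters mean is larger".
#' The default test is Welch's two-sample t-test; `method =
#' "normal_overlap"` instead fits a normal to the null accuracies and
#' reports \eqn{P(N(\mu_0, \sigma_0) \ge \mu_1)}.
#'
#' @param acc_without,acc_with numeric vectors of per-subset accuracies, equal
#'   length at least 2.
#' @param method `"welch"` or `"normal_overlap"`.
#' @return A one-row tibble: `mean_without`, `sd_without`, `mean_with`,
#'   `sd_with`, `p_value`, `method`.
#' @export
subset_significance <- function(acc_without, acc_with,
                                method = c("welch", "normal_overlap")) {
  method <- match.arg(method)
  stopifnot(length(acc_without) == length(acc_with), length(acc_with) >= 2)
  m0 <- mean(acc_without)
  m1 <- mean(acc_with)
  s0 <- sd(acc_without)
  s1 <- sd(acc_with)
  p <- if (method == "normal_overlap") {
    if (s0 == 0) as.numeric(m1 <= m0) else pnorm(m1, m0, s0, lower.tail = FALSE)
  } else if (s0 == 0 && s1 == 0) {
    # degenerate Welch: zero variance on both sides
    if (m1 == m0) 0.5 else as.numeric(m1 < m0)
  } else {
    t.test(acc_with, acc_without, alternative = "greater")$p.value
  }
  tibble::tibble(mean_without = m0, sd_without = s0,
                 mean_with = m1, sd_with = s1,
                 p_value = p, method = method)
}
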