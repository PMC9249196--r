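#' @title Channel-features RoI detection
#'
#' @description
#' A compact sliding-window detector in the aggregate-channel-features
#' tradition: gradient-based image channels are block-aggregated, a boosted
#' ensemble of depth-2 decision trees scores a fixed window at every position
#' of a scale pyramid, and greedy non-maximum suppression keeps the best
#' window. It localizes the C2-C4 vertebral column so the staging network
#' sees only the region of interest. It is a documented simplification of
#' the classical detector (grayscale channels, a single window aspect,
#' shallow trees, a couple of hard-negative-mining rounds) and is pluggable:
#' manifests may carry manual crop columns that take precedence downstream.
#' @name roi_detection
NULL

smooth121 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  v <- (p[1:nr, ] + 2 * p[2:(nr + 1), ] + p[3:(nr + 2), ]) / 4
  (v[, 1:nc] + 2 * v[, 2:(nc + 1)] + v[, 3:(nc + 2)]) / 4
}

block_sum <- function(m, s) {
  gr <- rep(seq_len(ceiling(nrow(m) / s)), each = s)[seq_len(nrow(m))]
  gc <- rep(seq_len(ceiling(ncol(m) / s)), each = s)[seq_len(ncol(m))]
  t(rowsum(t(rowsum(m, gr)), gc))
}

#' Aggregated detection channels of a grayscale image
#'
#' Computes 8 channels: raw intensity, gradient magnitude, and 6
#' gradient-orientation bins (unsigned orientation over \eqn{[0, \pi)},
#' magnitude-weighted), each summed over `shrink` x `shrink` blocks and
#' smoothed with a \{1,2,1\}/4 separable kernel.
#'
#' @param image grayscale matrix.
#' @param shrink block aggregation factor.
#' @return Array `(ceiling(rows/shrink), ceiling(cols/shrink), 8)`.
#' @export
compute_channels <- function(image, shrink = 4) {
  stopifnot(is.matrix(image))
  nr <- nrow(image)
  nc <- ncol(image)
  # central differences with replicated borders
  padc <- image[, c(1, seq_len(nc), nc)]
  gx <- (padc[, 3:(nc + 2)] - padc[, 1:nc]) / 2
  padr <- image[c(1, seq_len(nr), nr), ]
  gy <- (padr[3:(nr + 2), ] - padr[1:nr, ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ori / pi * 6) + 1, 6)
  chans <- c(
    list(intensity = image, gradmag = mag),
    lapply(1:6, function(k) mag * (bin == k))
  )
  names(chans)[3:8] <- paste0("orient_", 1:6)
  out <- vapply(chans, function(m) smooth121(block_sum(m, shrink)),
                matrix(0, ceiling(nr / shrink), ceiling(nc / shrink)))
  dimnames(out) <- list(NULL, NULL, names(chans))
  out
}

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes as lists/tibbles with `x`, `y`, `w`, `h`.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Detector hyperparameters
#'
#' @param n_trees boosted depth-2 trees per ensemble.
#' @param n_feature_sub candidate features sampled per tree node.
#' @param n_thresholds candidate split thresholds (value quantiles) per
#'   feature.
#' @param neg_per_image random negative windows sampled per training image.
#' @param mining_rounds hard-negative mining rounds after the initial fit.
#' @param mining_images cap on how many training images are scanned per
#'   mining round (scanning is the expensive step; hard negatives from a
#'   deterministic subsample are plenty).
#' @param mining_scales pyramid scales used while mining (the central scales
#'   produce almost all hard negatives).
#' @param shrink channel aggregation factor (pixels per channel cell).
#' @param scales pyramid scale factors (relative image resize); the default
#'   covers half an octave either way in steps of `2^(1/4)`.
#' @param score_quantile training-positive score quantile used as the
#'   detection threshold.
#' @param seed RNG seed for sampling and tree fitting.
#' @return A `roi_config` list.
#' @export
roi_config <- function(n_trees = 64, n_feature_sub = 400, n_thresholds = 8,
                       neg_per_image = 4, mining_rounds = 2,
                       mining_images = 120,
                       mining_scales = 2^seq(-0.25, 0.25, by = 0.25),
                       shrink = 4, scales = 2^seq(-0.5, 0.5, by = 0.25),
                       score_quantile = 0.02, seed = 1) {
  structure(
    list(n_trees = n_trees, n_feature_sub = n_feature_sub,
         n_thresholds = n_thresholds, neg_per_image = neg_per_image,
         mining_rounds = mining_rounds, mining_images = mining_images,
         mining_scales = mining_scales, shrink = shrink, scales = scales,
         score_quantile = score_quantile, seed = as.integer(seed)),
    class = "roi_config"
  )
}

# weighted real-adaboost leaf value
leaf_value <- function(wpos, wneg) 0.5 * log((wpos + 1e-6) / (wneg + 1e-6))

# best threshold split of one node over a feature subsample; the candidate
# thresholds are value quantiles per feature, and all features are scored at
# once per threshold index through one crossprod with the class weights
fit_stump <- function(Xf, y, wts, feats, n_thr) {
  Xs <- Xf[, feats, drop = FALSE]
  n <- nrow(Xs)
  wp <- wts * (y == 1)
  wn <- wts * (y == 0)
  tp <- sum(wp)
  tn <- sum(wn)
  probs <- seq_len(n_thr) / (n_thr + 1)
  thr <- apply(Xs, 2, quantile, probs = probs, names = FALSE, type = 1)
  thr <- matrix(thr, nrow = n_thr)
  best <- list(cost = Inf, feature = feats[1], threshold = Inf)
  for (k in seq_len(n_thr)) {
    L <- Xs <= rep(thr[k, ], each = n)
    lp <- as.vector(crossprod(L, wp))
    ln <- as.vector(crossprod(L, wn))
    cost <- 2 * sqrt(lp * ln) + 2 * sqrt(pmax(tp - lp, 0) * pmax(tn - ln, 0))
    j <- which.min(cost)
    if (cost[j] < best$cost) {
      best <- list(cost = cost[j], feature = feats[j], threshold = thr[k, j])
    }
  }
  best
}

fit_depth2_tree <- function(Xf, y, wts, n_feat_sub, n_thr) {
  d <- ncol(Xf)
  feats <- sample.int(d, min(n_feat_sub, d))
  root <- fit_stump(Xf, y, wts, feats, n_thr)
  left <- Xf[, root$feature] <= root$threshold
  fit_child <- function(sel) {
    if (sum(sel) < 4 || length(unique(y[sel])) < 2) {
      v <- leaf_value(sum(wts[sel & y == 1]), sum(wts[sel & y == 0]))
      return(list(feature = 1L, threshold = Inf, vl = v, vr = v))
    }
    feats <- sample.int(d, min(n_feat_sub, d))
    sp <- fit_stump(Xf[sel, , drop = FALSE], y[sel], wts[sel], feats, n_thr)
    below <- sel & Xf[, sp$feature] <= sp$threshold
    list(
      feature = sp$feature, threshold = sp$threshold,
      vl = leaf_value(sum(wts[below & y == 1]), sum(wts[below & y == 0])),
      vr = leaf_value(sum(wts[sel & !below & y == 1]),
                      sum(wts[sel & !below & y == 0]))
    )
  }
  list(feature = root$feature, threshold = root$threshold,
       left = fit_child(left), right = fit_child(!left))
}

tree_scores <- function(tree, Xf) {
  atL <- Xf[, tree$feature] <= tree$threshold
  sL <- ifelse(Xf[, tree$left$feature] <= tree$left$threshold,
               tree$left$vl, tree$left$vr)
  sR <- ifelse(Xf[, tree$right$feature] <= tree$right$threshold,
               tree$right$vl, tree$right$vr)
  ifelse(atL, sL, sR)
}

boost_ensemble <- function(Xf, y, cfg) {
  n <- nrow(Xf)
  wts <- rep(1 / n, n)
  ysgn <- ifelse(y == 1, 1, -1)
  trees <- vector("list", cfg$n_trees)
  F <- numeric(n)
  for (t in seq_len(cfg$n_trees)) {
    tree <- fit_depth2_tree(Xf, y, wts, cfg$n_feature_sub, cfg$n_thresholds)
    s <- tree_scores(tree, Xf)
    F <- F + s
    wts <- exp(-ysgn * F)
    wts <- wts / sum(wts)
    trees[[t]] <- tree
  }
  list(trees = trees, scores = F)
}

# feature id -> (row offset, col offset, channel) within the window,
# column-major over the (wr, wc, 8) crop
feature_coords <- function(f, wr, wc) {
  f0 <- f - 1L
  list(dr = f0 %% wr, dc = (f0 %/% wr) %% wc, ch = f0 %/% (wr * wc) + 1L)
}

window_feature <- function(chans, r0, c0, wr, wc) {
  as.vector(chans[r0:(r0 + wr - 1), c0:(c0 + wc - 1), , drop = FALSE])
}

#' Train the RoI detector
#'
#' Fits a boosted ensemble of depth-2 trees over aggregated channel features
#' of a fixed window (sized from the median labeled box), with random
#' negatives plus hard-negative mining rounds. Fully deterministic under
#' `config$seed`.
#'
#' @param data tibble with `pixels` (list of grayscale matrices) and true
#'   boxes `x`, `y`, `w`, `h` (1-based top-left corner).
#' @param config a [roi_config()].
#' @return A `roi_detector`: window size, ensemble, score threshold, config.
#' @export
train_roi_detector <- function(data, config = roi_config()) {
  stopifnot(all(c("pixels", "x", "y", "w", "h") %in% names(data)))
  if (nrow(data) < 2) stop("need at least 2 positive boxes to train")
  if (any(data$w <= 0 | data$h <= 0)) stop("degenerate boxes in training data")
  set.seed(config$seed)
  s <- config$shrink
  wr <- max(4L, round(median(data$h) / s))
  wc <- max(4L, round(median(data$w) / s))
  chans <- lapply(data$pixels, compute_channels, shrink = s)
  # positives: window centered on each true box
  pos <- t(mapply(function(ch, x, y, w, h) {
    r0 <- min(max(1, round((y + h / 2) / s - wr / 2)), dim(ch)[1] - wr + 1)
    c0 <- min(max(1, round((x + w / 2) / s - wc / 2)), dim(ch)[2] - wc + 1)
    window_feature(ch, r0, c0, wr, wc)
  }, chans, data$x, data$y, data$w, data$h))
  sample_negatives <- function(per_image) {
    out <- list()
    for (i in seq_len(nrow(data))) {
      ch <- chans[[i]]
      truth <- data[i, c("x", "y", "w", "h")]
      tries <- 0
      got <- 0
      while (got < per_image && tries < 50) {
        tries <- tries + 1
        r0 <- sample.int(dim(ch)[1] - wr + 1, 1)
        c0 <- sample.int(dim(ch)[2] - wc + 1, 1)
        cand <- list(x = (c0 - 1) * s + 1, y = (r0 - 1) * s + 1,
                     w = wc * s, h = wr * s)
        if (box_iou(cand, truth) < 0.3) {
          got <- got + 1
          out[[length(out) + 1]] <- window_feature(ch, r0, c0, wr, wc)
        }
      }
    }
    do.call(rbind, out)
  }
  neg <- sample_negatives(config$neg_per_image)
  det <- NULL
  for (round in 0:config$mining_rounds) {
    Xf <- rbind(pos, neg)
    y <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
    ens <- boost_ensemble(Xf, y, config)
    thr <- quantile(ens$scores[y == 1], config$score_quantile, names = FALSE)
    det <- structure(
      list(window = c(rows = wr, cols = wc), trees = ens$trees,
           score_threshold = thr, config = config),
      class = "roi_detector"
    )
    if (round == config$mining_rounds) break
    # harvest hard false positives against the current ensemble
    miner <- det
    miner$config$scales <- config$mining_scales
    mine_on <- seq_len(min(nrow(data), config$mining_images))
    hard <- list()
    for (i in mine_on) {
      hits <- detect_windows(data$pixels[[i]], miner, keep = 5)
      if (nrow(hits) == 0) next
      truth <- data[i, c("x", "y", "w", "h")]
      for (j in seq_len(nrow(hits))) {
        if (box_iou(hits[j, ], truth) < 0.3) {
          hard[[length(hard) + 1]] <-
            window_feature(compute_channels(
              resize_by(data$pixels[[i]], hits$scale[j]), s),
              hits$r0[j], hits$c0[j], wr, wc)
        }
      }
    }
    if (length(hard) > 0) neg <- rbind(neg, do.call(rbind, hard))
  }
  det
}

#' @export
print.roi_detector <- function(x, ...) {
  cat("<roi_detector> window ", x$window[1], "x", x$window[2],
      " channel cells (", x$window[1] * x$config$shrink, "x",
      x$window[2] * x$config$shrink, " px), ", length(x$trees),
      " depth-2 trees, threshold ", sprintf("%.3f", x$score_threshold),
      "\n", sep = "")
  invisible(x)
}

resize_by <- function(image, scale) {
  if (scale == 1) return(image)
  as_mat(EBImage::resize(image, w = max(8, round(nrow(image) * scale)),
                         h = max(8, round(ncol(image) * scale)),
                         filter = "bilinear"))
}

# score every window position at every pyramid scale; returns candidate boxes
# in original image coordinates above the detector threshold
detect_windows <- function(image, detector, keep = 20) {
  cfg <- detector$config
  s <- cfg$shrink
  wr <- detector$window[1]
  wc <- detector$window[2]
  out <- list()
  for (sc in cfg$scales) {
    im <- resize_by(image, sc)
    if (nrow(im) < wr * s || ncol(im) < wc * s) next
    ch <- compute_channels(im, shrink = s)
    nr_pos <- dim(ch)[1] - wr + 1
    nc_pos <- dim(ch)[2] - wc + 1
    if (nr_pos < 1 || nc_pos < 1) next
    fval <- function(f) {
      co <- feature_coords(f, wr, wc)
      ch[co$dr + seq_len(nr_pos), co$dc + seq_len(nc_pos), co$ch]
    }
    score <- matrix(0, nr_pos, nc_pos)
    for (tree in detector$trees) {
      atL <- fval(tree$feature) <= tree$threshold
      sL <- ifelse(fval(tree$left$feature) <= tree$left$threshold,
                   tree$left$vl, tree$left$vr)
      sR <- ifelse(fval(tree$right$feature) <= tree$right$threshold,
                   tree$right$vl, tree$right$vr)
      score <- score + ifelse(atL, sL, sR)
    }
    hit <- which(score >= detector$score_threshold, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        x = ((hit[, 2] - 1) * s) / sc + 1,
        y = ((hit[, 1] - 1) * s) / sc + 1,
        w = wc * s / sc, h = wr * s / sc,
        score = score[hit], scale = sc, r0 = hit[, 1], c0 = hit[, 2]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), score = numeric(), scale = numeric(),
                          r0 = integer(), c0 = integer()))
  }
  cands <- dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$score))
  utils::head(cands, keep * 10)
}

nms_greedy <- function(boxes, iou = 0.5) {
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (box_iou(boxes[i, ], boxes[j, ]) > iou) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  boxes[keep, , drop = FALSE]
}

#' Detect the cervical-vertebrae RoI in a radiograph
#'
#' Scans a `2^(1/4)`-step scale pyramid with the detector window, applies
#' greedy non-maximum suppression (IoU 0.5), and returns the best box. When
#' nothing scores above the detector threshold a zero-row tibble is returned
#' — the explicit no-detection signal on which callers fall back to manual
#' crop columns in the manifest.
#'
#' @param image grayscale matrix, larger than the detector window.
#' @param detector a trained `roi_detector`.
#' @return A tibble with zero rows (no detection) or one row: `x`, `y`, `w`,
#'   `h` (1-based, clipped to the image) and `score`.
#' @export
detect_roi <- function(image, detector) {
  stopifnot(inherits(detector, "roi_detector"), is.matrix(image))
  s <- detector$config$shrink
  if (nrow(image) < detector$window[1] * s ||
      ncol(image) < detector$window[2] * s) {
    stop("image smaller than the detector window")
  }
  cands <- detect_windows(image, detector)
  if (nrow(cands) == 0) return(cands[, c("x", "y", "w", "h", "score")])
  best <- nms_greedy(cands)[1, ]
  x <- max(1, round(best$x))
  y <- max(1, round(best$y))
  tibble::tibble(
    x = x, y = y,
    w = min(ncol(image) - x + 1, round(best$w)),
    h = min(nrow(image) - y + 1, round(best$h)),
    score = best$score
  )
}
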