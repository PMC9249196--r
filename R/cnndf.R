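#' Configuration of the CNNDF classifier
#'
#' Defaults reproduce the published architecture: a 77 x 35 grayscale input,
#' a tunable directional-filter first layer of 8 channels, a parallel 1 x 1
#' projection with batch norm added back in, four max-pool + residual
#' skip-connection blocks with 32/64/128/256 filters, and a 64-unit dense
#' head. `directional_support = 9` uses the 9-tap band-pass prototype (the
#' full smoothed design); `7` uses the 7-tap high-pass prototype so the first
#' layer matches a 7 x 7 kernel budget while staying zero-DC.
#'
#' @param num_classes 5 (merged CVMS scheme) or 6 (CS scheme).
#' @param input_shape `c(rows, cols, 1)`.
#' @param directional_support 9 or 7.
#' @param dropout_rate dropout fraction inside each skip block.
#' @param leaky_slope negative-slope of the front-end leaky ReLU.
#' @param seed integer seed for weight initialization.
#' @param random_init if `TRUE`, the first layer is randomly initialized
#'   instead of starting from the directional bank (the with/without-filters
#'   ablation switch); everything else is identical.
#' @param widths filter counts of the four skip blocks.
#' @param dense_units units of the dense head.
#' @return A `cnndf_config` list.
#' @export
cnndf_config <- function(num_classes = 5, input_shape = c(77, 35, 1),
                         directional_support = 9, dropout_rate = 0.2,
                         leaky_slope = 0.1, seed = 1, random_init = FALSE,
                         widths = c(32, 64, 128, 256), dense_units = 64) {
  stopifnot(num_classes %in% c(5, 6), dropout_rate >= 0, dropout_rate < 1,
            directional_support %in% c(7, 9), length(input_shape) == 3,
            input_shape[3] == 1, length(widths) == 4)
  structure(
    list(num_classes = as.integer(num_classes), input_shape = input_shape,
         directional_support = directional_support,
         dropout_rate = dropout_rate, leaky_slope = leaky_slope,
         seed = as.integer(seed), random_init = isTRUE(random_init),
         widths = as.integer(widths), dense_units = as.integer(dense_units)),
    class = "cnndf_config"
  )
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1]

#' Build the CNNDF model
#'
#' Constructs the residual network whose first convolutional layer holds the
#' eight directional kernels (flipped so the layer's correlation equals the
#' bank's convolution) and stays trainable; a depthwise "match" layer is
#' initialized as a centered identity so the initial forward pass through the
#' directional path is exactly directional filtering. A parallel 1 x 1
#' convolution + batch norm of the raw input is added back (the front-end
#' residual), followed by four max-pool + skip-connection blocks and a dense
#' softmax head.
#'
#' @param cfg a [cnndf_config()].
#' @param bank a `directional_bank` with 8 kernels; its support must equal
#'   `cfg$directional_support`.
#' @return A `cnndf` model object (an environment holding the layers, the
#'   config, and a layer-table; see [network_spec()]).
#' @export
build_cnndf <- function(cfg = cnndf_config(), bank = NULL) {
  stopifnot(inherits(cfg, "cnndf_config"))
  if (is.null(bank)) {
    proto <- if (cfg$directional_support == 9) {
      bandpass_prototype()
    } else {
      modulate_to_highpass(lagrange_halfband_lowpass())
    }
    bank <- build_bank(prototype = proto)
  }
  if (length(bank) != 8) stop("the directional bank must hold 8 kernels")
  if (nrow(bank[[1]]) != cfg$directional_support) {
    stop("bank support ", nrow(bank[[1]]), " does not match the config (",
         cfg$directional_support, ")")
  }
  set.seed(cfg$seed)
  H <- cfg$input_shape[1]
  W <- cfg$input_shape[2]
  k <- cfg$directional_support
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$bank <- bank
  L <- list()
  L$dir <- layer_conv(H, W, 1, 8, k, pad_mode = "sym", need_input_grad = FALSE)
  if (!cfg$random_init) {
    L$dir$W_ <- t(vapply(bank, function(kk) as.vector(rot180(unclass(kk))),
                         numeric(k * k)))
    L$dir$b_ <- numeric(8)
  }
  L$match <- layer_depthwise(H, W, 8, 7, pad_mode = "sym")
  L$match$W_ <- matrix(0, 8, 49)
  L$match$W_[, 25] <- 1  # centered delta: initial pass is pure filtering
  L$lrelu <- layer_relu(cfg$leaky_slope)
  L$conv0 <- layer_conv(H, W, 1, 8, 1, need_input_grad = FALSE)
  L$bn0 <- layer_bn(8, H * W)
  dims <- c(H, W)
  inC <- 8
  for (i in 1:4) {
    L[[paste0("pool", i)]] <- layer_maxpool(dims[1], dims[2], inC)
    dims <- ceiling(dims / 2)
    outC <- cfg$widths[i]
    hw <- prod(dims)
    L[[paste0("conv", i)]] <- layer_conv(dims[1], dims[2], inC, outC, 3)
    L[[paste0("bn", i)]] <- layer_bn(outC, hw)
    L[[paste0("relu", i)]] <- layer_relu()
    L[[paste0("drop", i)]] <- layer_dropout(cfg$dropout_rate)
    L[[paste0("convskip", i)]] <- layer_conv(dims[1], dims[2], inC, outC, 1)
    L[[paste0("bnskip", i)]] <- layer_bn(outC, hw)
    inC <- outC
  }
  flat <- prod(dims) * inC
  L$dense1 <- layer_dense(flat, cfg$dense_units)
  L$bnd <- layer_bn(cfg$dense_units, 1)
  L$relud <- layer_relu()
  L$dense2 <- layer_dense(cfg$dense_units, cfg$num_classes)
  m$layers <- L
  m$flat <- flat
  m$final_dims <- dims
  m$trained <- FALSE
  class(m) <- "cnndf"
  m
}

cnndf_forward <- function(m, X, training = FALSE) {
  L <- m$layers
  a <- conv_forward(L$dir, X)
  a <- depthwise_forward(L$match, a)
  a <- relu_forward(L$lrelu, a)
  b <- conv_forward(L$conv0, X)
  b <- bn_forward(L$bn0, b, training)
  x <- a + b
  for (i in 1:4) {
    x <- maxpool_forward(L[[paste0("pool", i)]], x)
    main <- conv_forward(L[[paste0("conv", i)]], x)
    main <- bn_forward(L[[paste0("bn", i)]], main, training)
    main <- relu_forward(L[[paste0("relu", i)]], main)
    main <- dropout_forward(L[[paste0("drop", i)]], main, training)
    short <- conv_forward(L[[paste0("convskip", i)]], x)
    short <- bn_forward(L[[paste0("bnskip", i)]], short, training)
    x <- main + short
  }
  x <- dense_forward(L$dense1, x)
  x <- bn_forward(L$bnd, x, training)
  x <- relu_forward(L$relud, x)
  dense_forward(L$dense2, x)
}

cnndf_backward <- function(m, dZ) {
  L <- m$layers
  d <- dense_backward(L$dense2, dZ)
  d <- relu_backward(L$relud, d)
  d <- bn_backward(L$bnd, d)
  d <- dense_backward(L$dense1, d)
  for (i in 4:1) {
    dmain <- dropout_backward(L[[paste0("drop", i)]], d)
    dmain <- relu_backward(L[[paste0("relu", i)]], dmain)
    dmain <- bn_backward(L[[paste0("bn", i)]], dmain)
    dmain <- conv_backward(L[[paste0("conv", i)]], dmain)
    dshort <- bn_backward(L[[paste0("bnskip", i)]], d)
    dshort <- conv_backward(L[[paste0("convskip", i)]], dshort)
    d <- maxpool_backward(L[[paste0("pool", i)]], dmain + dshort)
  }
  da <- relu_backward(L$lrelu, d)
  da <- depthwise_backward(L$match, da)
  conv_backward(L$dir, da)    # gradients only; input gradient not needed
  db <- bn_backward(L$bn0, d)
  conv_backward(L$conv0, db)
  invisible(NULL)
}

#' @export
print.cnndf <- function(x, ...) {
  pc <- count_parameters(x)
  cat("<cnndf> ", x$cfg$num_classes, "-class, input ",
      paste(x$cfg$input_shape, collapse = " x "),
      ", directional support ", x$cfg$directional_support, "x",
      x$cfg$directional_support,
      if (x$cfg$random_init) " (random init)" else " (directional init)",
      "\n  parameters: ", pc$total, " total (", pc$trainable,
      " trainable), ", if (x$trained) "trained" else "untrained", "\n",
      sep = "")
  invisible(x)
}

layer_param_count <- function(L) {
  train <- sum(vapply(L$params, function(p) length(get(p, envir = L)), 0))
  fixed <- if (L$type == "bn") 2 * L$C else 0
  c(trainable = train, fixed = fixed)
}

#' Count model parameters
#'
#' Totals all weights, biases and batch-norm parameters; batch-norm running
#' means/variances are the non-trainable share.
#'
#' @param model a `cnndf`.
#' @return A list with `total`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cnndf"))
  counts <- vapply(model$layers, layer_param_count, numeric(2))
  list(total = sum(counts), trainable = sum(counts["trainable", ]),
       non_trainable = sum(counts["fixed", ]))
}

#' Layer table of a built model
#'
#' One row per architectural layer with its kernel size, filter count, output
#' shape and parameter count (trainable + batch-norm running statistics) —
#' the shape/parameter audit trail of the network.
#'
#' @param model a `cnndf`.
#' @return A tibble with columns `name`, `type`, `kernel`, `filters`,
#'   `output_shape`, `params`, `connected_to`.
#' @export
network_spec <- function(model) {
  stopifnot(inherits(model, "cnndf"))
  L <- model$layers
  cfg <- model$cfg
  H <- cfg$input_shape[1]
  W <- cfg$input_shape[2]
  shp <- function(d) paste(d, collapse = " x ")
  n_of <- function(nm) sum(layer_param_count(L[[nm]]))
  rows <- list(
    list("Input", "input", NA, NA, shp(c(H, W, 1)), 0, ""),
    list("Directional", "conv",
         paste0(cfg$directional_support, "x", cfg$directional_support), 8,
         shp(c(H, W, 8)), n_of("dir"), "Input"),
    list("Match", "depthwise_conv", "7x7", 8, shp(c(H, W, 8)), n_of("match"),
         "Directional"),
    list("Dir_Leaky_ReLU", "leaky_relu", NA, NA, shp(c(H, W, 8)), 0, "Match"),
    list("Conv_0", "conv", "1x1", 8, shp(c(H, W, 8)), n_of("conv0"), "Input"),
    list("Batch_0", "batch_norm", NA, NA, shp(c(H, W, 8)), n_of("bn0"),
         "Conv_0"),
    list("ADD_1", "add", NA, NA, shp(c(H, W, 8)), 0,
         "Dir_Leaky_ReLU & Batch_0")
  )
  dims <- c(H, W)
  inC <- 8
  prev <- "ADD_1"
  for (i in 1:4) {
    dims <- ceiling(dims / 2)
    outC <- cfg$widths[i]
    rows <- c(rows, list(
      list(paste0("Max_", i), "max_pool", "2x2", NA, shp(c(dims, inC)), 0,
           prev),
      list(paste0("Skip_Con_", i), "skip_connection", NA, outC,
           shp(c(dims, outC)),
           n_of(paste0("conv", i)) + n_of(paste0("bn", i)) +
             n_of(paste0("convskip", i)) + n_of(paste0("bnskip", i)),
           paste0("Max_", i))
    ))
    inC <- outC
    prev <- paste0("Skip_Con_", i)
  }
  rows <- c(rows, list(
    list("Flatten", "flatten", NA, NA, as.character(model$flat), 0, prev),
    list("Dense_1", "dense", NA, cfg$dense_units,
         as.character(cfg$dense_units), n_of("dense1"), "Flatten"),
    list("Batch_11", "batch_norm", NA, NA, as.character(cfg$dense_units),
         n_of("bnd"), "Dense_1"),
    list("Relu_11", "relu", NA, NA, as.character(cfg$dense_units), 0,
         "Batch_11"),
    list("Output_Dense", "dense_softmax", NA, cfg$num_classes,
         as.character(cfg$num_classes), n_of("dense2"), "Relu_11")
  ))
  purrr::map_dfr(rows, ~tibble::tibble(
    name = .x[[1]], type = .x[[2]], kernel = as.character(.x[[3]]),
    filters = as.integer(.x[[4]]), output_shape = .x[[5]],
    params = as.integer(.x[[6]]), connected_to = .x[[7]]
  ))
}

pixels_to_matrix <- function(pixels, input_shape) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  stopifnot(all(vapply(pixels, function(p) {
    identical(dim(p), as.integer(input_shape[1:2]))
  }, TRUE)))
  vapply(pixels, as.vector, numeric(prod(input_shape[1:2])))
}

#' Predict class probabilities
#'
#' @param object a `cnndf` model.
#' @param pixels one grayscale matrix of the model's input size, a list of
#'   them, or a tibble with a `pixels` list-column.
#' @param type `"prob"` for a probability matrix (rows sum to 1) or
#'   `"class"` for argmax labels (ties broken toward the lower class index).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return A numeric matrix (n x num_classes) or an integer vector.
#' @export
predict.cnndf <- function(object, pixels, type = c("prob", "class"),
                          batch_size = 256, ...) {
  type <- match.arg(type)
  if (is.data.frame(pixels)) pixels <- pixels$pixels
  X <- pixels_to_matrix(pixels, object$cfg$input_shape)
  n <- ncol(X)
  probs <- matrix(NA_real_, n, object$cfg$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    span <- start:min(start + batch_size - 1, n)
    Z <- cnndf_forward(object, X[, span, drop = FALSE], training = FALSE)
    probs[span, ] <- t(softmax_cols(Z))
  }
  if (type == "class") max.col(probs, ties.method = "first") else probs
}

#' Training hyperparameters
#'
#' The optimizer, rate and schedule are exposed here; the loss is categorical
#' cross-entropy throughout.
#'
#' @param optimizer only `"adam"` is provided.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs passes over the training set.
#' @param seed seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 32, epochs = 60, seed = 1) {
  stopifnot(identical(optimizer, "adam"), epochs >= 1, batch_size >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the CNNDF
#'
#' Minibatch Adam on categorical cross-entropy. The tunable first layer is
#' updated by backpropagation like every other layer, so its weights move
#' away from the directional initialization during training. Training images
#' may be raw or augmented; labels must lie in `1..num_classes`.
#'
#' @param model a `cnndf` from [build_cnndf()]; mutated in place and returned.
#' @param data tibble with `pixels` (list of input-size matrices) and `label`.
#' @param cfg a [train_config()].
#' @param validation optional tibble like `data`, scored after each epoch
#'   (refused if it contains augmented rows).
#' @param verbose print per-epoch progress.
#' @return The model, with a `history` tibble (epoch, train_loss, train_acc,
#'   val_loss, val_acc) stored on it.
#' @export
train_cnndf <- function(model, data, cfg = train_config(), validation = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "cnndf"), inherits(cfg, "train_config"))
  if (nrow(data) == 0) stop("empty training set")
  y <- as.integer(data$label)
  if (any(is.na(y)) || any(y < 1 | y > model$cfg$num_classes)) {
    stop("labels out of range for a ", model$cfg$num_classes, "-class model")
  }
  if (!is.null(validation)) assert_not_augmented(validation)
  X <- pixels_to_matrix(data$pixels, model$cfg$input_shape)
  n <- ncol(X)
  set.seed(cfg$seed)
  hist <- vector("list", cfg$epochs)
  t_step <- 0
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      span <- perm[start:min(start + cfg$batch_size - 1, n)]
      Z <- cnndf_forward(model, X[, span, drop = FALSE], training = TRUE)
      ce <- cross_entropy(Z, y[span])
      cnndf_backward(model, ce$grad)
      t_step <- t_step + 1
      adam_step(model$layers, cfg$learning_rate, t_step)
      ep_loss <- ep_loss + ce$loss * length(span)
      ep_correct <- ep_correct + sum(max.col(t(ce$prob), "first") == y[span])
    }
    row <- tibble::tibble(
      epoch = epoch,
      train_loss = ep_loss / n,
      train_acc = ep_correct / n,
      val_loss = NA_real_,
      val_acc = NA_real_
    )
    if (!is.null(validation)) {
      vp <- predict(model, validation$pixels)
      vy <- as.integer(validation$label)
      row$val_loss <- -mean(log(pmax(vp[cbind(seq_along(vy), vy)], 1e-12)))
      row$val_acc <- mean(max.col(vp, "first") == vy)
    }
    hist[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f acc %.3f%s", epoch, row$train_loss,
                      row$train_acc,
                      if (is.na(row$val_acc)) "" else
                        sprintf(" | val %.3f", row$val_acc)))
    }
  }
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  invisible(model)
}

#' Evaluate a trained model on a held-out set
#'
#' Scores argmax predictions and one-vs-rest ROC/AUC via
#' [evaluate_predictions()]. Augmented rows are refused.
#'
#' @param model a trained `cnndf`.
#' @param data tibble with `pixels` and `label`.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, data) {
  stopifnot(nrow(data) > 0)
  assert_not_augmented(data)
  prob <- predict(model, data$pixels)
  evaluate_predictions(as.integer(data$label), prob)
}

#' @export
tidy.cnndf <- function(x, ...) network_spec(x)

#' @export
glance.cnndf <- function(x, ...) {
  pc <- count_parameters(x)
  tibble::tibble(
    num_classes = x$cfg$num_classes,
    parameters = pc$total,
    trainable = pc$trainable,
    directional_support = x$cfg$directional_support,
    random_init = x$cfg$random_init,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history)
  )
}

#' @export
autoplot.cnndf <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history yet")
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL,
                  title = "CNNDF training history")
}
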