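#' @title Synthetic cephalogram generator
#'
#' @description
#' The generator emulates what matters about a lateral cephalogram for CVM
#' staging: a large noisy radiograph containing the stacked C2-C4 vertebral
#' bodies, whose inferior-border concavity and body aspect ratio encode the
#' stage. Stage-conditional geometry follows the morphological definitions:
#'
#' * CS1: inferior borders of C2-C4 flat; C3 and C4 trapezoidal (superior
#'   border narrower than inferior).
#' * CS2: a notch on the inferior border of C2 only; C3/C4 flat, trapezoidal.
#' * CS3: notches on C2 and C3; C4 flat; C3/C4 still trapezoidal.
#' * CS4: obvious concavities on C2-C4; C3/C4 horizontally elongated
#'   rectangles (aspect ratio width/height > 1.15).
#' * CS5: concavities on all three; C3/C4 near-square (aspect in [0.9, 1.1]).
#' * CS6: concavities on all three; C3 and C4 vertically elongated
#'   (aspect < 0.85).
#'
#' The numeric shape parameters (width ranges, notch depths, the 1.15 /
#' [0.9, 1.1] / 0.85 aspect thresholds) are the generator's own
#' operationalization of those qualitative definitions; they are synthetic and
#' carry no measured morphometry.
#' @name synthetic
NULL

stage_params <- list(
  # concavity depth as a fraction of body height, per stage
  notch = list(
    `1` = c(0, 0.04), `2` = c(0.08, 0.18), `3` = c(0.10, 0.24),
    `4` = c(0.14, 0.28), `5` = c(0.18, 0.32), `6` = c(0.20, 0.34)
  ),
  flat = c(0, 0.04),
  # C3/C4 aspect ratio (width/height) and superior/inferior width ratio
  aspect = list(
    trapezoid = c(1.25, 1.55), cs4 = c(1.20, 1.45),
    cs5 = c(0.92, 1.08), cs6 = c(0.68, 0.84)
  ),
  sup_ratio = list(trapezoid = c(0.72, 0.88), rectangular = c(0.93, 1.0))
)

r_unif <- function(range) runif(1, range[1], range[2])

#' Draw a stage-conditional vertebral geometry
#'
#' Samples per-body shape parameters for C2, C3 and C4 from the
#' stage-conditional distributions described in [synthetic]. Uses the current
#' R random-number stream; seed with [set.seed()] for reproducibility.
#'
#' @param stage integer CVM stage, 1-6.
#' @return A `vertebra_geometry`: tibble with one row per body (`C2`, `C3`,
#'   `C4`) and columns `width`, `height`, `aspect` (width/height), `concavity`
#'   (inferior-notch depth as a fraction of height), `sup_ratio`
#'   (superior/inferior width ratio), and a `corners` list-column of 4x2
#'   (x, y) offsets (TL, TR, BR, BL) from the body center; the `stage` is kept
#'   as an attribute.
#' @export
#' @examples
#' set.seed(1)
#' sample_stage_geometry(4)
sample_stage_geometry <- function(stage) {
  if (!is.numeric(stage) || length(stage) != 1 || !stage %in% 1:6) {
    stop("stage must be a single integer in 1..6")
  }
  stage <- as.integer(stage)
  p <- stage_params
  notch <- p$notch[[as.character(stage)]]
  conc <- c(
    C2 = if (stage >= 2) r_unif(notch) else r_unif(p$flat),
    C3 = if (stage >= 3) r_unif(notch) else r_unif(p$flat),
    C4 = if (stage >= 4) r_unif(notch) else r_unif(p$flat)
  )
  asp_rng <- switch(as.character(stage),
    `4` = p$aspect$cs4, `5` = p$aspect$cs5, `6` = p$aspect$cs6,
    p$aspect$trapezoid
  )
  sup_rng <- if (stage <= 3) p$sup_ratio$trapezoid else p$sup_ratio$rectangular
  w3 <- runif(1, 40, 48)
  width <- c(C2 = w3 * runif(1, 1.0, 1.1), C3 = w3, C4 = w3 * runif(1, 0.96, 1.04))
  aspect <- c(C2 = runif(1, 1.35, 1.65), C3 = r_unif(asp_rng), C4 = r_unif(asp_rng))
  sup_ratio <- c(C2 = runif(1, 0.85, 0.95), C3 = r_unif(sup_rng), C4 = r_unif(sup_rng))
  height <- width / aspect
  corners <- purrr::map(1:3, function(i) {
    hw <- width[i] / 2
    hh <- height[i] / 2
    matrix(c(-hw * sup_ratio[i], -hh, hw * sup_ratio[i], -hh, hw, hh, -hw, hh),
           ncol = 2, byrow = TRUE,
           dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
  })
  out <- tibble::tibble(
    body = c("C2", "C3", "C4"),
    width = unname(width), height = unname(height), aspect = unname(aspect),
    concavity = unname(conc), sup_ratio = unname(sup_ratio),
    corners = corners
  )
  structure(out, stage = stage, class = c("vertebra_geometry", class(out)))
}

as_mat <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

# Rasterize one trapezoidal body with a concave inferior border.
# X, Y are col()/row() grids of the canvas; returns a logical mask.
body_mask <- function(X, Y, cx, cy, w, h, sup_ratio, depth) {
  top <- cy - h / 2
  bot <- cy + h / 2
  frac <- pmin(pmax((Y - top) / h, 0), 1)
  halfw <- (w / 2) * (sup_ratio + (1 - sup_ratio) * frac)
  u <- pmin(abs(X - cx) / (w / 2), 1)
  y_inf <- bot - depth * h * cospi(u / 2)^2
  (Y >= top) & (Y <= y_inf) & (abs(X - cx) <= halfw)
}

# Phase 1 of rendering: place the bodies on the canvas and derive the true
# RoI box, without rasterizing. Consumes RNG draws in a fixed order.
layout_stack <- function(geom, canvas, tilt_deg = 0) {
  nr <- canvas[1]
  nc <- canvas[2]
  cx0 <- nc * runif(1, 0.45, 0.60)
  top <- nr * runif(1, 0.30, 0.40)
  gaps <- runif(2, 0.18, 0.28)
  jit <- runif(3, -3, 3)
  cy <- numeric(3)
  y <- top
  for (i in 1:3) {
    cy[i] <- y + geom$height[i] / 2
    if (i < 3) y <- y + geom$height[i] + gaps[i] * geom$height[i]
  }
  stack_mid <- mean(cy)
  cx <- cx0 + jit + tanpi(tilt_deg / 180) * (cy - stack_mid)
  xmin <- min(cx - geom$width / 2)
  xmax <- max(cx + geom$width / 2)
  ymin <- min(cy - geom$height / 2)
  ymax <- max(cy + geom$height / 2)
  padx <- 0.10 * (xmax - xmin)
  pady <- 0.10 * (ymax - ymin)
  box <- tibble::tibble(
    x = max(1, floor(xmin - padx)),
    y = max(1, floor(ymin - pady)),
    w = min(nc, ceiling(xmax + padx)) - max(1, floor(xmin - padx)) + 1,
    h = min(nr, ceiling(ymax + pady)) - max(1, floor(ymin - pady)) + 1
  )
  list(cx = cx, cy = cy, box = box)
}

#' Render a synthetic cephalogram
#'
#' Rasterizes a [sample_stage_geometry()] draw onto a noisy radiograph-like
#' canvas: smooth low-frequency background texture, a bright elliptical skull
#' distractor, the three bodies as bright filled polygons, a global Gaussian
#' blur, and additive Gaussian noise. Uses the current RNG stream; the same
#' seed gives a bit-identical sample.
#'
#' @param geom a `vertebra_geometry`.
#' @param stage stage label to attach (defaults to the geometry's stage).
#' @param canvas `c(rows, cols)` canvas size.
#' @param noise_sd standard deviation of the additive pixel noise.
#' @param texture_amp amplitude of the low-frequency background texture.
#' @param blur_sigma Gaussian blur radius in pixels.
#' @param tilt_deg optional global tilt of the vertebral column (degrees);
#'   approximated by shearing the body centers, 0 by default.
#' @return A list of class `cvm_sample`: `pixels` (rows x cols matrix in
#'   \[0,1\]), `label`, `box` (tibble x, y, w, h; 1-based top-left corner),
#'   `geometry`.
#' @export
render_cephalogram <- function(geom, stage = attr(geom, "stage"),
                               canvas = c(400, 300), noise_sd = 0.04,
                               texture_amp = 0.06, blur_sigma = 1.2,
                               tilt_deg = 0) {
  stopifnot(inherits(geom, "vertebra_geometry"))
  nr <- canvas[1]
  nc <- canvas[2]
  if (max(geom$width, geom$height) > min(nr, nc) / 2) {
    stop("geometry too large for the canvas")
  }
  lay <- layout_stack(geom, canvas, tilt_deg)

  # background: base level plus two octaves of smooth noise
  bg <- matrix(0.33, nr, nc)
  if (texture_amp > 0) {
    coarse <- matrix(rnorm(8 * 6), 8, 6)
    fine <- matrix(rnorm(24 * 18), 24, 18)
    bg <- bg + texture_amp * as_mat(EBImage::resize(coarse, w = nr, h = nc)) +
      (texture_amp / 2) * as_mat(EBImage::resize(fine, w = nr, h = nc))
  } else {
    # keep the RNG stream aligned across texture settings
    rnorm(8 * 6 + 24 * 18)
  }
  # skull-like distractor: bright ellipse in the upper-left quadrant
  e_cx <- nc * runif(1, 0.15, 0.30)
  e_cy <- nr * runif(1, 0.15, 0.30)
  ex2 <- ((seq_len(nc) - e_cx) / (nc * 0.22))^2
  ey2 <- ((seq_len(nr) - e_cy) / (nr * 0.20))^2
  img <- bg + 0.15 * (outer(ey2, ex2, "+") < 1)

  levels <- runif(3, 0.68, 0.78)
  for (i in 1:3) {
    # rasterize each body only on its bounding subgrid
    rows <- max(1, floor(lay$cy[i] - geom$height[i] / 2 - 1)):
      min(nr, ceiling(lay$cy[i] + geom$height[i] / 2 + 1))
    cols <- max(1, floor(lay$cx[i] - geom$width[i] / 2 - 1)):
      min(nc, ceiling(lay$cx[i] + geom$width[i] / 2 + 1))
    Xs <- matrix(rep(cols, each = length(rows)), length(rows))
    Ys <- matrix(rep(rows, length(cols)), length(rows))
    m <- body_mask(Xs, Ys, lay$cx[i], lay$cy[i], geom$width[i],
                   geom$height[i], geom$sup_ratio[i], geom$concavity[i])
    sub <- img[rows, cols]
    sub[m] <- levels[i]
    img[rows, cols] <- sub
  }
  if (blur_sigma > 0) img <- as_mat(EBImage::gblur(img, sigma = blur_sigma))
  img <- img + rnorm(nr * nc, sd = noise_sd)
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(pixels = img, label = as.integer(stage), box = lay$box,
         geometry = geom),
    class = "cvm_sample"
  )
}

#' @export
print.cvm_sample <- function(x, ...) {
  cat("<cvm_sample> stage CS", x$label, ", ", nrow(x$pixels), "x",
      ncol(x$pixels), " px, RoI box (x=", x$box$x, ", y=", x$box$y,
      ", w=", x$box$w, ", h=", x$box$h, ")\n", sep = "")
  invisible(x)
}

#' @export
autoplot.cvm_sample <- function(object, ...) {
  px <- object$pixels
  df <- tibble::tibble(
    col = as.vector(col(px)), row = as.vector(row(px)), value = as.vector(px)
  )
  b <- object$box
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::annotate("rect", xmin = b$x, xmax = b$x + b$w - 1,
                      ymin = b$y + b$h - 1, ymax = b$y,
                      colour = "red", fill = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Synthetic cephalogram, stage CS", object$label),
                  x = NULL, y = NULL, fill = "I")
}

#' The published six-stage class profile
#'
#' Per-stage image counts of the study data set (CS1..CS6); they sum to 1018.
#' Used as the default per-class profile of [generate_manifest()].
#'
#' @return Integer vector of length 6.
#' @export
published_class_profile <- function() c(154L, 187L, 174L, 159L, 167L, 177L)

published_profile <- published_class_profile

resolve_profile <- function(n_per_class) {
  if (identical(n_per_class, "published")) return(published_profile())
  stopifnot(is.numeric(n_per_class), length(n_per_class) == 6,
            all(n_per_class >= 0))
  as.integer(n_per_class)
}

#' Generate a labeled set of synthetic cephalograms in memory
#'
#' @param n_per_class integer vector of per-stage counts (stages 1-6), or
#'   `"published"` for the published class profile 154, 187, 174, 159, 167, 177.
#' @param seed integer master seed; each sample gets its own sub-seed so
#'   generation is reproducible and order-independent.
#' @param ... passed to [render_cephalogram()].
#' @return A tibble with columns `source_id`, `label`, `seed`, `x`, `y`, `w`,
#'   `h` (true RoI box) and a `pixels` list-column.
#' @export
generate_samples <- function(n_per_class, seed = 1, ...) {
  plan <- manifest_plan(n_per_class, seed)
  rows <- purrr::pmap(plan, function(source_id, label, seed, ...) {
    set.seed(seed)
    s <- render_cephalogram(sample_stage_geometry(label), ...)
    tibble::tibble(source_id = source_id, label = label, seed = seed,
                   x = s$box$x, y = s$box$y, w = s$box$w, h = s$box$h,
                   pixels = list(s$pixels))
  })
  dplyr::bind_rows(rows)
}

# The deterministic skeleton shared by generate_samples()/generate_manifest():
# ids, labels and per-sample seeds, plus the true boxes (phase-1 layout only).
manifest_plan <- function(n_per_class, seed) {
  counts <- resolve_profile(n_per_class)
  labels <- rep(1:6, counts)
  n <- length(labels)
  set.seed(seed)
  seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
  tibble::tibble(
    source_id = sprintf("syn_%04d_cs%d", seq_len(n), labels),
    label = labels,
    seed = seeds
  )
}

#' Write a synthetic data set to disk with a CSV manifest
#'
#' Renders `n_per_class` samples per stage, writes each as an 8-bit grayscale
#' PNG, and writes a manifest CSV with columns `path`, `label`, `x`, `y`, `w`,
#' `h`, `seed` (the true RoI box uses 1-based top-left pixel coordinates).
#' Runs twice with the same seed produce byte-identical manifests and images.
#'
#' @inheritParams generate_samples
#' @param outdir output directory (created if missing).
#' @param write_images if `FALSE`, only the manifest is produced (the boxes
#'   are still computed from each sample's layout draw); useful for planning
#'   and for count checks.
#' @return The manifest tibble, invisibly written to `outdir/manifest.csv`.
#' @export
generate_manifest <- function(n_per_class = "published", seed = 1, outdir,
                              write_images = TRUE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  plan <- manifest_plan(n_per_class, seed)
  boxes <- purrr::pmap(plan, function(source_id, label, seed) {
    set.seed(seed)
    if (write_images) {
      s <- render_cephalogram(sample_stage_geometry(label), ...)
      png::writePNG(s$pixels, file.path(outdir, paste0(source_id, ".png")))
      s$box
    } else {
      dots <- list(...)
      geom <- sample_stage_geometry(label)
      layout_stack(geom,
                   canvas = if (is.null(dots$canvas)) c(400, 300) else dots$canvas,
                   tilt_deg = if (is.null(dots$tilt_deg)) 0 else dots$tilt_deg)$box
    }
  })
  manifest <- dplyr::bind_cols(
    tibble::tibble(path = file.path(outdir, paste0(plan$source_id, ".png")),
                   label = plan$label),
    dplyr::bind_rows(boxes),
    tibble::tibble(seed = plan$seed)
  )
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}
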