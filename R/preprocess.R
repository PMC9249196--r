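#' Crop an RoI and resize to the network input without distorting proportions
#'
#' The crop is scaled by the single factor that fits it inside the target
#' (both axes share the factor, so vertebra proportions are preserved), then
#' padded symmetrically with the crop's median intensity to exactly the
#' target size. Bilinear interpolation throughout. Extra padding pixels go to
#' the bottom/right when the total is odd.
#'
#' @param image grayscale matrix in \[0,1\].
#' @param box RoI as a tibble/list with `x`, `y`, `w`, `h` (1-based top-left).
#' @param target `c(rows, cols)` output size; default `c(77, 35)`.
#' @return A `target[1]` x `target[2]` matrix.
#' @export
crop_and_resize <- function(image, box, target = c(77, 35)) {
  stopifnot(is.matrix(image))
  x <- round(box$x)
  y <- round(box$y)
  w <- round(box$w)
  h <- round(box$h)
  if (is.na(w) || is.na(h) || w < 1 || h < 1) stop("empty crop")
  x <- max(1, x)
  y <- max(1, y)
  x2 <- min(ncol(image), x + w - 1)
  y2 <- min(nrow(image), y + h - 1)
  if (x2 < x || y2 < y) stop("empty crop")
  crop <- image[y:y2, x:x2, drop = FALSE]
  scale <- min(target[1] / nrow(crop), target[2] / ncol(crop))
  nr <- max(1L, round(nrow(crop) * scale))
  nc <- max(1L, round(ncol(crop) * scale))
  resized <- as_mat(EBImage::resize(crop, w = nr, h = nc, filter = "bilinear"))
  fill <- median(crop)
  out <- matrix(fill, target[1], target[2])
  r0 <- (target[1] - nr) %/% 2
  c0 <- (target[2] - nc) %/% 2
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- resized
  out
}

#' Shift an image by whole pixels with constant fill
#'
#' Positive `dy` moves content down, positive `dx` moves it right; exposed
#' pixels take `fill`.
#'
#' @param image grayscale matrix.
#' @param dy,dx integer displacements in pixels.
#' @param fill fill intensity for exposed pixels.
#' @return A matrix of the same size.
#' @export
shift_image <- function(image, dy, dx, fill = median(image)) {
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

#' Rotate an image about its center
#'
#' Bilinear resampling on the inverse mapping; pixels sampled from outside
#' the source take `fill`. Positive angles rotate counterclockwise.
#'
#' @inheritParams shift_image
#' @param angle_deg rotation angle in degrees.
#' @return A matrix of the same size.
#' @export
rotate_image <- function(image, angle_deg, fill = median(image)) {
  nr <- nrow(image)
  nc <- ncol(image)
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  # inverse mapping: for each output pixel, sample the source at -angle
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  Y <- matrix(rep(seq_len(nr), nc), nr, nc) - cy
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  sx <- R[1, 1] * X + R[1, 2] * Y + cx
  sy <- R[2, 1] * X + R[2, 2] * Y + cy
  x0 <- floor(sx)
  y0 <- floor(sy)
  fx <- sx - x0
  fy <- sy - y0
  pick <- function(yy, xx) {
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- pick(y0, x0)
  v01 <- pick(y0, x0 + 1)
  v10 <- pick(y0 + 1, x0)
  v11 <- pick(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' The ten label-preserving augmentations of an RoI image
#'
#' Eight integer shifts (3 px and 6 px toward each of right, left, down, up)
#' and two rotations (+5 and -5 degrees about the center, bilinear), all
#' filled with the image's median intensity. Displacements are small relative
#' to the 35-px image width so the vertebral stack stays in frame.
#'
#' @param image 77x35 grayscale matrix (any size is accepted).
#' @return A named list of 10 matrices
#'   (`shift_right3`, ..., `rot_ccw5`).
#' @export
augment_image <- function(image) {
  stopifnot(is.matrix(image))
  fill <- median(image)
  list(
    shift_right3 = shift_image(image, 0, 3, fill),
    shift_left3  = shift_image(image, 0, -3, fill),
    shift_down3  = shift_image(image, 3, 0, fill),
    shift_up3    = shift_image(image, -3, 0, fill),
    shift_right6 = shift_image(image, 0, 6, fill),
    shift_left6  = shift_image(image, 0, -6, fill),
    shift_down6  = shift_image(image, 6, 0, fill),
    shift_up6    = shift_image(image, -6, 0, fill),
    rot_cw5      = rotate_image(image, -5, fill),
    rot_ccw5     = rotate_image(image, 5, fill)
  )
}

#' Augment a training set elevenfold
#'
#' Appends the 10 augmentations of every image to the originals, preserving
#' labels and per-class proportions exactly (output counts are 11x the input
#' counts in every class). Augmented rows carry `is_augmented = TRUE` and a
#' `parent_id` so the evaluation protocol can assert that no augmented image
#' ever reaches a validation or test fold.
#'
#' @param data tibble with at least `source_id`, `label` and a `pixels`
#'   list-column of grayscale matrices.
#' @return A tibble of `11 * nrow(data)` rows with columns `source_id`,
#'   `parent_id`, `label`, `is_augmented`, `pixels`.
#' @export
augment_dataset <- function(data) {
  stopifnot(all(c("source_id", "label", "pixels") %in% names(data)))
  orig <- tibble::tibble(
    source_id = data$source_id,
    parent_id = data$source_id,
    label = data$label,
    is_augmented = FALSE,
    pixels = data$pixels
  )
  aug <- purrr::map2(data$pixels, data$source_id, function(px, id) {
    a <- augment_image(px)
    tibble::tibble(
      source_id = paste0(id, "_", names(a)),
      parent_id = id,
      label = NA_integer_,
      is_augmented = TRUE,
      pixels = unname(a)
    )
  })
  aug <- dplyr::bind_rows(aug)
  aug$label <- rep(data$label, each = 10L)
  dplyr::bind_rows(orig, aug)
}
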